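#' Pipeline configuration
#'
#' All tunable parameters of the end-to-end run, serialized into the output
#' manifest. Defaults follow the analysis conventions: alpha 0.05, minimum
#' cluster extent 9 voxels, 8-connectivity, 500 um central fovea exclusion,
#' age/sex/retina covariates.
#'
#' @param input_dir directory of grid-tsv maps plus `covariates.csv`
#' @param output_dir result directory (created)
#' @param layers response layers analysed against the reference group
#' @param covariates GLM covariates, subset of `c("age","sex","retina_voxel")`
#' @param reference_group label of the control group
#' @param target_policy `"cohort-mean-template"` or `"designated-reference"`
#' @param eye_policy `"average-within-subject"` or `"eye-level"`
#' @param alpha FDR level
#' @param min_cluster_voxels minimum surviving cluster extent
#' @param connectivity 4 or 8
#' @param fovea_exclusion_radius_um central exclusion radius (um)
#' @param fovea_sigma_um fovea-detection smoothing in micrometres
#' @param rescale_thickness rescale thickness by the depth-affine scale
#' @param color_range_um,color_range_pct overlay clipping limits
#' @param seed integer seed recorded in the manifest
#' @return a named list of class `pipeline_config`
#' @export
pipeline_config <- function(input_dir = NULL, output_dir = NULL,
                            layers = c("RNFL", "GCIPL", "INL"),
                            covariates = c("age", "sex", "retina_voxel"),
                            reference_group = "HC",
                            target_policy = "cohort-mean-template",
                            eye_policy = "average-within-subject",
                            alpha = 0.05, min_cluster_voxels = 9L,
                            connectivity = 8L,
                            fovea_exclusion_radius_um = 500,
                            fovea_sigma_um = 250, rescale_thickness = FALSE,
                            color_range_um = 5, color_range_pct = 15,
                            seed = 1L) {
  structure(as.list(environment()), class = "pipeline_config")
}

#' Validate a pipeline configuration
#'
#' Reports unknown keys, out-of-range values and missing inputs without
#' aborting.
#'
#' @param config a [pipeline_config()] or plain named list
#' @return list: `valid` (logical) and `issues` (character vector)
#' @export
validate_config <- function(config) {
  known <- names(formals(pipeline_config))
  issues <- character()
  unknown <- setdiff(names(config), known)
  if (length(unknown))
    issues <- c(issues, paste("unknown key(s):", paste(unknown, collapse = ", ")))
  chk <- function(cond, msg) if (!isTRUE(cond)) issues <<- c(issues, msg)
  chk(is.numeric(config$alpha) && config$alpha > 0 && config$alpha < 1,
      "alpha must be in (0, 1)")
  chk(is.numeric(config$min_cluster_voxels) && config$min_cluster_voxels >= 1,
      "min_cluster_voxels must be >= 1")
  chk(config$connectivity %in% c(4, 8), "connectivity must be 4 or 8")
  chk(is.numeric(config$fovea_exclusion_radius_um) &&
        config$fovea_exclusion_radius_um >= 0,
      "fovea_exclusion_radius_um must be >= 0")
  chk(config$eye_policy %in% c("average-within-subject", "eye-level"),
      "eye_policy must be average-within-subject or eye-level")
  chk(config$target_policy %in% c("cohort-mean-template",
                                  "designated-reference"),
      "target_policy must be cohort-mean-template or designated-reference")
  chk(all(config$layers %in% c("RNFL", "GCIPL", "INL")),
      "layers must be among RNFL, GCIPL, INL")
  if (!is.null(config$input_dir))
    chk(dir.exists(config$input_dir),
        paste("input_dir does not exist:", config$input_dir))
  list(valid = length(issues) == 0L, issues = issues)
}

#' Write a synthetic cohort to disk in the portable formats
#'
#' One grid-tsv map (plus sidecar) per subject/eye/layer, named
#' `<subject>_<eye>_<layer>.tsv`, plus `covariates.csv` and
#' `ground_truth.json`.
#'
#' @param cohort a [make_cohort()] result
#' @param dir output directory (created)
#' @return `dir`, invisibly
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (subj in cohort$subjects) {
    eye <- "OS"
    for (layer in names(subj$maps)) {
      m <- subj$maps[[layer]]
      write_thickness_map(
        m, file.path(dir, sprintf("%s_%s_%s.tsv", m$subject_id, eye,
                                  gsub("/", "-", layer))))
    }
  }
  utils::write.csv(cohort$covariates, file.path(dir, "covariates.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(jitters = cohort$ground_truth$jitters,
         scales = cohort$ground_truth$scales),
    file.path(dir, "ground_truth.json"), digits = NA)
  invisible(dir)
}

#' Run the full analysis pipeline
#'
#' End-to-end run over a directory of thickness maps: read and
#' left-normalize all scans, build the target space, register every scan,
#' stack each layer per the eye policy, compare every non-reference group
#' with the reference by voxel-wise GLM with BH-FDR + cluster-extent
#' correction, compute percentage-change maps, render overlays, and write a
#' manifest (configuration, package version, per-comparison cluster tables)
#' sufficient to reproduce the run. Deterministic outputs are bit-identical
#' across reruns with the same inputs and configuration.
#'
#' @param config a [pipeline_config()] with `input_dir` and `output_dir` set
#' @return the manifest, invisibly; outputs under `config$output_dir`
#' @export
run_pipeline <- function(config) {
  chk <- validate_config(config)
  if (!chk$valid)
    stop("config error: ", paste(chk$issues, collapse = "; "))
  if (is.null(config$input_dir) || is.null(config$output_dir))
    stop("config error: input_dir and output_dir are required")
  out <- config$output_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  log_lines <- character()
  say <- function(fmt, ...) {
    line <- sprintf(fmt, ...)
    message(line)
    log_lines <<- c(log_lines, line)
  }

  cov <- read_covariates(file.path(config$input_dir, "covariates.csv"))
  say("stage covariates: %d rows, groups %s", nrow(cov),
      paste(unique(cov$group), collapse = "/"))

  layer_names <- c("RNFL", "GCIPL", "INL", "Retina")
  scans <- list()
  scan_meta <- NULL
  for (r in seq_len(nrow(cov))) {
    id <- cov$subject_id[r]; eye <- cov$eye[r]
    maps <- lapply(layer_names, function(layer) {
      p <- file.path(config$input_dir,
                     sprintf("%s_%s_%s.tsv", id, eye, layer))
      if (!file.exists(p))
        stop(sprintf("stage read: missing map for subject %s (%s): %s",
                     id, eye, p))
      flip_to_left(read_thickness_map(p))
    })
    names(maps) <- layer_names
    scans[[length(scans) + 1L]] <- list(maps = maps, boundaries = NULL)
    scan_meta <- rbind(scan_meta, data.frame(subject_id = id, eye = eye,
                                             group = cov$group[r]))
  }
  say("stage read: %d scans x 4 layers", length(scans))

  target <- build_target(scans, policy = config$target_policy,
                         sigma_um = config$fovea_sigma_um)
  say("stage target: %s, fovea (%d, %d)", target$source,
      target$fovea_position[1], target$fovea_position[2])

  registered <- lapply(scans, function(s)
    register_scan(s$maps, s$boundaries, target, sigma_um = config$fovea_sigma_um,
                  rescale_thickness = config$rescale_thickness)$maps)
  say("stage register: %d scans registered", length(registered))

  fmask <- fovea_exclusion_mask(target, config$fovea_exclusion_radius_um)
  groups <- unique(scan_meta$group)
  others <- setdiff(groups, config$reference_group)
  if (!config$reference_group %in% groups)
    stop("stage stacks: reference group ", config$reference_group,
         " absent from the covariate table")

  stack_for <- function(layer, keep) {
    build_group_stack(lapply(which(keep), function(i)
      registered[[i]][[layer]]), cov,
      eye_policy = config$eye_policy, eyes = scan_meta$eye[keep])
  }

  spec <- glm_spec(contrast = "two-group-t", covariates = config$covariates,
                   alpha = config$alpha,
                   min_cluster_voxels = config$min_cluster_voxels,
                   connectivity = config$connectivity,
                   reference_group = config$reference_group)
  results <- list()
  for (layer in config$layers) {
    for (g in others) {
      keep <- scan_meta$group %in% c(config$reference_group, g)
      ls <- stack_for(layer, keep)
      rs <- if ("retina_voxel" %in% config$covariates)
        stack_for("Retina", keep) else NULL
      sm <- voxelwise_glm(ls, rs, spec, mask = fmask)
      keep_p <- scan_meta$group == g
      keep_h <- scan_meta$group == config$reference_group
      pct <- percentage_change_map(stack_for(layer, keep_p),
                                   stack_for(layer, keep_h))
      tag <- sprintf("%s_%s_vs_%s", layer, g, config$reference_group)
      write_matrix_tsv(sm$diff, file.path(out, paste0(tag, "_diff.tsv")))
      write_matrix_tsv(pct, file.path(out, paste0(tag, "_pct.tsv")))
      write_matrix_tsv(sm$p, file.path(out, paste0(tag, "_p.tsv")))
      write_matrix_tsv(sm$clusters * 1,
                       file.path(out, paste0(tag, "_clusters.tsv")))
      render_overlay(sm, sm$diff, color_range = config$color_range_um,
                     file = file.path(out, paste0(tag, "_overlay.png")),
                     label = "difference (um)")
      results[[tag]] <- list(
        layer = layer, group = g, n_significant = sum(sm$sig),
        n_clusters = nrow(sm$cluster_table),
        q_threshold = sm$q_threshold,
        clusters = sm$cluster_table)
      say("stage voxstats %s: %d significant voxels in %d cluster(s)",
          tag, sum(sm$sig), nrow(sm$cluster_table))
    }
  }

  manifest <- list(
    package = "octvbm",
    version = as.character(utils::packageVersion("octvbm")),
    config = unclass(config),
    n_scans = length(scans),
    target = list(source = target$source,
                  fovea = target$fovea_position,
                  n_rows = target$n_rows, n_cols = target$n_cols),
    comparisons = results)
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  writeLines(log_lines, file.path(out, "run.log"))
  invisible(manifest)
}

write_matrix_tsv <- function(m, path) {
  txt <- apply(m, 1L, function(r)
    paste(ifelse(is.na(r), "NA", sprintf("%.17g", r)), collapse = "\t"))
  writeLines(txt, path)
}

#' Write a synthetic preset dataset
#'
#' Three ready-made validation scenarios in the portable formats:
#' `"null"` (two groups, no effect), `"atrophy-disc"` (a -5 um GCIPL disc in
#' the patient group), `"retest"` (repeated scans of healthy subjects).
#'
#' @param preset scenario name
#' @param out_dir output directory
#' @param seed integer seed
#' @param n subjects per group (or retest subjects)
#' @param geometry grid for the phantom (default 25 x 128 for compact files)
#' @return `out_dir`, invisibly
#' @export
simulate_preset <- function(preset = c("null", "atrophy-disc", "retest"),
                            out_dir, seed = 1L, n = 15L,
                            geometry = oct_geometry(n_ascans = 128L)) {
  preset <- match.arg(preset)
  tpl <- make_template(template_spec(geometry = geometry))
  if (preset == "retest") {
    stk <- make_retest(tpl, n_subjects = n, seed = seed)
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (i in seq_len(stk$n_subjects))
      for (j in seq_len(stk$n_sessions))
        write_thickness_map(
          thickness_map(stk$data[i, j, , ], stk$layer, "L", geometry,
                        registered = TRUE,
                        subject_id = sprintf("S%03d", i),
                        session_id = sprintf("visit%d", j)),
          file.path(out_dir, sprintf("S%03d_s%d_%s.tsv", i, j, stk$layer)))
    jsonlite::write_json(attr(stk, "ground_truth"),
                         file.path(out_dir, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA)
    return(invisible(out_dir))
  }
  effects <- if (preset == "atrophy-disc")
    list(effect_spec("GCIPL", -5, "disc",
                     center = tpl$fovea_center + c(0, round(geometry$n_ascans / 4)),
                     radius_vox = 8))
  else list()
  cohort <- make_cohort(tpl, groups = list(
    list(label = "HC", n = n, effects = list()),
    list(label = "RMS", n = n, effects = effects)), seed = seed)
  write_cohort(cohort, out_dir)
  invisible(out_dir)
}
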