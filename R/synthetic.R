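#' Specification of the synthetic macular phantom
#'
#' Parameterizes a smooth four-layer macular phantom: a foveal pit (the
#' retinal thickness minimum, anchored at `fovea_center`), RNFL increasing
#' toward the optic-nerve-head side (left, in left-normalized orientation),
#' a perifoveal GCIPL annulus, and a low-amplitude seeded texture field
#' (suppressed inside the pit so the minimum stays put). Defaults emulate
#' the acquisition protocol of 25 B-scans x 1024 A-scans over 20 x 20
#' degrees; measurement noise defaults to 1.5 um per layer, inside the
#' reported test-retest envelope (within-subject SD below 3 um).
#'
#' @param geometry an [oct_geometry()]
#' @param fovea_center integer `c(row, col)`; default the grid centre
#' @param pit_depth_um total central retinal thinning (um)
#' @param pit_radius_um pit radius (um); the pit profile is Gaussian with
#'   sigma = `pit_radius_um / 2`
#' @param baselines named layer baselines (um): `RNFL`, `GCIPL`, `INL`,
#'   `outer` (everything from INL/OPL to BM)
#' @param gcipl_annulus_um perifoveal GCIPL bump amplitude (um) at radius
#'   `annulus_radius_um`
#' @param annulus_radius_um,annulus_sigma_um annulus position / width (um)
#' @param rnfl_onh_gradient RNFL increase toward the ONH side (um per mm)
#' @param noise_sd_um per-layer measurement noise SD (um)
#' @param texture_amp_um amplitude of the seeded smooth texture field (um)
#' @param seed integer seed for the texture field
#' @return an object of class `template_spec`
#' @export
template_spec <- function(geometry = oct_geometry(), fovea_center = NULL,
                          pit_depth_um = 120, pit_radius_um = 900,
                          baselines = c(RNFL = 28, GCIPL = 70, INL = 36,
                                        outer = 190),
                          gcipl_annulus_um = 25, annulus_radius_um = 1500,
                          annulus_sigma_um = 700, rnfl_onh_gradient = 6,
                          noise_sd_um = 1.5, texture_amp_um = 0.2,
                          seed = 1L) {
  if (is.null(fovea_center))
    fovea_center <- c(round((geometry$n_bscans + 1) / 2),
                      round((geometry$n_ascans + 1) / 2))
  if (noise_sd_um < 0) stop("spec error: noise_sd_um must be >= 0")
  if (pit_depth_um < 0 || pit_radius_um <= 0)
    stop("spec error: pit parameters must be non-negative / positive")
  if (!all(c("RNFL", "GCIPL", "INL", "outer") %in% names(baselines)))
    stop("spec error: baselines must name RNFL, GCIPL, INL, outer")
  structure(list(geometry = geometry,
                 fovea_center = as.integer(round(fovea_center)),
                 pit_depth_um = pit_depth_um, pit_radius_um = pit_radius_um,
                 baselines = baselines, gcipl_annulus_um = gcipl_annulus_um,
                 annulus_radius_um = annulus_radius_um,
                 annulus_sigma_um = annulus_sigma_um,
                 rnfl_onh_gradient = rnfl_onh_gradient,
                 noise_sd_um = noise_sd_um,
                 texture_amp_um = texture_amp_um, seed = as.integer(seed)),
            class = "template_spec")
}

#' Build the noise-free phantom template
#'
#' Deterministic (seeded) smooth component maps plus a boundary set whose
#' surface depths are consistent with the thicknesses. The Retina map is the
#' exact sum of the RNFL, GCIPL, INL and outer components, so the
#' component-vs-total invariant holds by construction, and the pit produces
#' a unique retinal minimum at `fovea_center`.
#'
#' @param spec a [template_spec()]
#' @return list: `maps` (four left-normalized [thickness_map()]s),
#'   `boundaries` ([boundary_set()]), `components` (RNFL/GCIPL/INL/outer
#'   matrices), `fovea_center`, `spec`
#' @export
make_template <- function(spec = template_spec()) {
  stopifnot(inherits(spec, "template_spec"))
  geom <- spec$geometry
  fc <- spec$fovea_center
  d <- grid_distance_um(geom, fc[1], fc[2])
  sigma_p <- spec$pit_radius_um / 2
  g_sup <- exp(-d^2 / (2 * sigma_p^2))        # 1 at the fovea, -> 0 outside
  ann <- exp(-(d - spec$annulus_radius_um)^2 / (2 * spec$annulus_sigma_um^2))
  # RNFL gradient toward the ONH side (left = column 1)
  x_um <- (seq_len(geom$n_ascans) - 1) * col_spacing_um(geom)
  width_um <- (geom$n_ascans - 1) * col_spacing_um(geom)
  grad <- matrix((width_um - x_um) / 1000 * spec$rnfl_onh_gradient,
                 geom$n_bscans, geom$n_ascans, byrow = TRUE)
  b <- spec$baselines
  rnfl_flat <- b[["RNFL"]] + grad
  # the whole foveal structure (central suppression and perifoveal annuli)
  # scales with the requested pit depth, so pit_depth_um = 0 yields flat
  # layers up to the RNFL gradient
  inner_flat <- rnfl_flat[fc[1], fc[2]] + b[["GCIPL"]] + b[["INL"]]
  pit_frac <- min(1, spec$pit_depth_um / inner_flat)
  gcipl_flat <- b[["GCIPL"]] + spec$gcipl_annulus_um * ann * pit_frac
  inl_flat <- b[["INL"]] + 0.3 * spec$gcipl_annulus_um * ann * pit_frac
  inner_at_fovea <- rnfl_flat[fc[1], fc[2]] + gcipl_flat[fc[1], fc[2]] +
    inl_flat[fc[1], fc[2]]
  rem <- max(0, spec$pit_depth_um - pit_frac * inner_at_fovea)
  supp <- 1 - pit_frac * g_sup
  rnfl <- rnfl_flat * supp
  gcipl <- gcipl_flat * supp
  inl <- inl_flat * supp
  outer <- matrix(b[["outer"]], geom$n_bscans, geom$n_ascans) - rem * g_sup
  if (spec$texture_amp_um > 0) {
    set.seed(spec$seed)
    tex <- gaussian_smooth_na(
      matrix(stats::rnorm(geom$n_bscans * geom$n_ascans),
             geom$n_bscans, geom$n_ascans), 2)
    tex <- tex / stats::sd(tex) * spec$texture_amp_um
    outer <- outer + tex * (1 - g_sup)   # damped in the pit
  }
  comps <- list(RNFL = rnfl, GCIPL = gcipl, INL = inl, outer = outer)
  build_phantom_scan(comps, geom, g_sup, fovea = fc, spec = spec)
}

# assemble maps + boundaries from component thickness matrices
build_phantom_scan <- function(comps, geom, g_sup = NULL, fovea = NULL,
                               spec = NULL, subject_id = NA_character_,
                               session_id = NA_character_) {
  comps <- lapply(comps, function(m) pmax(m, 0))
  retina <- comps$RNFL + comps$GCIPL + comps$INL + comps$outer
  ilm <- 120 + if (is.null(g_sup)) 0 else 15 * g_sup
  if (length(ilm) == 1L) ilm <- matrix(ilm, nrow(retina), ncol(retina))
  surfaces <- list(
    "ILM" = ilm,
    "RNFL/GCL" = ilm + comps$RNFL,
    "IPL/INL" = ilm + comps$RNFL + comps$GCIPL,
    "INL/OPL" = ilm + comps$RNFL + comps$GCIPL + comps$INL,
    "BM" = ilm + retina)
  vals <- list(RNFL = comps$RNFL, GCIPL = comps$GCIPL, INL = comps$INL,
               Retina = retina)
  maps <- lapply(names(vals), function(layer)
    thickness_map(vals[[layer]], layer, "L", geom, subject_id = subject_id,
                  session_id = session_id))
  names(maps) <- names(vals)
  list(maps = maps,
       boundaries = boundary_set(surfaces, geom, "L"),
       components = comps, fovea_center = fovea, spec = spec)
}

#' Ground-truth effect on a synthetic cohort
#'
#' A signed thickness change applied inside a spatial footprint of one layer
#' of every subject of a group. Disc footprints may be given in index-space
#' voxels (`radius_vox`, a circle in grid coordinates) or micrometres
#' (`radius_um`, physical distance).
#'
#' @param layer affected layer (`RNFL`, `GCIPL`, `INL`)
#' @param delta_um signed thickness change (um)
#' @param shape `"disc"`, `"annulus"`, or `"sector"`
#' @param center `c(row, col)`; default the template fovea
#' @param radius_vox,radius_um disc radius (one of the two)
#' @param r_in_um,r_out_um annulus radii (um)
#' @param angle_deg sector bounds `c(lo, hi)` degrees, 0 = temporal (right)
#' @return an object of class `effect_spec`
#' @export
effect_spec <- function(layer, delta_um, shape = c("disc", "annulus",
                                                   "sector"),
                        center = NULL, radius_vox = NULL, radius_um = NULL,
                        r_in_um = NULL, r_out_um = NULL, angle_deg = NULL) {
  shape <- match.arg(shape)
  if (!is.finite(delta_um)) stop("spec error: delta must be finite")
  structure(list(layer = match.arg(layer, c("RNFL", "GCIPL", "INL")),
                 delta_um = delta_um, shape = shape, center = center,
                 radius_vox = radius_vox, radius_um = radius_um,
                 r_in_um = r_in_um, r_out_um = r_out_um,
                 angle_deg = angle_deg),
            class = "effect_spec")
}

#' Footprint mask of an effect
#'
#' @param effect an [effect_spec()]
#' @param geom an [oct_geometry()]
#' @param default_center fallback centre `c(row, col)`
#' @return logical matrix of the footprint
#' @export
effect_mask <- function(effect, geom, default_center) {
  ctr <- effect$center %||% default_center
  if (effect$shape == "disc") {
    if (!is.null(effect$radius_vox)) {
      dr <- outer((seq_len(geom$n_bscans) - ctr[1])^2,
                  (seq_len(geom$n_ascans) - ctr[2])^2, `+`)
      return(sqrt(dr) <= effect$radius_vox)
    }
    return(grid_distance_um(geom, ctr[1], ctr[2]) <= effect$radius_um)
  }
  if (effect$shape == "annulus") {
    d <- grid_distance_um(geom, ctr[1], ctr[2])
    return(d >= effect$r_in_um & d <= effect$r_out_um)
  }
  off <- grid_offsets_um(geom, ctr[1], ctr[2])
  ang <- (atan2(outer(-off$dy, rep(1, geom$n_ascans)),
                outer(rep(1, geom$n_bscans), off$dx)) * 180 / pi) %% 360
  in_arc(ang, effect$angle_deg[1], effect$angle_deg[2])
}

#' Draw one synthetic subject from the template
#'
#' The template is shifted by an integer fovea jitter (given exactly or
#' drawn uniformly within `jitter_max`), optionally scaled by a per-subject
#' multiplicative factor (inter-subject thickness variation), effect deltas
#' are added inside their footprints, and independent Gaussian measurement
#' noise is added per component layer. The Retina map is recomputed as the
#' component sum, so boundary order and the component-vs-total invariant
#' hold after noise. Uses the current RNG state (seed the caller).
#'
#' @param template a [make_template()] result
#' @param noise_sd_um per-component noise SD (um)
#' @param jitter exact integer `c(drow, dcol)`, or `NULL` to draw one
#' @param jitter_max `c(rows, cols)` maximum absolute jitter when drawing
#' @param subject_scale_sd SD of the multiplicative subject scale
#' @param effects list of [effect_spec()]s applied to this subject
#' @param subject_id,session_id identifiers
#' @return list: `maps`, `boundaries`, `jitter` (ground truth), `scale`
#' @export
sample_subject <- function(template, noise_sd_um = 1.5, jitter = NULL,
                           jitter_max = c(1, 3), subject_scale_sd = 0,
                           effects = list(), subject_id = NA_character_,
                           session_id = NA_character_) {
  geom <- template$maps$Retina$geometry
  if (is.null(jitter))
    jitter <- c(sample(-jitter_max[1]:jitter_max[1], 1),
                sample(-jitter_max[2]:jitter_max[2], 1))
  jitter <- as.integer(jitter)
  fc <- template$fovea_center
  margin_r <- min(fc[1] - 1, geom$n_bscans - fc[1])
  margin_c <- min(fc[2] - 1, geom$n_ascans - fc[2])
  if (abs(jitter[1]) > margin_r || abs(jitter[2]) > margin_c)
    stop("jitter out of range: fovea would leave the grid")
  s <- 1 + (if (subject_scale_sd > 0) stats::rnorm(1, 0, subject_scale_sd)
            else 0)
  comps <- lapply(template$components, function(m) m * s)
  for (ef in effects) {
    msk <- effect_mask(ef, geom, template$fovea_center)
    comps[[ef$layer]][msk] <- comps[[ef$layer]][msk] + ef$delta_um
  }
  if (noise_sd_um > 0)
    comps <- lapply(comps, function(m)
      m + matrix(stats::rnorm(length(m), 0, noise_sd_um), nrow(m)))
  comps <- lapply(comps, function(m) translate_matrix(pmax(m, 0), jitter))
  g_sup <- translate_matrix(
    exp(-grid_distance_um(geom, fc[1], fc[2])^2 /
          (2 * (template$spec$pit_radius_um / 2)^2)), jitter)
  scan <- build_phantom_scan_shifted(comps, geom, g_sup, subject_id,
                                     session_id)
  scan$jitter <- jitter
  scan$scale <- s
  scan$fovea_center <- fc + jitter
  scan
}

# like build_phantom_scan but tolerates NA borders from the jitter shift
build_phantom_scan_shifted <- function(comps, geom, g_sup, subject_id,
                                       session_id) {
  retina <- comps$RNFL + comps$GCIPL + comps$INL + comps$outer
  ilm <- 120 + 15 * g_sup
  surfaces <- list(
    "ILM" = ilm,
    "RNFL/GCL" = ilm + comps$RNFL,
    "IPL/INL" = ilm + comps$RNFL + comps$GCIPL,
    "INL/OPL" = ilm + comps$RNFL + comps$GCIPL + comps$INL,
    "BM" = ilm + retina)
  vals <- list(RNFL = comps$RNFL, GCIPL = comps$GCIPL, INL = comps$INL,
               Retina = retina)
  maps <- lapply(names(vals), function(layer)
    thickness_map(vals[[layer]], layer, "L", geom, subject_id = subject_id,
                  session_id = session_id))
  names(maps) <- names(vals)
  list(maps = maps, boundaries = boundary_set(surfaces, geom, "L"),
       components = comps)
}

#' Generate a multi-group synthetic cohort with known ground truth
#'
#' Per group, `n` subjects are drawn from the template with that group's
#' effects; covariates are drawn from configured distributions. All
#' randomness flows from `seed`, so the cohort is bit-reproducible. Ground
#' truth (jitters, scales, effect footprints) is returned alongside the
#' scans.
#'
#' @param template a [make_template()] result
#' @param groups list of `list(label =, n =, effects = list(...))`
#' @param noise_sd_um,jitter_max,subject_scale_sd see [sample_subject()]
#' @param age_mean,age_sd age distribution (years), truncated to [18, 70]
#' @param seed integer seed
#' @return list: `subjects` (list of scans), `covariates` (data.frame),
#'   `ground_truth` (jitters, scales, effect masks per group)
#' @export
make_cohort <- function(template, groups, noise_sd_um = 1.5,
                        jitter_max = c(1, 3), subject_scale_sd = 0.03,
                        age_mean = 35, age_sd = 10, seed = 1L) {
  labels <- vapply(groups, `[[`, "", "label")
  if (anyDuplicated(labels)) stop("spec error: group labels must be unique")
  set.seed(seed)
  geom <- template$maps$Retina$geometry
  subjects <- list()
  cov <- NULL
  gt_masks <- list()
  i <- 0L
  for (g in groups) {
    masks <- lapply(g$effects %||% list(), effect_mask, geom = geom,
                    default_center = template$fovea_center)
    gt_masks[[g$label]] <- masks
    for (k in seq_len(g$n)) {
      i <- i + 1L
      id <- sprintf("S%03d", i)
      subj <- sample_subject(template, noise_sd_um = noise_sd_um,
                             jitter_max = jitter_max,
                             subject_scale_sd = subject_scale_sd,
                             effects = g$effects %||% list(),
                             subject_id = id)
      subj$group <- g$label
      subjects[[i]] <- subj
      age <- min(70, max(18, stats::rnorm(1, age_mean, age_sd)))
      is_hc <- identical(g$label, "HC")
      cov <- rbind(cov, data.frame(
        subject_id = id, eye = "OS", group = g$label, age = age,
        sex = sample(c("M", "F"), 1),
        edss = if (is_hc) 0 else round(stats::runif(1, 0, 6) * 2) / 2,
        disease_duration = if (is_hc) 0 else stats::rexp(1, 1 / 4)))
    }
  }
  list(subjects = subjects, covariates = cov,
       ground_truth = list(
         jitters = t(vapply(subjects, `[[`, integer(2), "jitter")),
         scales = vapply(subjects, `[[`, numeric(1), "scale"),
         effect_masks = gt_masks))
}

#' Generate a synthetic test-retest dataset
#'
#' Per subject, one latent map (template plus an independent Gaussian
#' between-subject deviation per voxel) is "measured" `n_sessions` times
#' with independent within-session noise. The ground-truth voxel ICC(2,1)
#' is `between_sd^2 / (between_sd^2 + within_sd^2)` and the ground-truth Sw
#' is `within_sd`. Maps are generated directly in target space (no jitter).
#'
#' @param template a [make_template()] result
#' @param n_subjects number of subjects
#' @param between_sd_um between-subject SD per voxel (um)
#' @param within_sd_um within-subject (measurement) SD per voxel (um)
#' @param layer which layer to generate
#' @param n_sessions sessions per subject (default 2)
#' @param seed integer seed
#' @return a [retest_stack()] with attribute `ground_truth`
#' @export
make_retest <- function(template, n_subjects = 10, between_sd_um = 2.5,
                        within_sd_um = 1.5, layer = "GCIPL",
                        n_sessions = 2L, seed = 1L) {
  if (n_subjects < 2) stop("need >= 2 subjects")
  set.seed(seed)
  base <- template$maps[[layer]]$values
  R <- nrow(base); C <- ncol(base)
  data <- array(NA_real_, c(n_subjects, n_sessions, R, C))
  for (i in seq_len(n_subjects)) {
    latent <- base + matrix(stats::rnorm(R * C, 0, between_sd_um), R, C)
    for (j in seq_len(n_sessions))
      data[i, j, , ] <- latent + matrix(stats::rnorm(R * C, 0, within_sd_um),
                                        R, C)
  }
  stk <- retest_stack(data, layer = layer, same_day = TRUE)
  attr(stk, "ground_truth") <- list(
    between_sd_um = between_sd_um, within_sd_um = within_sd_um,
    icc = between_sd_um^2 / (between_sd_um^2 + within_sd_um^2))
  stk
}
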