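#' Stack registered maps of one layer into a group array
#'
#' Joins registered maps with a covariate table into a `subject x row x col`
#' array ready for voxel-wise statistics. With
#' `eye_policy = "average-within-subject"` the two eye maps of a subject are
#' voxel-wise averaged (a voxel valid in only one eye keeps that eye's
#' value); with `"eye-level"` every eye is a row of the stack.
#'
#' @param maps list of registered [thickness_map()]s, one layer, each with a
#'   `subject_id`
#' @param cov covariate `data.frame` (see [read_covariates()]); one row per
#'   subject/eye, matched by `subject_id` (and `eye` for eye-level stacks)
#' @param eye_policy `"average-within-subject"` or `"eye-level"`
#' @param eyes character vector of eye labels parallel to `maps` (required
#'   for averaging when subjects contribute two maps)
#' @return an object of class `group_stack`: `layer`, `data` (3D array),
#'   `covariates` (rows parallel to the stack), `validity` (per-voxel count)
#' @export
build_group_stack <- function(maps, cov,
                              eye_policy = c("average-within-subject",
                                             "eye-level"),
                              eyes = NULL) {
  eye_policy <- match.arg(eye_policy)
  layer <- unique(vapply(maps, `[[`, "", "layer"))
  if (length(layer) != 1L)
    stop("stack error: maps mix layers: ", paste(layer, collapse = ", "))
  if (!all(vapply(maps, `[[`, TRUE, "registered")))
    stop("stack error: all maps must be registered to the same target")
  dims <- unique(t(vapply(maps, function(m) dim(m$values), integer(2L))))
  if (nrow(dims) != 1L)
    stop("stack error: maps are on different grids")
  ids <- vapply(maps, `[[`, "", "subject_id")
  if (eye_policy == "eye-level") {
    units <- seq_along(maps)
    unit_maps <- lapply(units, function(i) maps[[i]]$values)
    unit_ids <- ids
    unit_eyes <- eyes %||% rep(NA_character_, length(maps))
  } else {
    unit_ids <- unique(ids)
    unit_maps <- lapply(unit_ids, function(id) {
      vs <- lapply(maps[ids == id], `[[`, "values")
      if (length(vs) == 1L) return(vs[[1]])
      stack <- simplify2array(vs)            # row x col x eye
      out <- apply(stack, c(1, 2), function(x)
        if (all(is.na(x))) NA_real_ else mean(x, na.rm = TRUE))
      out
    })
    unit_eyes <- rep(NA_character_, length(unit_ids))
  }
  n <- length(unit_maps)
  data <- array(NA_real_, c(n, dims[1, 1], dims[1, 2]))
  for (i in seq_len(n)) data[i, , ] <- unit_maps[[i]]
  # join covariates by subject id (first matching row per subject when
  # averaging eyes; per-eye row for eye-level)
  pick <- integer(n)
  for (i in seq_len(n)) {
    rows <- which(cov$subject_id == unit_ids[i])
    if (eye_policy == "eye-level" && !is.na(unit_eyes[i]) && "eye" %in% names(cov))
      rows <- rows[cov$eye[rows] == unit_eyes[i]]
    if (!length(rows))
      stop("stack error: no covariate row for subject ", unit_ids[i])
    pick[i] <- rows[1]
  }
  structure(list(layer = layer, data = data,
                 covariates = cov[pick, , drop = FALSE],
                 validity = apply(!is.na(data), c(2, 3), sum)),
            class = "group_stack")
}

#' @export
print.group_stack <- function(x, ...) {
  cat(sprintf("%s group stack: %d maps on %d x %d grid (groups: %s)\n",
              x$layer, dim(x$data)[1], dim(x$data)[2], dim(x$data)[3],
              paste(unique(x$covariates$group), collapse = ", ")))
  invisible(x)
}

# Per-voxel mean over subjects, NA where no subject is valid.
stack_mean <- function(stack) {
  m <- apply(stack$data, c(2, 3), function(x)
    if (all(is.na(x))) NA_real_ else mean(x, na.rm = TRUE))
  m
}

#' Voxel-wise percentage-change map
#'
#' `change(%) = (mean_patient - mean_HC) / mean_HC * 100` at every voxel;
#' voxels where the healthy-control mean is zero (or no valid subjects) are
#' invalid.
#'
#' @param patient_stack,hc_stack [build_group_stack()] results, same layer
#'   and grid
#' @return matrix of percentage change
#' @export
percentage_change_map <- function(patient_stack, hc_stack) {
  if (patient_stack$layer != hc_stack$layer)
    stop("stack error: layers differ")
  if (!identical(dim(patient_stack$data)[2:3], dim(hc_stack$data)[2:3]))
    stop("stack error: grids differ")
  mp <- stack_mean(patient_stack)
  mh <- stack_mean(hc_stack)
  if (all(is.na(mh) | mh == 0))
    stop("degenerate error: healthy-control mean map is all zero/invalid")
  out <- (mp - mh) / mh * 100
  out[!is.na(mh) & mh == 0] <- NA
  out
}

#' Central fovea exclusion mask
#'
#' Voxels whose centre lies within `radius_um` of the target fovea are
#' masked out of voxel-wise statistics (default radius 500 um, roughly the
#' central ETDRS subfield). Radius 0 masks nothing.
#'
#' @param target a [target_grid()] with geometry
#' @param radius_um exclusion radius in micrometres
#' @return object of class `fovea_mask`: logical `mask` (TRUE = excluded)
#'   and `radius_um`
#' @export
fovea_exclusion_mask <- function(target, radius_um = 500) {
  stopifnot(inherits(target, "target_grid"), radius_um >= 0)
  geom <- target$geometry
  if (is.null(geom)) stop("geometry error: target grid lacks geometry")
  d <- grid_distance_um(geom, target$fovea_position[1],
                        target$fovea_position[2])
  mask <- if (radius_um == 0) d < 0 else d <= radius_um
  structure(list(mask = mask, radius_um = radius_um),
            class = "fovea_mask")
}

#' Macular layer volume
#'
#' Integrates a thickness map over a region: `sum(thickness * voxel area)`
#' in mm^3 over valid voxels. `region = "full-field"` uses the whole grid;
#' `region = list(type = "circle", diameter_mm = d)` restricts to a disc
#' centred on `center` (default: grid centre).
#'
#' @param map a [thickness_map()]
#' @param region `"full-field"` or a circle spec (see details)
#' @param center integer `c(row, col)` circle centre
#' @return volume in mm^3
#' @export
macular_layer_volume <- function(map, region = "full-field", center = NULL) {
  stopifnot(inherits(map, "thickness_map"))
  geom <- map$geometry
  sel <- !is.na(map$values)
  if (!identical(region, "full-field")) {
    if (!is.list(region) || !identical(region$type, "circle"))
      stop("region must be \"full-field\" or list(type=\"circle\", diameter_mm=...)")
    if (is.null(center))
      center <- c((geom$n_bscans + 1) / 2, (geom$n_ascans + 1) / 2)
    d <- grid_distance_um(geom, center[1], center[2])
    sel <- sel & (d <= region$diameter_mm * 1000 / 2)
  }
  if (!any(sel)) stop("empty-region error: no valid voxels in region")
  sum(map$values[sel]) / 1000 * voxel_area_mm2(geom)
}

# angle membership on a circular arc [lo, hi) in degrees, wrapping at 360
in_arc <- function(angle, lo, hi) {
  angle <- angle %% 360; lo <- lo %% 360; hi <- hi %% 360
  if (lo <= hi) angle >= lo & angle < hi else angle >= lo | angle < hi
}

#' Peripapillary ring sector means
#'
#' Mean thickness of the global ring, the temporal quadrant and the
#' papillomacular-bundle arc of a peripapillary RNFL profile. Angles follow
#' the profile's declared convention in the left-normalized orientation with
#' 0 degrees at the temporal ring position; sector bounds are configurable,
#' with defaults temporal = [315, 45) and PMB = [324, 36).
#'
#' @param ring a [ring_profile()]
#' @param temporal_deg,pmb_deg numeric `c(lo, hi)` arc bounds in degrees
#' @return named list: `global`, `temporal`, `PMB` mean thickness (um)
#' @export
peripapillary_sectors <- function(ring, temporal_deg = c(315, 45),
                                  pmb_deg = c(324, 36)) {
  stopifnot(inherits(ring, "ring_profile"))
  step <- 360 / ring$n_samples
  arc_width <- min((temporal_deg[2] - temporal_deg[1]) %% 360,
                   (pmb_deg[2] - pmb_deg[1]) %% 360)
  if (step > arc_width)
    stop("resolution error: profile too coarse for the requested sectors")
  ang <- (ring$start_angle_deg +
            ring$direction * (seq_len(ring$n_samples) - 1L) * step) %% 360
  list(global = mean(ring$values),
       temporal = mean(ring$values[in_arc(ang, temporal_deg[1], temporal_deg[2])]),
       PMB = mean(ring$values[in_arc(ang, pmb_deg[1], pmb_deg[2])]))
}
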