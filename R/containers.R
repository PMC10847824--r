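#' En-face layer thickness map
#'
#' A 2D grid of layer thickness values in micrometres on the acquisition grid
#' (rows = B-scans, row 1 most superior; columns = A-scan positions). Invalid
#' cells (failed segmentation, voxels translated in from outside the field)
#' are `NA`, never zero: zeros would bias group statistics.
#'
#' @param values numeric matrix of thickness in micrometres; `NA` = invalid
#' @param layer one of `"RNFL"`, `"GCIPL"`, `"INL"`, `"Retina"`
#' @param laterality `"OD"`, `"OS"`, or `"L"` (left-normalized)
#' @param geometry an [oct_geometry()] consistent with `dim(values)`
#' @param registered logical flag: is the map in target space?
#' @param subject_id,session_id optional identifiers
#' @return an object of class `thickness_map`
#' @export
thickness_map <- function(values, layer, laterality, geometry,
                          registered = FALSE, subject_id = NA_character_,
                          session_id = NA_character_) {
  values <- as.matrix(values)
  layer <- match.arg(layer, c("RNFL", "GCIPL", "INL", "Retina"))
  laterality <- match.arg(laterality, c("OD", "OS", "L"))
  if (!identical(dim(values), c(geometry$n_bscans, geometry$n_ascans)))
    stop(sprintf("geometry error: map is %d x %d but geometry declares %d x %d",
                 nrow(values), ncol(values),
                 geometry$n_bscans, geometry$n_ascans))
  if (any(values < 0, na.rm = TRUE))
    stop("thickness values must be >= 0 or NA")
  structure(list(values = values, layer = layer, laterality = laterality,
                 geometry = geometry, registered = isTRUE(registered),
                 subject_id = subject_id, session_id = session_id),
            class = "thickness_map")
}

#' Validity mask of a thickness map
#'
#' @param map a [thickness_map()]
#' @return logical matrix, `TRUE` where the cell holds a valid measurement
#' @export
validity_mask <- function(map) {
  stopifnot(inherits(map, "thickness_map"))
  !is.na(map$values)
}

#' @export
print.thickness_map <- function(x, ...) {
  cat(sprintf("%s thickness map (%s%s): %d x %d, %d valid voxels, mean %.1f um\n",
              x$layer, x$laterality, if (x$registered) ", registered" else "",
              nrow(x$values), ncol(x$values), sum(!is.na(x$values)),
              mean(x$values, na.rm = TRUE)))
  invisible(x)
}

# Canonical surface order, inner to outer.
SURFACES <- c("ILM", "RNFL/GCL", "IPL/INL", "INL/OPL", "BM")

#' Segmented retinal boundary surfaces for one scan
#'
#' Depth positions (micrometres from the top of the volume) of the five
#' segmented surfaces at every A-line. At every valid A-line the anatomical
#' order ILM <= RNFL/GCL <= IPL/INL <= INL/OPL <= BM must hold; A-lines where
#' segmentation failed are `NA` in every surface.
#'
#' @param surfaces named list of matrices, names `ILM`, `RNFL/GCL`,
#'   `IPL/INL`, `INL/OPL`, `BM`, each `n_bscans x n_ascans`, depth in um
#' @param geometry an [oct_geometry()]
#' @param laterality `"OD"`, `"OS"`, or `"L"`
#' @return an object of class `boundary_set`
#' @export
boundary_set <- function(surfaces, geometry, laterality) {
  laterality <- match.arg(laterality, c("OD", "OS", "L"))
  if (!all(SURFACES %in% names(surfaces)))
    stop("boundary_set needs surfaces: ", paste(SURFACES, collapse = ", "))
  surfaces <- lapply(surfaces[SURFACES], as.matrix)
  dims <- c(geometry$n_bscans, geometry$n_ascans)
  for (s in SURFACES)
    if (!identical(dim(surfaces[[s]]), dims))
      stop(sprintf("geometry error: surface %s is %d x %d, expected %d x %d",
                   s, nrow(surfaces[[s]]), ncol(surfaces[[s]]),
                   dims[1], dims[2]))
  valid <- Reduce(`&`, lapply(surfaces, function(m) !is.na(m)))
  for (i in seq_len(length(SURFACES) - 1L)) {
    lo <- surfaces[[SURFACES[i]]]; hi <- surfaces[[SURFACES[i + 1L]]]
    bad <- valid & (hi < lo - 1e-9)
    if (any(bad)) {
      idx <- which(bad, arr.ind = TRUE)
      stop(sprintf(
        "segmentation error: surface order %s > %s violated at %d A-line(s), first at (row %d, col %d)",
        SURFACES[i], SURFACES[i + 1L], nrow(idx), idx[1, 1], idx[1, 2]))
    }
  }
  structure(list(surfaces = surfaces, geometry = geometry,
                 laterality = laterality, valid = valid),
            class = "boundary_set")
}

#' Raw macular OCT volume
#'
#' @param intensity 3D numeric array, dimensions `bscan x depth x ascan`,
#'   arbitrary intensity units
#' @param geometry an [oct_geometry()] with matching B-/A-scan counts
#' @param laterality `"OD"`, `"OS"`, or `"L"`
#' @param subject_id,session_id identifiers
#' @return an object of class `oct_volume`
#' @export
oct_volume <- function(intensity, geometry, laterality,
                       subject_id = NA_character_, session_id = NA_character_) {
  laterality <- match.arg(laterality, c("OD", "OS", "L"))
  d <- dim(intensity)
  if (length(d) != 3L)
    stop("geometry error: intensity must be a 3D array (bscan x depth x ascan)")
  if (d[1] != geometry$n_bscans || d[3] != geometry$n_ascans)
    stop(sprintf("geometry error: volume is %d x %d x %d but geometry declares %d B-scans x %d A-scans",
                 d[1], d[2], d[3], geometry$n_bscans, geometry$n_ascans))
  structure(list(intensity = intensity, geometry = geometry,
                 laterality = laterality, subject_id = subject_id,
                 session_id = session_id),
            class = "oct_volume")
}

#' Peripapillary ring thickness profile
#'
#' A circular 1D thickness profile sampled on a ring around the optic nerve
#' head. The angle of sample `i` is `start_angle_deg + direction * (i-1) *
#' 360 / n`, in the left-normalized orientation; indexing wraps.
#'
#' @param values numeric vector of thickness (um), length >= 12
#' @param start_angle_deg angle of the first sample, degrees
#' @param direction `1` (counter-clockwise) or `-1` (clockwise)
#' @param diameter_deg ring diameter in degrees (default 12)
#' @return an object of class `ring_profile`
#' @export
ring_profile <- function(values, start_angle_deg = 0, direction = 1,
                         diameter_deg = 12) {
  values <- as.numeric(values)
  if (length(values) < 12L)
    stop("ring profile needs at least 12 samples")
  if (!direction %in% c(1, -1)) stop("direction must be 1 or -1")
  structure(list(values = values, n_samples = length(values),
                 start_angle_deg = start_angle_deg, direction = direction,
                 diameter_deg = diameter_deg),
            class = "ring_profile")
}

#' Common target space for registration
#'
#' The grid all scans are registered onto. Carries the target fovea position
#' and, when built from a reference scan or cohort template, the target ILM
#' and BM depth grids used to fit the per-A-line depth affines.
#'
#' @param n_rows,n_cols grid size
#' @param fovea_position integer `c(row, col)` of the target fovea
#' @param source `"designated-reference"` or `"cohort-mean-template"`
#' @param geometry an [oct_geometry()] for physical conversions
#' @param ilm,bm optional target ILM / BM depth grids (um)
#' @return an object of class `target_grid`
#' @export
target_grid <- function(n_rows, n_cols, fovea_position,
                        source = c("designated-reference",
                                   "cohort-mean-template"),
                        geometry = NULL, ilm = NULL, bm = NULL) {
  source <- match.arg(source)
  fovea_position <- as.integer(round(fovea_position))
  if (fovea_position[1] < 1L || fovea_position[1] > n_rows ||
      fovea_position[2] < 1L || fovea_position[2] > n_cols)
    stop("fovea_position outside the target grid")
  structure(list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
                 fovea_position = fovea_position, source = source,
                 geometry = geometry, ilm = ilm, bm = bm),
            class = "target_grid")
}

#' Read a covariate table
#'
#' CSV with one row per subject/eye. Required columns: `subject_id`, `eye`
#' (`OD`/`OS`), `group`. Optional: `age` (years), `sex` (`M`/`F`), `edss`,
#' `disease_duration` (years). Missing values must be written as empty cells
#' or `NA` (explicit), never as sentinel numbers.
#'
#' @param path CSV file path
#' @return a `data.frame`
#' @export
read_covariates <- function(path) {
  if (!file.exists(path)) stop("covariate file not found: ", path)
  cov <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = c("", "NA"))
  req <- c("subject_id", "eye", "group")
  miss <- setdiff(req, names(cov))
  if (length(miss))
    stop("metadata error: covariate table lacks column(s): ",
         paste(miss, collapse = ", "))
  key <- paste(cov$subject_id, cov$eye)
  if (anyDuplicated(key))
    stop("covariate table: subject ids must be unique per eye")
  cov
}
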