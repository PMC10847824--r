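#' Scan geometry of a macular OCT volume
#'
#' Describes the acquisition grid of a macular volume scan: number of B-scans
#' (grid rows, row 1 = most superior) and A-scans per B-scan (grid columns),
#' angular field of view, physical B-scan spacing, axial sampling, and the
#' degree-to-micrometre conversion used for physical distances.
#'
#' Defaults follow a common spectral-domain protocol: 25 B-scans of 1024
#' A-scans covering 20 x 20 degrees, 240 um between B-scans, 3.87 um axial
#' resolution. The degree-to-micrometre factor (default 288 um/deg) is only
#' used for reporting physical distances, areas and volumes.
#'
#' @param n_bscans number of B-scans (rows), >= 2
#' @param n_ascans number of A-scans per B-scan (columns), >= 2
#' @param field_deg field of view, c(horizontal, vertical) in degrees
#' @param bscan_spacing_um distance between adjacent B-scans, micrometres
#' @param axial_resolution_um axial (depth) sampling, micrometres per sample
#' @param um_per_degree conversion factor, micrometres per degree
#' @return an object of class `oct_geometry`
#' @export
oct_geometry <- function(n_bscans = 25L, n_ascans = 1024L,
                         field_deg = c(20, 20), bscan_spacing_um = 240,
                         axial_resolution_um = 3.87, um_per_degree = 288) {
  n_bscans <- as.integer(n_bscans)
  n_ascans <- as.integer(n_ascans)
  if (length(field_deg) == 1L) field_deg <- rep(field_deg, 2L)
  if (n_bscans < 2L || n_ascans < 2L)
    stop("geometry error: n_bscans and n_ascans must both be >= 2")
  if (any(field_deg <= 0) || bscan_spacing_um <= 0 ||
      axial_resolution_um <= 0 || um_per_degree <= 0)
    stop("geometry error: field, spacings and conversion must be positive")
  structure(list(n_bscans = n_bscans, n_ascans = n_ascans,
                 field_deg = as.numeric(field_deg),
                 bscan_spacing_um = as.numeric(bscan_spacing_um),
                 axial_resolution_um = as.numeric(axial_resolution_um),
                 um_per_degree = as.numeric(um_per_degree)),
            class = "oct_geometry")
}

#' @export
print.oct_geometry <- function(x, ...) {
  cat(sprintf("OCT geometry: %d B-scans x %d A-scans, %g x %g deg, %g um B-scan spacing\n",
              x$n_bscans, x$n_ascans, x$field_deg[1], x$field_deg[2],
              x$bscan_spacing_um))
  invisible(x)
}

# Physical column (A-scan) spacing in micrometres.
col_spacing_um <- function(geom) {
  geom$field_deg[1] * geom$um_per_degree / geom$n_ascans
}

# Physical row (B-scan) spacing in micrometres; the vertical field divided
# by the row count so that n_rows * row_spacing covers the stated field.
row_spacing_um <- function(geom) {
  geom$field_deg[2] * geom$um_per_degree / geom$n_bscans
}

# En-face voxel area in mm^2, respecting grid anisotropy.
voxel_area_mm2 <- function(geom) {
  (row_spacing_um(geom) / 1000) * (col_spacing_um(geom) / 1000)
}

# Physical (y, x) offsets in um of every grid cell from a reference (row, col).
grid_offsets_um <- function(geom, ref_row, ref_col) {
  dy <- (seq_len(geom$n_bscans) - ref_row) * row_spacing_um(geom)
  dx <- (seq_len(geom$n_ascans) - ref_col) * col_spacing_um(geom)
  list(dy = dy, dx = dx)
}

# Matrix of physical distances (um) from a reference grid point.
grid_distance_um <- function(geom, ref_row, ref_col) {
  off <- grid_offsets_um(geom, ref_row, ref_col)
  sqrt(outer(off$dy^2, off$dx^2, `+`))
}

geometry_to_list <- function(geom) unclass(geom)

geometry_from_list <- function(x) {
  oct_geometry(n_bscans = x$n_bscans, n_ascans = x$n_ascans,
               field_deg = unlist(x$field_deg),
               bscan_spacing_um = x$bscan_spacing_um,
               axial_resolution_um = x$axial_resolution_um,
               um_per_degree = x$um_per_degree)
}
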