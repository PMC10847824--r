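#' @importFrom jsonlite read_json write_json
NULL

sidecar_path <- function(path) paste0(tools::file_path_sans_ext(path), ".json")

map_sidecar <- function(map, extra = list()) {
  c(list(layer = map$layer, laterality = map$laterality,
         registered = map$registered, units = "um",
         subject_id = map$subject_id, session_id = map$session_id,
         row_convention = "row 1 = most superior B-scan",
         col_convention = "column = A-scan position",
         geometry = geometry_to_list(map$geometry)),
    extra)
}

read_sidecar <- function(path) {
  sc <- sidecar_path(path)
  if (!file.exists(sc))
    stop("metadata error: sidecar not found: ", sc)
  meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
  for (f in c("layer", "laterality", "geometry"))
    if (is.null(meta[[f]]))
      stop("metadata error: sidecar field missing: ", f)
  meta
}

#' Write a thickness map
#'
#' Three portable formats, each with a JSON sidecar (`<stem>.json`) carrying
#' layer, laterality, geometry and registration state:
#' \describe{
#'   \item{grid-tsv}{tab-separated full-precision text, `NA` for invalid
#'     cells; round-trips bit-exactly.}
#'   \item{nifti}{float64 NIfTI via \pkg{RNifti}; invalid cells stored as
#'     `NaN`; round-trips bit-exactly.}
#'   \item{float-tiff}{two-page 32-bit TIFF (values scaled into [0,1] with
#'     the scale in the sidecar, plus a validity page); lossless only to
#'     float32 precision.}
#' }
#'
#' @param map a [thickness_map()]
#' @param path output file path; the sidecar is written next to it
#' @param format `"grid-tsv"`, `"nifti"`, or `"float-tiff"`
#' @return `path`, invisibly
#' @export
write_thickness_map <- function(map, path,
                                format = c("grid-tsv", "nifti", "float-tiff")) {
  stopifnot(inherits(map, "thickness_map"))
  format <- match.arg(format)
  extra <- list(format = format)
  if (format == "grid-tsv") {
    txt <- apply(map$values, 1L, function(r)
      paste(ifelse(is.na(r), "NA", sprintf("%.17g", r)), collapse = "\t"))
    writeLines(txt, path)
  } else if (format == "nifti") {
    v <- map$values
    v[is.na(v)] <- NaN
    RNifti::writeNifti(RNifti::asNifti(v, datatype = "double"), path)
  } else {
    v <- map$values
    vmax <- max(v, na.rm = TRUE)
    scale <- if (is.finite(vmax) && vmax > 0) vmax else 1
    page <- v / scale
    page[is.na(page)] <- 0
    suppressWarnings(tiff::writeTIFF(
      list(page, (!is.na(v)) * 1), path,
      bits.per.sample = 32L, reduce = FALSE))
    extra$scale <- scale
  }
  jsonlite::write_json(map_sidecar(map, extra), sidecar_path(path),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read a thickness map
#'
#' Counterpart of [write_thickness_map()]. The JSON sidecar must be present;
#' non-finite or sentinel cells are marked invalid (`NA`).
#'
#' @param path file path
#' @param format `"grid-tsv"`, `"nifti"`, or `"float-tiff"`; default inferred
#'   from the sidecar
#' @return a [thickness_map()]
#' @export
read_thickness_map <- function(path, format = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  meta <- read_sidecar(path)
  if (is.null(format)) format <- meta$format
  format <- match.arg(format, c("grid-tsv", "nifti", "float-tiff"))
  geom <- geometry_from_list(meta$geometry)
  if (format == "grid-tsv") {
    v <- as.matrix(utils::read.table(path, sep = "\t", header = FALSE,
                                     na.strings = "NA",
                                     colClasses = "numeric"))
    dimnames(v) <- NULL
  } else if (format == "nifti") {
    arr <- RNifti::readNifti(path)
    v <- matrix(as.numeric(arr), nrow(arr), ncol(arr))
    v[!is.finite(v)] <- NA
  } else {
    pages <- tiff::readTIFF(path, all = TRUE)
    v <- pages[[1]] * meta$scale
    v[pages[[2]] < 0.5] <- NA
  }
  v[!is.finite(v)] <- NA
  thickness_map(v, layer = meta$layer, laterality = meta$laterality,
                geometry = geom, registered = isTRUE(meta$registered),
                subject_id = if (is.null(meta$subject_id)) NA_character_
                             else meta$subject_id,
                session_id = if (is.null(meta$session_id)) NA_character_
                             else meta$session_id)
}

#' Write / read a raw OCT volume (raw-bin + JSON dialect)
#'
#' The portable volume dialect: little-endian float32 samples in
#' `bscan`-major order (depth fastest within an A-line written column-wise),
#' i.e. `writeBin(as.vector(intensity))` of the R array, plus a JSON header
#' next to the file with dimensions, geometry and laterality. Proprietary
#' raw exports must be converted to this dialect upstream.
#'
#' @param vol an [oct_volume()]
#' @param path output `.bin` path
#' @return `path`, invisibly
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "oct_volume"))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.numeric(vol$intensity), con, size = 4L, endian = "little")
  jsonlite::write_json(
    list(dim = dim(vol$intensity), dtype = "float32-le",
         order = "bscan,depth,ascan (first index fastest)",
         laterality = vol$laterality, subject_id = vol$subject_id,
         session_id = vol$session_id,
         geometry = geometry_to_list(vol$geometry)),
    sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_volume
#' @param path input `.bin` path (JSON header alongside)
#' @return [read_volume()]: an [oct_volume()]
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  meta <- read_sidecar_volume(path)
  d <- as.integer(unlist(meta$dim))
  n <- prod(d)
  expected <- n * 4
  actual <- file.size(path)
  if (actual < expected)
    stop(sprintf("I/O error: truncated volume: expected %d bytes (%d samples), found %d",
                 expected, n, actual))
  con <- file(path, "rb")
  on.exit(close(con))
  x <- readBin(con, "numeric", n = n, size = 4L, endian = "little")
  oct_volume(array(x, dim = d), geometry_from_list(meta$geometry),
             laterality = meta$laterality,
             subject_id = meta$subject_id %||% NA_character_,
             session_id = meta$session_id %||% NA_character_)
}

read_sidecar_volume <- function(path) {
  sc <- sidecar_path(path)
  if (!file.exists(sc)) stop("metadata error: sidecar not found: ", sc)
  meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
  for (f in c("dim", "laterality", "geometry"))
    if (is.null(meta[[f]])) stop("metadata error: sidecar field missing: ", f)
  meta
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Flip a scan to the left-eye orientation
#'
#' Scans of right eyes (OD) are mirrored along the A-scan (column) axis so
#' that the optic nerve head appears on the left side in every subject, and
#' relabelled `"L"` (left-normalized). Left eyes (OS) and already-normalized
#' inputs are relabelled only; the operation is idempotent.
#'
#' @param x a [thickness_map()], [boundary_set()], or [oct_volume()]
#' @return the same type, left-normalized
#' @export
flip_to_left <- function(x) UseMethod("flip_to_left")

mirror_cols <- function(m) m[, rev(seq_len(ncol(m))), drop = FALSE]

#' @export
flip_to_left.thickness_map <- function(x) {
  if (is.na(x$laterality)) stop("laterality error: laterality unknown")
  if (x$laterality == "OD") x$values <- mirror_cols(x$values)
  x$laterality <- "L"
  x
}

#' @export
flip_to_left.boundary_set <- function(x) {
  if (is.na(x$laterality)) stop("laterality error: laterality unknown")
  if (x$laterality == "OD") {
    x$surfaces <- lapply(x$surfaces, mirror_cols)
    x$valid <- mirror_cols(x$valid)
  }
  x$laterality <- "L"
  x
}

#' @export
flip_to_left.oct_volume <- function(x) {
  if (is.na(x$laterality)) stop("laterality error: laterality unknown")
  if (x$laterality == "OD")
    x$intensity <- x$intensity[, , rev(seq_len(dim(x$intensity)[3])),
                               drop = FALSE]
  x$laterality <- "L"
  x
}

#' Layer thickness maps from segmented boundaries
#'
#' Thickness is the depth difference between consecutive surfaces:
#' RNFL = RNFL/GCL - ILM, GCIPL = IPL/INL - RNFL/GCL, INL = INL/OPL -
#' IPL/INL, Retina = BM - ILM. A-lines flagged invalid in the boundary set
#' propagate to the validity masks of all four maps.
#'
#' @param b a [boundary_set()]
#' @param subject_id,session_id identifiers attached to the maps
#' @return named list of four [thickness_map()]s: `RNFL`, `GCIPL`, `INL`,
#'   `Retina`
#' @export
thickness_from_boundaries <- function(b, subject_id = NA_character_,
                                      session_id = NA_character_) {
  stopifnot(inherits(b, "boundary_set"))
  s <- b$surfaces
  pairs <- list(RNFL = c("ILM", "RNFL/GCL"),
                GCIPL = c("RNFL/GCL", "IPL/INL"),
                INL = c("IPL/INL", "INL/OPL"),
                Retina = c("ILM", "BM"))
  out <- lapply(names(pairs), function(layer) {
    v <- s[[pairs[[layer]][2]]] - s[[pairs[[layer]][1]]]
    v[!b$valid] <- NA
    v[v < 0 & v > -1e-9] <- 0  # guard float jitter at touching surfaces
    thickness_map(v, layer = layer, laterality = b$laterality,
                  geometry = b$geometry, subject_id = subject_id,
                  session_id = session_id)
  })
  names(out) <- names(pairs)
  out
}
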