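#' Intensity normalization of a raw volume
#'
#' Applies the monotone affine map that brings the volume's intensity mean
#' and standard deviation (over `mask` voxels if given, else all voxels) to
#' the reference values, so images acquired at different gains have similar
#' intensity levels. The rank order of voxel intensities is preserved.
#'
#' @param v an [oct_volume()]
#' @param reference_mean,reference_sd target mean / SD
#' @param mask optional logical array (same dim as the volume) restricting
#'   the voxels over which mean and SD are computed, e.g. the retina band
#' @return an [oct_volume()] with rescaled intensities
#' @export
normalize_intensity <- function(v, reference_mean, reference_sd, mask = NULL) {
  stopifnot(inherits(v, "oct_volume"))
  x <- if (is.null(mask)) v$intensity else v$intensity[mask]
  x <- x[is.finite(x)]
  m <- mean(x); s <- stats::sd(x)
  if (!is.finite(s) || s == 0)
    stop("degenerate-input error: volume has zero intensity variance")
  v$intensity <- (v$intensity - m) / s * reference_sd + reference_mean
  v
}

#' Extract the retina band of a volume
#'
#' Voxels outside the [ILM, BM] depth span of their A-line are set to a
#' background marker; intensities inside the retina are unchanged. The depth
#' of axial sample `d` is `(d - 1) * axial_resolution_um`. A-lines flagged
#' invalid in the boundary set are fully masked.
#'
#' @param v an [oct_volume()]
#' @param b a [boundary_set()] for the same scan
#' @param background value assigned to non-retina voxels (default `NA`)
#' @return an [oct_volume()] with non-retina voxels masked
#' @export
extract_retina <- function(v, b, background = NA_real_) {
  stopifnot(inherits(v, "oct_volume"), inherits(b, "boundary_set"))
  d <- dim(v$intensity)
  if (d[1] != b$geometry$n_bscans || d[3] != b$geometry$n_ascans)
    stop("geometry error: volume and boundary grids disagree")
  depth_um <- (seq_len(d[2]) - 1) * v$geometry$axial_resolution_um
  ilm <- b$surfaces$ILM; bm <- b$surfaces$BM
  out <- v$intensity
  for (r in seq_len(d[1])) {
    lo <- ilm[r, ]; hi <- bm[r, ]
    lo[!b$valid[r, ] | hi <= lo] <- Inf  # invalid/zero-span A-line: mask all
    # outer comparison: depth x ascan logical of out-of-band samples
    keep <- outer(depth_um, lo, `>=`) & outer(depth_um, hi, `<=`)
    slab <- out[r, , ]
    slab[!keep] <- background
    out[r, , ] <- slab
  }
  v$intensity <- out
  v
}

# Separable, NA-aware Gaussian smoothing by normalized convolution, with a
# per-axis sigma (in voxels) to respect grid anisotropy: the kernel mass
# falling on invalid or out-of-grid cells is renormalized away, so valid
# cells near edges keep an unbiased local mean and invalid cells stay NA.
gaussian_smooth_na <- function(m, sigma) {
  if (length(sigma) == 1L) sigma <- rep(sigma, 2L)
  if (all(sigma <= 0)) return(m)
  w <- !is.na(m)
  v <- m; v[!w] <- 0
  conv1 <- function(x, along, s) {
    if (s <= 0) return(x)
    # zero-padded convolution along rows (1) or cols (2)
    if (along == 2L) x <- t(x)
    half <- max(1L, ceiling(3 * s))
    k <- stats::dnorm(seq(-half, half), sd = s)
    k <- k / sum(k)
    n <- nrow(x)
    out <- matrix(0, n, ncol(x))
    for (j in seq_along(k)) {
      off <- j - half - 1L
      src <- seq_len(n) + off
      ok <- src >= 1L & src <= n
      out[ok, ] <- out[ok, ] + k[j] * x[src[ok], , drop = FALSE]
    }
    if (along == 2L) t(out) else out
  }
  num <- conv1(conv1(v, 1L, sigma[1]), 2L, sigma[2])
  den <- conv1(conv1(w * 1, 1L, sigma[1]), 2L, sigma[2])
  res <- num / den
  res[!w] <- NA
  res
}

#' Locate the fovea on a retina thickness map
#'
#' The fovea is the thinnest point of the retina. The map is smoothed with a
#' small Gaussian before taking the global minimum over valid voxels; exact
#' ties are broken by the centroid of the minimum set rounded to the nearest
#' grid point. Because the acquisition grid is strongly anisotropic (B-scan
#' spacing of hundreds of micrometres vs a few micrometres between A-scans),
#' the smoothing width is specified in micrometres and converted to per-axis
#' voxel sigmas; `sigma_um = 0` disables smoothing (raw argmin).
#'
#' @param retina a [thickness_map()] of layer `"Retina"`
#' @param sigma_um smoothing width in micrometres (default 250)
#' @return integer `c(row, col)` of the detected fovea
#' @export
detect_fovea <- function(retina, sigma_um = 250) {
  stopifnot(inherits(retina, "thickness_map"))
  if (retina$layer != "Retina")
    warning("fovea detection expects a Retina map, got ", retina$layer)
  if (all(is.na(retina$values)))
    stop("no-fovea error: map has no valid voxels")
  geom <- retina$geometry
  sig <- c(sigma_um / row_spacing_um(geom), sigma_um / col_spacing_um(geom))
  sm <- gaussian_smooth_na(retina$values, sig)
  mn <- min(sm, na.rm = TRUE)
  idx <- which(sm == mn, arr.ind = TRUE)
  c(as.integer(round(mean(idx[, 1]))), as.integer(round(mean(idx[, 2]))))
}

#' Global en-face translation aligning a subject fovea to the target
#'
#' @param subject_fovea integer `c(row, col)` from [detect_fovea()]
#' @param target a [target_grid()]
#' @return integer `c(delta_row, delta_col)`; adding it to the subject fovea
#'   gives the target fovea exactly
#' @export
compute_global_translation <- function(subject_fovea, target) {
  stopifnot(inherits(target, "target_grid"))
  as.integer(target$fovea_position - subject_fovea)
}

# Integer-shift a matrix onto an n_rows x n_cols grid; cells translated in
# from outside the source field become NA (never zero).
translate_matrix <- function(m, delta, n_rows = nrow(m), n_cols = ncol(m)) {
  out <- matrix(NA_real_, n_rows, n_cols)
  src_r <- seq_len(n_rows) - delta[1]
  src_c <- seq_len(n_cols) - delta[2]
  ok_r <- src_r >= 1L & src_r <= nrow(m)
  ok_c <- src_c >= 1L & src_c <= ncol(m)
  out[ok_r, ok_c] <- m[src_r[ok_r], src_c[ok_c], drop = FALSE]
  out
}

#' Apply an integer en-face translation to a thickness map
#'
#' @param map a [thickness_map()]
#' @param delta integer `c(delta_row, delta_col)`
#' @param n_rows,n_cols output grid size (default: input size)
#' @return a translated [thickness_map()]; cells with no source are invalid
#' @export
translate_map <- function(map, delta, n_rows = NULL, n_cols = NULL) {
  stopifnot(inherits(map, "thickness_map"))
  n_rows <- n_rows %||% nrow(map$values)
  n_cols <- n_cols %||% ncol(map$values)
  v <- translate_matrix(map$values, delta, n_rows, n_cols)
  geom <- map$geometry
  if (n_rows != geom$n_bscans || n_cols != geom$n_ascans) {
    geom$n_bscans <- as.integer(n_rows)
    geom$n_ascans <- as.integer(n_cols)
  }
  thickness_map(v, map$layer, map$laterality, geom,
                registered = map$registered, subject_id = map$subject_id,
                session_id = map$session_id)
}

#' Per-A-line 1D affine depth alignment
#'
#' Fits, at each A-line, the affine map `z -> a z + b` taking the subject's
#' ILM and BM depths exactly onto the target's. Works elementwise on scalars
#' or matrices. A-lines with a non-positive subject retinal span are flagged
#' invalid (`NA` coefficients) rather than producing a degenerate transform.
#'
#' @param subject_ilm,subject_bm subject ILM / BM depth (um)
#' @param target_ilm,target_bm target ILM / BM depth (um)
#' @return list with elements `a` (scale) and `b` (offset, um)
#' @export
fit_aline_affine <- function(subject_ilm, subject_bm, target_ilm, target_bm) {
  span_s <- subject_bm - subject_ilm
  span_t <- target_bm - target_ilm
  bad <- !is.na(span_s) & span_s <= 0
  if (length(span_s) == 1L && isTRUE(bad))
    stop("degenerate A-line error: subject retinal span is zero")
  a <- span_t / span_s
  a[bad] <- NA
  b <- target_ilm - a * subject_ilm
  list(a = a, b = b)
}

#' Register one scan to the target space
#'
#' The full spatial normalization of a left-normalized scan: the fovea is
#' detected on the Retina map, the global integer translation onto the
#' target fovea is applied to all four layer maps (one shared translation
#' per scan), and per-A-line depth affines are fitted between the subject's
#' translated ILM/BM surfaces and the target's. By default the depth affine
#' only establishes anatomical correspondence: thickness values are the
#' original boundary differences and are \emph{not} rescaled by the affine
#' scale (set `rescale_thickness = TRUE` for the alternative convention).
#'
#' @param maps named list of the four [thickness_map()]s (`RNFL`, `GCIPL`,
#'   `INL`, `Retina`), left-normalized
#' @param boundaries the scan's [boundary_set()], left-normalized
#' @param target a [target_grid()]
#' @param sigma_um fovea-detection smoothing in micrometres
#' @param rescale_thickness multiply thickness by the per-A-line affine
#'   scale (default `FALSE`)
#' @return list with `maps` (registered maps) and `transform` (a
#'   `registration_transform`: `translation`, `aline_scale`, `aline_offset`)
#' @export
register_scan <- function(maps, boundaries, target, sigma_um = 250,
                          rescale_thickness = FALSE) {
  stopifnot(inherits(target, "target_grid"))
  if (!all(c("RNFL", "GCIPL", "INL", "Retina") %in% names(maps)))
    stop("register_scan needs the four maps RNFL, GCIPL, INL, Retina")
  lat <- unique(vapply(maps, `[[`, "", "laterality"))
  if (!identical(lat, "L"))
    stop("laterality error: maps must be left-normalized (flip_to_left) first")
  fovea <- detect_fovea(maps$Retina, sigma_um = sigma_um)
  delta <- compute_global_translation(fovea, target)
  reg <- lapply(maps, function(m) {
    out <- translate_map(m, delta, target$n_rows, target$n_cols)
    out$registered <- TRUE
    out
  })
  aline <- list(a = matrix(1, target$n_rows, target$n_cols),
                b = matrix(0, target$n_rows, target$n_cols))
  if (!is.null(boundaries) && !is.null(target$ilm) && !is.null(target$bm)) {
    ilm_t <- translate_matrix(boundaries$surfaces$ILM, delta,
                              target$n_rows, target$n_cols)
    bm_t <- translate_matrix(boundaries$surfaces$BM, delta,
                             target$n_rows, target$n_cols)
    aline <- fit_aline_affine(ilm_t, bm_t, target$ilm, target$bm)
  }
  if (isTRUE(rescale_thickness))
    reg <- lapply(reg, function(m) {
      m$values <- m$values * aline$a
      m
    })
  transform <- structure(list(translation = delta, aline_scale = aline$a,
                              aline_offset = aline$b, target = target),
                         class = "registration_transform")
  list(maps = reg, transform = transform)
}

#' Build the common target space from a cohort
#'
#' With `policy = "designated-reference"` the target is the first scan: its
#' fovea position and ILM/BM surfaces define the space. With
#' `policy = "cohort-mean-template"` every scan is first registered to the
#' designated reference, the registered Retina maps and ILM/BM surfaces are
#' voxel-wise averaged, and the average defines the final target (scans are
#' then registered to this mean template, i.e. re-registered once).
#'
#' @param scans list of scans, each a list with `maps` (four
#'   [thickness_map()]s, left-normalized) and `boundaries`
#' @param policy target-space policy
#' @param sigma_um fovea-detection smoothing in micrometres
#' @return a [target_grid()]
#' @export
build_target <- function(scans,
                         policy = c("cohort-mean-template",
                                    "designated-reference"),
                         sigma_um = 250) {
  policy <- match.arg(policy)
  ref <- scans[[1]]
  geom <- ref$maps$Retina$geometry
  fov <- detect_fovea(ref$maps$Retina, sigma_um = sigma_um)
  t0 <- target_grid(geom$n_bscans, geom$n_ascans, fov,
                    source = "designated-reference", geometry = geom,
                    ilm = ref$boundaries$surfaces$ILM,
                    bm = ref$boundaries$surfaces$BM)
  if (policy == "designated-reference" || length(scans) == 1L) return(t0)
  acc_ret <- acc_ilm <- acc_bm <- matrix(0, t0$n_rows, t0$n_cols)
  cnt <- matrix(0, t0$n_rows, t0$n_cols)
  for (s in scans) {
    r <- register_scan(s$maps, s$boundaries, t0, sigma_um = sigma_um)
    v <- r$maps$Retina$values
    ok <- !is.na(v)
    acc_ret[ok] <- acc_ret[ok] + v[ok]
    ilm_t <- translate_matrix(s$boundaries$surfaces$ILM,
                              r$transform$translation, t0$n_rows, t0$n_cols)
    bm_t <- translate_matrix(s$boundaries$surfaces$BM,
                             r$transform$translation, t0$n_rows, t0$n_cols)
    acc_ilm[ok] <- acc_ilm[ok] + ilm_t[ok]
    acc_bm[ok] <- acc_bm[ok] + bm_t[ok]
    cnt[ok] <- cnt[ok] + 1
  }
  mean_ret <- acc_ret / cnt
  mean_ret[cnt == 0] <- NA
  mean_ilm <- acc_ilm / cnt; mean_ilm[cnt == 0] <- NA
  mean_bm <- acc_bm / cnt; mean_bm[cnt == 0] <- NA
  tpl <- thickness_map(pmax(mean_ret, 0), "Retina", "L", geom,
                       registered = TRUE)
  fov1 <- detect_fovea(tpl, sigma_um = sigma_um)
  target_grid(geom$n_bscans, geom$n_ascans, fov1,
              source = "cohort-mean-template", geometry = geom,
              ilm = mean_ilm, bm = mean_bm)
}
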