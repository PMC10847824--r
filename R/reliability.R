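#' Test-retest stack of registered maps
#'
#' Repeated same-day scans of the same subjects, registered to one target:
#' a `subject x session x row x col` array for one layer.
#'
#' @param data 4D numeric array, `subject x session x row x col`
#' @param layer layer name
#' @param same_day logical flag recorded with the stack
#' @return an object of class `retest_stack`
#' @export
retest_stack <- function(data, layer, same_day = TRUE) {
  d <- dim(data)
  if (length(d) != 4L)
    stop("retest data must be subject x session x row x col")
  if (d[2] < 2L) stop("session-count error: need >= 2 sessions")
  structure(list(data = data, layer = layer, n_subjects = d[1],
                 n_sessions = d[2], same_day = isTRUE(same_day)),
            class = "retest_stack")
}

# per-voxel two-way mean squares of a retest stack:
# rows = subjects (random), columns = sessions
retest_mean_squares <- function(stack) {
  d <- stack$data
  n <- dim(d)[1]; k <- dim(d)[2]
  grand <- apply(d, c(3, 4), mean)                     # row x col
  subj_mean <- apply(d, c(1, 3, 4), mean)              # n x row x col
  sess_mean <- apply(d, c(2, 3, 4), mean)              # k x row x col
  ssr <- k * apply(sweep(subj_mean, c(2, 3), grand)^2, c(2, 3), sum)
  ssc <- n * apply(sweep(sess_mean, c(2, 3), grand)^2, c(2, 3), sum)
  sst <- apply(sweep(d, c(3, 4), grand)^2, c(3, 4), sum)
  sse <- sst - ssr - ssc
  sse[sse < 0] <- 0   # guard float cancellation
  list(msr = ssr / (n - 1), msc = ssc / (k - 1),
       mse = sse / ((n - 1) * (k - 1)), n = n, k = k, grand = grand)
}

#' Voxel-wise within-subject standard deviation (Sw)
#'
#' `Sw = sqrt(mean over subjects of the within-subject variance across
#' sessions)` at every voxel; for two sessions this reduces to
#' `sqrt(sum(d_i^2) / (2 n))` with `d_i` the session difference. Invariant
#' under adding a constant to all measurements.
#'
#' @param stack a [retest_stack()]
#' @return matrix of Sw (um)
#' @export
voxelwise_sw <- function(stack) {
  stopifnot(inherits(stack, "retest_stack"))
  d <- stack$data
  subj_mean <- apply(d, c(1, 3, 4), mean)
  k <- dim(d)[2]
  within_ss <- apply(sweep(d, c(1, 3, 4), subj_mean)^2, c(3, 4), sum)
  sqrt(within_ss / (k - 1) / dim(d)[1])
}

#' Voxel-wise coefficient of variation (CV)
#'
#' `CV = Sw / grand mean * 100` per voxel (the within-subject SD relative to
#' the voxel's grand mean across subjects and sessions). Voxels with a
#' non-positive grand mean are invalid.
#'
#' @param stack a [retest_stack()]
#' @return matrix of CV (%)
#' @export
voxelwise_cv <- function(stack) {
  stopifnot(inherits(stack, "retest_stack"))
  sw <- voxelwise_sw(stack)
  grand <- apply(stack$data, c(3, 4), mean)
  cv <- sw / grand * 100
  cv[grand <= 0] <- NA
  cv
}

#' Voxel-wise intraclass correlation coefficient
#'
#' Two-way random-effects ICC per voxel from the subject x session ANOVA
#' decomposition. The default form is absolute agreement, single measurement
#' (ICC(2,1)):
#' `(MSR - MSE) / (MSR + (k-1) MSE + k (MSC - MSE) / n)`;
#' `form = "consistency"` gives ICC(3,1) = `(MSR - MSE) / (MSR + (k-1) MSE)`.
#' Voxels with zero total variance are invalid.
#'
#' @param stack a [retest_stack()]
#' @param form `"absolute-agreement"` (default) or `"consistency"`
#' @return matrix of ICC (unitless, <= 1)
#' @export
voxelwise_icc <- function(stack, form = c("absolute-agreement",
                                          "consistency")) {
  stopifnot(inherits(stack, "retest_stack"))
  form <- match.arg(form)
  ms <- retest_mean_squares(stack)
  denom <- if (form == "absolute-agreement")
    ms$msr + (ms$k - 1) * ms$mse + ms$k * (ms$msc - ms$mse) / ms$n
  else
    ms$msr + (ms$k - 1) * ms$mse
  icc <- (ms$msr - ms$mse) / denom
  icc[denom <= 0] <- NA
  icc
}

#' Qualitative ICC classification
#'
#' Default bands: >= 0.9 excellent, >= 0.75 good, >= 0.5 moderate, else
#' poor.
#'
#' @param icc numeric (scalar, vector or matrix) of ICC values
#' @param bands named thresholds, decreasing
#' @return character of the same shape
#' @export
icc_classify <- function(icc, bands = c(excellent = 0.9, good = 0.75,
                                        moderate = 0.5)) {
  out <- rep(NA_character_, length(icc))
  out[!is.na(icc)] <- "poor"
  for (b in rev(seq_along(bands)))
    out[!is.na(icc) & icc >= bands[b]] <- names(bands)[b]
  if (is.matrix(icc)) out <- matrix(out, nrow(icc), ncol(icc))
  out
}

#' Reliability summary of a retest stack
#'
#' Voxel-wise Sw, CV and ICC maps plus their means over valid voxels and the
#' qualitative ICC classification of the map average.
#'
#' @param stack a [retest_stack()]
#' @param form ICC form, see [voxelwise_icc()]
#' @param mask optional exclusion mask (TRUE = exclude)
#' @return object of class `reliability_maps`: `sw`, `cv`, `icc`, `summary`
#'   (mean Sw/CV/ICC), `classification`
#' @export
reliability_maps <- function(stack, form = "absolute-agreement",
                             mask = NULL) {
  sw <- voxelwise_sw(stack)
  cv <- voxelwise_cv(stack)
  icc <- voxelwise_icc(stack, form = form)
  excl <- resolve_mask(mask, nrow(sw), ncol(sw))
  sw[excl] <- NA; cv[excl] <- NA; icc[excl] <- NA
  summ <- c(sw = mean(sw, na.rm = TRUE), cv = mean(cv, na.rm = TRUE),
            icc = mean(icc, na.rm = TRUE))
  structure(list(sw = sw, cv = cv, icc = icc, summary = summ,
                 classification = icc_classify(summ[["icc"]]),
                 layer = stack$layer),
            class = "reliability_maps")
}

#' @export
print.reliability_maps <- function(x, ...) {
  cat(sprintf("%s reliability: mean Sw %.2f um, CV %.2f%%, ICC %.3f (%s)\n",
              x$layer, x$summary[["sw"]], x$summary[["cv"]],
              x$summary[["icc"]], x$classification))
  invisible(x)
}

#' Voxel-wise paired retest comparison
#'
#' Paired t-test per voxel between the first and second scan of a two-session
#' retest stack, followed by the same BH-FDR + cluster-extent procedure as
#' the group comparisons. On a well-behaved scanner no voxel should remain
#' significant.
#'
#' @param stack a [retest_stack()] with exactly 2 sessions
#' @param alpha,min_cluster_voxels,connectivity multiplicity parameters
#' @param mask optional exclusion mask
#' @return a `stat_map_set` (paired t in `stat`, mean session difference in
#'   `diff`)
#' @export
retest_paired_test <- function(stack, alpha = 0.05, min_cluster_voxels = 9L,
                               connectivity = 8L, mask = NULL) {
  stopifnot(inherits(stack, "retest_stack"))
  if (stack$n_sessions != 2L)
    stop("session mismatch: paired test needs exactly 2 sessions")
  d <- stack$data[, 2, , ] - stack$data[, 1, , ]   # n x row x col
  n <- dim(d)[1]
  mean_d <- apply(d, c(2, 3), mean)
  sd_d <- apply(d, c(2, 3), stats::sd)
  tt <- mean_d / (sd_d / sqrt(n))
  tt[sd_d == 0 & mean_d == 0] <- 0
  p <- 2 * stats::pt(-abs(tt), n - 1)
  p[sd_d == 0 & mean_d == 0] <- 1
  excl <- resolve_mask(mask, nrow(p), ncol(p))
  fdr <- fdr_correct(p, alpha, mask = excl)
  cl <- cluster_filter(fdr$sig, min_cluster_voxels, connectivity)
  structure(list(beta = list(session_diff = mean_d), stat = tt, p = p,
                 sig = cl$sig, q_threshold = fdr$cutoff,
                 clusters = cl$labels, diff = mean_d,
                 adjusted_means = NULL,
                 n_effective = matrix(n, nrow(p), ncol(p)),
                 contrast = "paired-t", alpha = alpha,
                 min_cluster_voxels = as.integer(min_cluster_voxels),
                 connectivity = as.integer(connectivity),
                 cluster_table = cl$table),
            class = "stat_map_set")
}

#' Scalar test-retest reliability
#'
#' CV and ICC of per-subject, per-session scalar summaries (e.g. macular
#' layer volumes): the voxel-wise formulas applied to a 1 x 1 grid.
#'
#' @param values numeric matrix, `subject x session`
#' @param form ICC form, see [voxelwise_icc()]
#' @return list: `sw`, `cv` (%), `icc`, `classification`
#' @export
scalar_reliability <- function(values, form = "absolute-agreement") {
  values <- as.matrix(values)
  stk <- retest_stack(array(values, c(nrow(values), ncol(values), 1, 1)),
                      layer = "scalar")
  icc <- voxelwise_icc(stk, form = form)[1, 1]
  list(sw = voxelwise_sw(stk)[1, 1], cv = voxelwise_cv(stk)[1, 1],
       icc = icc, classification = icc_classify(icc))
}
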