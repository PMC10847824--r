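#' Specification of a voxel-wise GLM analysis
#'
#' @param contrast `"two-group-t"` (t on the group indicator, disease minus
#'   reference) or `"omnibus-F"` (F over all group dummies)
#' @param covariates subset of `c("age", "sex", "retina_voxel")`;
#'   `"retina_voxel"` enters the subject's Retina thickness at the voxel
#'   being tested as a per-voxel covariate
#' @param alpha FDR level (default 0.05)
#' @param min_cluster_voxels minimum surviving cluster extent (default 9
#'   voxels, a 3 x 3 footprint)
#' @param connectivity 4- or 8-neighbour adjacency on the en-face grid
#' @param reference_group label of the reference (control) group
#' @return an object of class `glm_spec`
#' @export
glm_spec <- function(contrast = c("two-group-t", "omnibus-F"),
                     covariates = c("age", "sex", "retina_voxel"),
                     alpha = 0.05, min_cluster_voxels = 9L,
                     connectivity = 8L, reference_group = "HC") {
  contrast <- match.arg(contrast)
  if (length(covariates))
    covariates <- match.arg(covariates, c("age", "sex", "retina_voxel"),
                            several.ok = TRUE)
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  if (min_cluster_voxels < 1) stop("min_cluster_voxels must be >= 1")
  if (!connectivity %in% c(4L, 8L)) stop("connectivity must be 4 or 8")
  structure(list(contrast = contrast, covariates = covariates, alpha = alpha,
                 min_cluster_voxels = as.integer(min_cluster_voxels),
                 connectivity = as.integer(connectivity),
                 reference_group = reference_group),
            class = "glm_spec")
}

# Least squares on a common design X for many responses Y (n x V), with an
# optional per-voxel regressor Rm (n x V) appended to the design. The
# per-voxel column is absorbed by the Frisch-Waugh step: residualize Rm and
# Y on X, fit the per-voxel scalar coefficient gamma on the residualized
# column, then correct the common-column coefficients through the Schur
# complement. Columns of Y/Rm must be complete (no NA).
ls_block <- function(X, Y, Rm = NULL) {
  n <- nrow(X); p <- ncol(X)
  A <- crossprod(X)
  Ai <- tryCatch(chol2inv(chol(A)), error = function(e) NULL)
  if (is.null(Ai)) stop("design error: rank-deficient common design matrix")
  B0 <- Ai %*% crossprod(X, Y)
  E0 <- Y - X %*% B0
  if (is.null(Rm)) {
    rss <- colSums(E0^2)
    df <- n - p
    return(list(beta = B0, gamma = NULL, rss = rss, df = df, Ai = Ai,
                W = NULL, s = NULL))
  }
  U <- crossprod(X, Rm)
  W <- Ai %*% U
  MR <- Rm - X %*% W
  s <- colSums(Rm * MR)           # = || M r ||^2
  s[s < .Machine$double.eps * n] <- NA  # collinear per-voxel column
  gamma <- colSums(MR * Y) / s
  E <- E0 - sweep(MR, 2L, gamma, `*`)
  rss <- colSums(E^2)
  beta <- B0 - sweep(W, 2L, gamma, `*`)
  list(beta = beta, gamma = gamma, rss = rss, df = n - p - 1L, Ai = Ai,
       W = W, s = s)
}

# variance of common coefficient j from an ls_block fit
ls_var_beta <- function(fit, j, sigma2) {
  if (is.null(fit$W)) sigma2 * fit$Ai[j, j]
  else sigma2 * (fit$Ai[j, j] + fit$W[j, ]^2 / fit$s)
}

# assemble the common design from covariate table and spec
build_design <- function(cov, spec) {
  grp <- factor(cov$group)
  if (spec$reference_group %in% levels(grp))
    grp <- stats::relevel(grp, ref = spec$reference_group)
  terms <- "grp"
  df <- data.frame(grp = grp)
  if ("age" %in% spec$covariates && "age" %in% names(cov)) {
    df$age <- cov$age; terms <- c(terms, "age")
  }
  if ("sex" %in% spec$covariates && "sex" %in% names(cov)) {
    df$sex <- factor(cov$sex); terms <- c(terms, "sex")
  }
  X <- stats::model.matrix(stats::reformulate(terms), df)
  group_cols <- grep("^grp", colnames(X))
  list(X = X, group_cols = group_cols, group = grp)
}

#' Voxel-wise general linear model comparison
#'
#' Fits, independently at every unmasked voxel,
#' `thickness ~ intercept + group + age + sex + retina_thickness(voxel)`
#' (terms per `spec$covariates`) and tests the group effect: a t contrast on
#' the group indicator for two groups, or the omnibus F over the group
#' dummies. Raw p values are corrected by Benjamini-Hochberg FDR over all
#' valid voxels of the map, then the cluster-extent filter removes
#' significant components smaller than `spec$min_cluster_voxels`. Voxels
#' with fewer complete observations than model parameters + 1 are excluded
#' and reported in `n_effective`.
#'
#' @param layer_stack [build_group_stack()] of the response layer
#' @param retina_stack matching stack of Retina maps (required when
#'   `"retina_voxel"` is in `spec$covariates`)
#' @param spec a [glm_spec()]
#' @param mask optional [fovea_exclusion_mask()] (or logical matrix,
#'   `TRUE` = exclude)
#' @return an object of class `stat_map_set`: `beta` (named list of
#'   coefficient maps), `stat` (t or F), `p`, `sig` (after FDR + cluster),
#'   `q_threshold` (realized BH cutoff), `clusters` (label grid), `diff`
#'   (unadjusted group mean difference, um), `adjusted_means`,
#'   `n_effective`, and the spec parameters
#' @export
voxelwise_glm <- function(layer_stack, retina_stack = NULL, spec = glm_spec(),
                          mask = NULL) {
  stopifnot(inherits(layer_stack, "group_stack"))
  use_retina <- "retina_voxel" %in% spec$covariates
  if (use_retina && is.null(retina_stack))
    stop("retina_stack required when covariates include retina_voxel")
  dims <- dim(layer_stack$data)
  n <- dims[1]; R <- dims[2]; C <- dims[3]; V <- R * C
  Y <- matrix(layer_stack$data, n, V)
  Rm <- if (use_retina) matrix(retina_stack$data, n, V) else NULL
  des <- build_design(layer_stack$covariates, spec)
  X <- des$X
  k <- length(des$group_cols)
  if (spec$contrast == "two-group-t" && k != 1L)
    stop("two-group-t contrast requires exactly two group levels, found ",
         k + 1L)
  p_par <- ncol(X) + use_retina
  excl <- resolve_mask(mask, R, C)

  obs_ok <- is.finite(Y)
  if (use_retina) obs_ok <- obs_ok & is.finite(Rm)
  n_eff <- colSums(obs_ok)
  testable <- !as.vector(excl) & n_eff >= p_par + 1L
  complete <- testable & n_eff == n

  stat <- pval <- dif <- rep(NA_real_, V)
  beta <- matrix(NA_real_, ncol(X) + use_retina, V)
  mu_ref <- mu_alt <- rep(NA_real_, V)

  # reduced design (group dummies dropped) for the omnibus F
  X0 <- X[, -des$group_cols, drop = FALSE]
  grp_num <- as.integer(des$group) # 1 = reference
  xbar <- colMeans(X)

  fit_cols <- function(cols, Xc, Yc, Rc) {
    fit <- ls_block(Xc, Yc, Rc)
    df <- fit$df
    sigma2 <- fit$rss / df
    if (spec$contrast == "two-group-t") {
      j <- des$group_cols
      vb <- ls_var_beta(fit, j, sigma2)
      tt <- fit$beta[j, ] / sqrt(vb)
      pp <- 2 * stats::pt(-abs(tt), df)
      pp[sigma2 == 0] <- 1  # perfect fit with zero effect
      tt[sigma2 == 0 & fit$beta[j, ] == 0] <- 0
    } else {
      fit0 <- ls_block(X0, Yc, Rc)
      q <- k
      tt <- ((fit0$rss - fit$rss) / q) / sigma2
      pp <- stats::pf(tt, q, df, lower.tail = FALSE)
    }
    stat[cols] <<- tt
    pval[cols] <<- pp
    b <- fit$beta
    if (!is.null(fit$gamma)) b <- rbind(b, fit$gamma)
    beta[, cols] <<- b
    # adjusted means at covariate means (two-group case)
    if (spec$contrast == "two-group-t") {
      xadj <- xbar; xadj[des$group_cols] <- 0
      base <- as.vector(xadj %*% fit$beta)
      if (!is.null(fit$gamma))
        base <- base + fit$gamma * colMeans(Rc)
      mu_ref[cols] <<- base
      mu_alt[cols] <<- base + fit$beta[des$group_cols, ]
    }
  }

  if (any(complete)) {
    cols <- which(complete)
    fit_cols(cols, X, Y[, cols, drop = FALSE],
             if (use_retina) Rm[, cols, drop = FALSE] else NULL)
  }
  partial <- which(testable & !complete)
  for (v in partial) {
    ok <- obs_ok[, v]
    Xv <- X[ok, , drop = FALSE]
    if (use_retina) Xv <- cbind(Xv, Rm[ok, v])
    if (qr(Xv)$rank < ncol(Xv)) next
    yv <- Y[ok, v]
    f <- stats::lm.fit(Xv, yv)
    dfv <- sum(ok) - ncol(Xv)
    if (dfv < 1L) next
    rssv <- sum(f$residuals^2)
    s2 <- rssv / dfv
    XtXi <- chol2inv(qr.R(f$qr))
    if (spec$contrast == "two-group-t") {
      j <- des$group_cols
      se <- sqrt(s2 * XtXi[j, j])
      tt <- if (se == 0 && f$coefficients[j] == 0) 0 else f$coefficients[j] / se
      stat[v] <- tt
      pval[v] <- if (s2 == 0) 1 else 2 * stats::pt(-abs(tt), dfv)
      xadj <- colMeans(Xv); xadj[j] <- 0
      mu_ref[v] <- sum(xadj * f$coefficients)
      mu_alt[v] <- mu_ref[v] + f$coefficients[j]
    } else {
      X0v <- Xv[, -des$group_cols, drop = FALSE]
      f0 <- stats::lm.fit(X0v, yv)
      Fv <- ((sum(f0$residuals^2) - rssv) / k) / s2
      stat[v] <- Fv
      pval[v] <- stats::pf(Fv, k, dfv, lower.tail = FALSE)
    }
    beta[, v] <- f$coefficients
  }

  # unadjusted group mean difference (what the figures render)
  if (k == 1L) {
    is_alt <- grp_num == 2L
    Ya <- Y; Ya[!obs_ok] <- NA
    m_alt <- colMeans(Ya[is_alt, , drop = FALSE], na.rm = TRUE)
    m_ref <- colMeans(Ya[!is_alt, , drop = FALSE], na.rm = TRUE)
    dif <- m_alt - m_ref
    dif[!testable] <- NA
  }

  p_map <- matrix(pval, R, C)
  fdr <- fdr_correct(p_map, spec$alpha, mask = excl)
  cl <- cluster_filter(fdr$sig, spec$min_cluster_voxels, spec$connectivity)

  coef_names <- c(colnames(X), if (use_retina) "retina_voxel")
  beta_maps <- lapply(seq_len(nrow(beta)), function(i) matrix(beta[i, ], R, C))
  names(beta_maps) <- coef_names
  structure(list(
    beta = beta_maps,
    stat = matrix(stat, R, C), p = p_map,
    sig = cl$sig, q_threshold = fdr$cutoff, clusters = cl$labels,
    diff = matrix(dif, R, C),
    adjusted_means = if (k == 1L)
      list(reference = matrix(mu_ref, R, C), other = matrix(mu_alt, R, C))
      else NULL,
    n_effective = matrix(n_eff, R, C),
    contrast = spec$contrast, alpha = spec$alpha,
    min_cluster_voxels = spec$min_cluster_voxels,
    connectivity = spec$connectivity,
    cluster_table = cl$table),
    class = "stat_map_set")
}

#' @export
print.stat_map_set <- function(x, ...) {
  cat(sprintf("voxel-wise %s map: %d x %d, %d significant voxels in %d cluster(s) (alpha %.3g, min extent %d)\n",
              x$contrast, nrow(x$p), ncol(x$p), sum(x$sig, na.rm = TRUE),
              if (is.null(x$cluster_table)) 0L else nrow(x$cluster_table),
              x$alpha, x$min_cluster_voxels))
  invisible(x)
}

resolve_mask <- function(mask, R, C) {
  if (is.null(mask)) return(matrix(FALSE, R, C))
  if (inherits(mask, "fovea_mask")) mask <- mask$mask
  stopifnot(is.logical(mask), identical(dim(mask), c(R, C)))
  mask
}

#' Benjamini-Hochberg FDR correction over a p-value map
#'
#' Step-up BH procedure at level `alpha` over the family of all valid
#' (finite, unmasked) voxels of one map. Returns the rejection grid and the
#' realized p cutoff (the largest ordered p with `p_(i) <= i alpha / m`).
#'
#' @param p_map matrix of raw p values (`NA` = not tested)
#' @param alpha FDR level
#' @param mask optional exclusion mask ([fovea_exclusion_mask()] or logical
#'   matrix, `TRUE` = exclude)
#' @return list: `sig` (logical grid), `cutoff` (realized p threshold or
#'   `NA` when nothing is rejected), `m` (family size), `n_rejected`
#' @export
fdr_correct <- function(p_map, alpha = 0.05, mask = NULL) {
  stopifnot(is.matrix(p_map), alpha > 0, alpha < 1)
  excl <- resolve_mask(mask, nrow(p_map), ncol(p_map))
  fam <- is.finite(p_map) & !excl
  sig <- matrix(FALSE, nrow(p_map), ncol(p_map))
  if (!any(fam)) {
    warning("empty family: no valid voxels to correct")
    return(list(sig = sig, cutoff = NA_real_, m = 0L, n_rejected = 0L))
  }
  pv <- p_map[fam]
  if (any(pv < 0 | pv > 1)) stop("p values must lie in [0, 1]")
  padj <- stats::p.adjust(pv, method = "BH")
  rej <- padj <= alpha
  sig[fam] <- rej
  # realized step-up cutoff from the definition
  m <- length(pv)
  ps <- sort(pv)
  below <- which(ps <= seq_len(m) * alpha / m)
  cutoff <- if (length(below)) ps[max(below)] else NA_real_
  list(sig = sig, cutoff = cutoff, m = m, n_rejected = sum(rej))
}

#' Cluster-extent filtering of a significance grid
#'
#' Connected components of the significant voxels are identified under 4- or
#' 8-neighbour adjacency; components smaller than `min_voxels` are removed.
#' Surviving components are labelled 1..K in decreasing size, ties broken by
#' the component containing the top-left-most voxel (smallest row, then
#' column).
#'
#' @param sig logical matrix of significant voxels
#' @param min_voxels minimum component size kept (default 9)
#' @param connectivity 4 or 8
#' @return list: `sig` (filtered grid), `labels` (integer grid, 0 =
#'   background), `table` (data.frame: label, size, centroid, peak position)
#' @export
cluster_filter <- function(sig, min_voxels = 9L, connectivity = 8L) {
  stopifnot(is.logical(sig), min_voxels >= 1,
            connectivity %in% c(4L, 8L))
  sig[is.na(sig)] <- FALSE
  R <- nrow(sig); C <- ncol(sig)
  labels <- matrix(0L, R, C)
  idx <- which(sig)
  out_tab <- data.frame(label = integer(), size = integer(),
                        centroid_row = numeric(), centroid_col = numeric())
  if (!length(idx))
    return(list(sig = sig & FALSE, labels = labels, table = out_tab))
  rows <- ((idx - 1L) %% R) + 1L
  cols <- ((idx - 1L) %/% R) + 1L
  offs <- if (connectivity == 4L)
    cbind(c(-1, 1, 0, 0), c(0, 0, -1, 1))
  else
    cbind(rep(c(-1, 0, 1), each = 3), rep(c(-1, 0, 1), 3))[-5, , drop = FALSE]
  pos <- match(seq_len(R * C), idx)   # grid index -> vertex id
  edges <- NULL
  for (o in seq_len(nrow(offs))) {
    nr <- rows + offs[o, 1]; nc <- cols + offs[o, 2]
    ok <- nr >= 1 & nr <= R & nc >= 1 & nc <= C
    nb <- rep(NA_integer_, length(idx))
    nb[ok] <- pos[(nc[ok] - 1L) * R + nr[ok]]
    has <- !is.na(nb)
    if (any(has)) edges <- rbind(edges, cbind(which(has), nb[has]))
  }
  g <- igraph::graph_from_edgelist(
    if (is.null(edges)) matrix(integer(), 0, 2) else edges, directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, length(idx) - igraph::vcount(g)))
  comp <- igraph::components(g)
  keep_comp <- which(comp$csize >= min_voxels)
  if (!length(keep_comp))
    return(list(sig = sig & FALSE, labels = labels, table = out_tab))
  # order: decreasing size, ties by smallest row-major (row, col) voxel
  first_voxel <- vapply(keep_comp, function(cc) {
    vs <- which(comp$membership == cc)
    min(rows[vs] * (C + 1L) + cols[vs])
  }, numeric(1))
  ord <- keep_comp[order(-comp$csize[keep_comp], first_voxel)]
  tab <- data.frame(label = seq_along(ord),
                    size = comp$csize[ord],
                    centroid_row = NA_real_, centroid_col = NA_real_)
  for (i in seq_along(ord)) {
    vs <- which(comp$membership == ord[i])
    labels[idx[vs]] <- i
    tab$centroid_row[i] <- mean(rows[vs])
    tab$centroid_col[i] <- mean(cols[vs])
  }
  list(sig = labels > 0L, labels = labels, table = tab)
}

#' Voxel-wise covariate regression with standardized coefficients
#'
#' At every valid voxel, regresses the (z-scored) layer thickness on the
#' (z-scored) covariate plus any adjusters; the coefficient on the z-scored
#' predictor is the standardized regression coefficient (SRC), equal to
#' Pearson's r when there are no adjusters. Raw p values then pass through
#' the same BH-FDR + cluster-extent procedure as the group comparisons.
#'
#' @param layer_stack a [build_group_stack()]
#' @param covariate column of the covariate table to test (e.g. `"age"`,
#'   `"edss"`, `"disease_duration"`); needs >= 3 distinct values
#' @param adjusters character vector of additional covariate-table columns
#'   entered unstandardized (e.g. `c("age", "sex")`)
#' @param alpha,min_cluster_voxels,connectivity multiplicity parameters
#' @param mask optional exclusion mask
#' @return list: `src`, `p`, `sig`, `clusters`, `q_threshold`, `n_effective`
#' @export
voxelwise_regression <- function(layer_stack, covariate,
                                 adjusters = character(), alpha = 0.05,
                                 min_cluster_voxels = 9L, connectivity = 8L,
                                 mask = NULL) {
  stopifnot(inherits(layer_stack, "group_stack"))
  cov <- layer_stack$covariates
  if (!covariate %in% names(cov))
    stop("covariate not present: ", covariate)
  x <- cov[[covariate]]
  if (length(unique(x[is.finite(x)])) < 3L)
    stop("degenerate-covariate error: ", covariate,
         " has fewer than 3 distinct values")
  dims <- dim(layer_stack$data)
  n <- dims[1]; R <- dims[2]; C <- dims[3]; V <- R * C
  Y <- matrix(layer_stack$data, n, V)
  Xadj <- matrix(1, n, 1)
  colnames(Xadj) <- "(Intercept)"
  for (a in adjusters) {
    if (!a %in% names(cov)) stop("adjuster not present: ", a)
    col <- cov[[a]]
    if (is.character(col) || is.factor(col)) col <- as.numeric(factor(col))
    Xadj <- cbind(Xadj, col)
    colnames(Xadj)[ncol(Xadj)] <- a
  }
  ok_x <- is.finite(x) & apply(is.finite(Xadj), 1L, all)
  excl <- resolve_mask(mask, R, C)
  src <- pval <- rep(NA_real_, V)
  n_eff <- integer(V)
  p_par <- ncol(Xadj) + 1L
  zx_all <- as.vector(scale(x))
  for_complete <- NULL
  obs_ok <- is.finite(Y) & ok_x
  n_eff <- colSums(obs_ok)
  testable <- !as.vector(excl) & n_eff >= p_par + 1L
  complete <- testable & n_eff == sum(ok_x)
  if (any(complete)) {
    rows <- which(ok_x)
    Yc <- Y[rows, complete, drop = FALSE]
    Yz <- scale(Yc)                     # per-voxel z-scored response
    sd0 <- attr(Yz, "scaled:scale") == 0
    X <- cbind(Xadj[rows, , drop = FALSE], zx = as.vector(scale(x[rows])))
    fit <- ls_block(X, Yz)
    sigma2 <- fit$rss / fit$df
    j <- ncol(X)
    se <- sqrt(ls_var_beta(fit, j, sigma2))
    tt <- fit$beta[j, ] / se
    cols <- which(complete)
    src[cols] <- fit$beta[j, ]
    pval[cols] <- 2 * stats::pt(-abs(tt), fit$df)
    src[cols[sd0]] <- NA; pval[cols[sd0]] <- NA
  }
  for (v in which(testable & !complete)) {
    ok <- obs_ok[, v]
    yv <- Y[ok, v]
    if (stats::sd(yv) == 0) next
    X <- cbind(Xadj[ok, , drop = FALSE], zx = as.vector(scale(x[ok])))
    if (qr(X)$rank < ncol(X)) next
    f <- stats::lm.fit(X, as.vector(scale(yv)))
    dfv <- sum(ok) - ncol(X)
    s2 <- sum(f$residuals^2) / dfv
    XtXi <- chol2inv(qr.R(f$qr))
    j <- ncol(X)
    src[v] <- f$coefficients[j]
    pval[v] <- 2 * stats::pt(-abs(f$coefficients[j] / sqrt(s2 * XtXi[j, j])),
                             dfv)
  }
  p_map <- matrix(pval, R, C)
  fdr <- fdr_correct(p_map, alpha, mask = excl)
  cl <- cluster_filter(fdr$sig, min_cluster_voxels, connectivity)
  list(src = matrix(src, R, C), p = p_map, sig = cl$sig,
       clusters = cl$labels, q_threshold = fdr$cutoff,
       n_effective = matrix(n_eff, R, C))
}

#' Render significant voxels over a fundus image
#'
#' Paints only the significant voxels of a difference (um) or
#' percentage-change map over a fundus background with a diverging colormap
#' clipped at `+/- color_range`, and embeds a colorbar legend. Without a
#' fundus image a blank background with grid ticks is used.
#'
#' @param stat a `stat_map_set` (its `sig` grid selects the painted voxels)
#' @param diff_or_pct matrix to colour (same grid)
#' @param fundus optional grayscale matrix in `[0, 1]`
#' @param color_range symmetric clipping limit (e.g. 5 um or 15 %)
#' @param file optional PNG path; when given the plot is written there
#' @param label colorbar label
#' @return `file` (or `NULL` when drawing to the active device), invisibly
#' @export
render_overlay <- function(stat, diff_or_pct, fundus = NULL, color_range = 5,
                           file = NULL, label = "difference") {
  stopifnot(inherits(stat, "stat_map_set") || is.logical(stat$sig))
  sig <- stat$sig
  stopifnot(identical(dim(sig), dim(diff_or_pct)))
  if (!is.null(file)) {
    grDevices::png(file, width = 900, height = 400)
    on.exit(grDevices::dev.off())
  }
  R <- nrow(sig); C <- ncol(sig)
  pal <- grDevices::colorRampPalette(c("#2166AC", "#F7F7F7", "#B2182B"))(255)
  op <- graphics::par(mar = c(2, 2, 2, 6))
  on.exit(graphics::par(op), add = TRUE)
  if (is.null(fundus)) {
    graphics::image(seq_len(C), seq_len(R), matrix(0, C, R),
                    col = "grey85", xlab = "", ylab = "", axes = TRUE,
                    ylim = c(R + 0.5, 0.5))
  } else {
    graphics::image(seq_len(ncol(fundus)), seq_len(nrow(fundus)), t(fundus),
                    col = grDevices::gray.colors(255, 0, 1), xlab = "",
                    ylab = "", axes = TRUE,
                    ylim = c(nrow(fundus) + 0.5, 0.5))
  }
  if (any(sig, na.rm = TRUE)) {
    v <- diff_or_pct
    v[!sig] <- NA
    v <- pmin(pmax(v, -color_range), color_range)
    graphics::image(seq_len(C), seq_len(R), t(v),
                    zlim = c(-color_range, color_range), col = pal,
                    add = TRUE)
  }
  # colorbar legend in the right margin
  usr <- graphics::par("usr")
  xl <- usr[2] + 0.02 * (usr[2] - usr[1])
  xr <- usr[2] + 0.05 * (usr[2] - usr[1])
  yy <- seq(usr[3], usr[4], length.out = 256)
  graphics::par(xpd = TRUE)
  graphics::rect(xl, yy[-256], xr, yy[-1], col = pal, border = NA)
  graphics::text(xr, c(usr[3], (usr[3] + usr[4]) / 2, usr[4]),
                 labels = c(color_range, 0, -color_range), pos = 4, cex = 0.8)
  graphics::text(xr, usr[4] - 0.06 * (usr[4] - usr[3]), label, pos = 4,
                 cex = 0.8)
  invisible(file)
}
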