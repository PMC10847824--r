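test_that("identical group samples give t = 0 and p = 1", {
  cov <- data.frame(subject_id = sprintf("S%d", 1:6), eye = "OS",
                    group = rep(c("HC", "RMS"), each = 3))
  d <- array(rep(c(1, 2, 3, 1, 2, 3), 4), c(6, 2, 2))
  st <- stack_from_array(d, cov)
  sm <- voxelwise_glm(st, spec = glm_spec(covariates = character(0)))
  expect_equal(sm$stat, matrix(0, 2, 2), tolerance = 1e-12)
  expect_equal(sm$p, matrix(1, 2, 2), tolerance = 1e-12)
  expect_false(any(sm$sig))
})

test_that("with no covariates the t map equals the pooled two-sample t", {
  set.seed(14)
  n <- 16
  cov <- random_cov(n)
  d <- array(rnorm(n * 4 * 5, 100, 8), c(n, 4, 5))
  st <- stack_from_array(d, cov)
  sm <- voxelwise_glm(st, spec = glm_spec(covariates = character(0)))
  g2 <- cov$group == "RMS"
  for (r in 1:4) for (cc in 1:5) {
    x <- d[g2, r, cc]; y <- d[!g2, r, cc]
    sp <- sqrt(((length(x) - 1) * var(x) + (length(y) - 1) * var(y)) /
                 (length(x) + length(y) - 2))
    t_pool <- (mean(x) - mean(y)) / (sp * sqrt(1 / length(x) + 1 / length(y)))
    expect_equal(sm$stat[r, cc], t_pool, tolerance = 1e-10)
    expect_equal(sm$diff[r, cc], mean(x) - mean(y), tolerance = 1e-12)
  }
})

test_that("GLM coefficients match a brute-force per-voxel lm solve", {
  set.seed(15)
  for (rep in 1:5) {
    n <- sample(12:24, 1)
    cov <- random_cov(n)
    d <- array(rnorm(n * 3 * 4, 80, 6), c(n, 3, 4))
    ret <- array(rnorm(n * 3 * 4, 300, 15), c(n, 3, 4))
    st <- stack_from_array(d, cov)
    rt <- stack_from_array(ret, cov, layer = "Retina")
    sm <- voxelwise_glm(st, rt, glm_spec())
    for (r in 1:3) for (cc in 1:4) {
      fit <- lm(d[, r, cc] ~ factor(cov$group, levels = c("HC", "RMS")) +
                  cov$age + factor(cov$sex) + ret[, r, cc])
      co <- summary(fit)$coefficients
      expect_equal(unname(sm$beta[[2]][r, cc]), unname(co[2, 1]),
                   tolerance = 1e-10)
      expect_equal(unname(sm$beta$retina_voxel[r, cc]), unname(co[5, 1]),
                   tolerance = 1e-10)
      expect_equal(unname(sm$stat[r, cc]), unname(co[2, 3]),
                   tolerance = 1e-10)
      expect_equal(unname(sm$p[r, cc]), unname(co[2, 4]), tolerance = 1e-10)
    }
  }
})

test_that("voxels with missing subjects fall back to complete-case fits", {
  set.seed(16)
  n <- 20
  cov <- random_cov(n)
  d <- array(rnorm(n * 2 * 3, 80, 6), c(n, 2, 3))
  ret <- array(rnorm(n * 2 * 3, 300, 15), c(n, 2, 3))
  d[1:4, 1, 1] <- NA                 # partial voxel
  d[, 2, 2] <- NA                    # untestable voxel
  st <- stack_from_array(d, cov); rt <- stack_from_array(ret, cov, "Retina")
  sm <- voxelwise_glm(st, rt, glm_spec())
  expect_identical(sm$n_effective[1, 1], n - 4L)
  ok <- !is.na(d[, 1, 1])
  fit <- lm(d[ok, 1, 1] ~ factor(cov$group[ok], levels = c("HC", "RMS")) +
              cov$age[ok] + factor(cov$sex[ok]) + ret[ok, 1, 1])
  expect_equal(unname(sm$stat[1, 1]),
               unname(summary(fit)$coefficients[2, 3]), tolerance = 1e-10)
  expect_true(is.na(sm$stat[2, 2]))
})

test_that("the omnibus F matches the incremental F of a brute-force fit", {
  set.seed(17)
  n <- 24
  cov <- random_cov(n, groups = c("HC", "CIS", "RMS", "PMS"))
  d <- array(rnorm(n * 2 * 2, 80, 6), c(n, 2, 2))
  st <- stack_from_array(d, cov)
  sm <- voxelwise_glm(st, spec = glm_spec(contrast = "omnibus-F",
                                          covariates = "age"))
  for (r in 1:2) for (cc in 1:2) {
    full <- lm(d[, r, cc] ~ relevel(factor(cov$group), "HC") + cov$age)
    red <- lm(d[, r, cc] ~ cov$age)
    a <- anova(red, full)
    expect_equal(sm$stat[r, cc], a$F[2], tolerance = 1e-10)
    expect_equal(sm$p[r, cc], a$`Pr(>F)`[2], tolerance = 1e-10)
  }
})

test_that("BH step-up matches the hand-computed rejection set and cutoff", {
  p <- matrix(c(0.01, 0.02, 0.03, 0.04), 2, 2)
  res <- fdr_correct(p, alpha = 0.05)
  expect_true(all(res$sig))                       # largest i with p <= i a/m is 4
  expect_equal(res$cutoff, 0.04)
  res1 <- fdr_correct(matrix(1, 3, 3), 0.05)
  expect_false(any(res1$sig))
  expect_true(is.na(res1$cutoff))
  # a mixed case checked against an explicit step-up
  set.seed(18)
  pv <- matrix(runif(40)^2, 5, 8)
  got <- fdr_correct(pv, 0.05)
  ps <- sort(as.vector(pv)); m <- length(ps)
  k <- max(c(0, which(ps <= seq_len(m) * 0.05 / m)))
  manual <- if (k == 0) pv > 1 else pv <= ps[k]
  expect_identical(got$sig, manual)
  # empty family warns and rejects nothing
  expect_warning(r0 <- fdr_correct(matrix(NA_real_, 2, 2), 0.05), "empty")
  expect_false(any(r0$sig))
})

test_that("cluster filter drops small components and labels by size", {
  sig <- matrix(FALSE, 12, 12)
  sig[2:4, 2:4] <- TRUE              # 9 voxels: survives at default
  sig[8, 8] <- TRUE                  # isolated voxel: removed
  res <- cluster_filter(sig, 9, 8)
  expect_equal(sum(res$sig), 9)
  expect_false(res$sig[8, 8])
  # empty grid
  r0 <- cluster_filter(matrix(FALSE, 3, 3))
  expect_equal(sum(r0$labels), 0)
  # one 8-voxel and one 10-voxel component: only the larger labeled
  sig2 <- matrix(FALSE, 12, 20)
  sig2[2:3, 2:5] <- TRUE             # 8 voxels
  sig2[8:9, 10:14] <- TRUE           # 10 voxels
  r2 <- cluster_filter(sig2, 9, 8)
  expect_equal(sum(r2$sig), 10)
  expect_equal(max(r2$labels), 1L)
  expect_true(all(r2$labels[8:9, 10:14] == 1L))
  # diagonal voxels connect under 8- but not 4-connectivity
  diag_sig <- matrix(FALSE, 6, 6)
  diag_sig[cbind(1:5, 1:5)] <- TRUE
  expect_equal(sum(cluster_filter(diag_sig, 5, 8)$sig), 5)
  expect_equal(sum(cluster_filter(diag_sig, 5, 4)$sig), 0)
})

test_that("cluster labeling agrees with an independent flood fill", {
  set.seed(19)
  for (conn in c(4L, 8L)) {
    sig <- matrix(runif(30 * 40) < 0.3, 30, 40)
    got <- cluster_filter(sig, 1L, conn)
    oracle <- flood_fill_components(sig, conn)
    # same partition: labels must be a bijection of oracle labels
    expect_identical(got$sig, sig)
    for (l in seq_len(max(oracle)))
      expect_equal(length(unique(got$labels[oracle == l])), 1L)
    expect_equal(max(got$labels), max(oracle))
    # sizes sorted decreasing
    expect_false(is.unsorted(-got$table$size))
  }
})

test_that("alpha and extent thresholds act monotonically", {
  set.seed(20)
  tpl <- tiny_template()
  coh <- make_cohort(tpl, groups = list(
    list(label = "HC", n = 12),
    list(label = "RMS", n = 12,
         effects = list(effect_spec("GCIPL", -8, "disc",
                                    center = tpl$fovea_center + c(0, 30),
                                    radius_vox = 6)))),
    jitter_max = c(0, 0), seed = 99)
  tg <- tiny_target()
  regs <- lapply(coh$subjects, function(s)
    register_scan(s$maps, s$boundaries, tg)$maps)
  st <- build_group_stack(lapply(regs, `[[`, "GCIPL"), coh$covariates)
  base <- voxelwise_glm(st, spec = glm_spec(covariates = "age"))
  tighter <- voxelwise_glm(st, spec = glm_spec(covariates = "age",
                                               alpha = 0.01))
  expect_true(all(base$sig[tighter$sig]))   # shrinking alpha adds nothing
  bigger <- voxelwise_glm(st, spec = glm_spec(covariates = "age",
                                              min_cluster_voxels = 25))
  expect_lte(max(bigger$clusters), max(base$clusters))
  expect_true(all(base$sig[bigger$sig]))
})

test_that("standardized regression coefficients behave like correlations", {
  set.seed(22)
  n <- 30
  cov <- random_cov(n, "RMS")
  # response exactly linear in age -> SRC = 1 everywhere
  d <- array(rep(2 * cov$age, 6), c(n, 2, 3))
  st <- stack_from_array(d, cov)
  res <- voxelwise_regression(st, "age")
  expect_equal(res$src, matrix(1, 2, 3), tolerance = 1e-10)
  # SRC equals Pearson r at every voxel when no adjusters
  d2 <- array(rnorm(n * 2 * 3, 100, 10), c(n, 2, 3))
  st2 <- stack_from_array(d2, cov)
  res2 <- voxelwise_regression(st2, "age")
  for (r in 1:2) for (cc in 1:3)
    expect_equal(res2$src[r, cc], cor(cov$age, d2[, r, cc]),
                 tolerance = 1e-10)
  # independent covariate: mean SRC near zero (n = 200 Monte-Carlo)
  set.seed(23)
  cov3 <- random_cov(200, "RMS")
  d3 <- array(rnorm(200 * 4 * 4, 100, 10), c(200, 4, 4))
  res3 <- voxelwise_regression(stack_from_array(d3, cov3), "age",
                               adjusters = c("sex"))
  expect_lt(abs(mean(res3$src)), 0.05)
  # constant covariate rejected
  cov4 <- random_cov(10, "RMS"); cov4$edss <- 3
  expect_error(voxelwise_regression(stack_from_array(
    array(1, c(10, 2, 2)), cov4), "edss"), "degenerate-covariate")
})

test_that("overlays render significant voxels and clip at the color range", {
  set.seed(24)
  sm <- list(sig = matrix(FALSE, 10, 20))
  class(sm) <- "stat_map_set"
  d <- matrix(0, 10, 20)
  f <- file.path(tempdir(), "ov0.png")
  render_overlay(sm, d, color_range = 5, file = f)
  expect_true(file.exists(f) && file.size(f) > 0)
  sm$sig[5, 5] <- TRUE
  d[5, 5] <- -12                      # clips at the colormap minimum
  f2 <- file.path(tempdir(), "ov1.png")
  render_overlay(sm, d, color_range = 5, file = f2)
  expect_true(file.exists(f2) && file.size(f2) > 0)
  # with a fundus background
  f3 <- file.path(tempdir(), "ov2.png")
  render_overlay(sm, d, fundus = matrix(runif(200), 10, 20),
                 color_range = 15, file = f3)
  expect_true(file.exists(f3) && file.size(f3) > 0)
})
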