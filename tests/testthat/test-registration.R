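test_that("intensity normalization is an exact affine standardization", {
  geom <- oct_geometry(n_bscans = 4L, n_ascans = 6L)
  set.seed(8)
  x <- array(rnorm(4 * 10 * 6, mean = 50, sd = 10), c(4, 10, 6))
  v <- oct_volume(x, geom, "OS")
  out <- normalize_intensity(v, 100, 20)
  expect_equal(mean(out$intensity), 100, tolerance = 1e-10)
  expect_equal(sd(out$intensity), 20, tolerance = 1e-10)
  # rank order preserved
  expect_identical(order(out$intensity), order(v$intensity))
  # already at reference -> unchanged
  again <- normalize_intensity(out, 100, 20)
  expect_equal(again$intensity, out$intensity, tolerance = 1e-12)
  # zero variance rejected
  expect_error(normalize_intensity(oct_volume(array(1, c(4, 10, 6)), geom,
                                              "OS"), 0, 1),
               "degenerate")
})

test_that("extract_retina masks exactly the out-of-band depth samples", {
  geom <- oct_geometry(n_bscans = 3L, n_ascans = 4L,
                       axial_resolution_um = 10)
  n_depth <- 50L                    # depths 0, 10, ..., 490 um
  set.seed(9)
  v <- oct_volume(array(rnorm(3 * n_depth * 4), c(3, n_depth, 4)), geom, "OS")
  ilm <- matrix(100, 3, 4); bm <- matrix(400, 3, 4)
  ilm[1, 2] <- 150; bm[1, 2] <- 150   # degenerate A-line: fully masked
  b <- boundary_set(list("ILM" = ilm, "RNFL/GCL" = ilm, "IPL/INL" = ilm,
                         "INL/OPL" = ilm, "BM" = bm), geom, "OS")
  out <- extract_retina(v, b)
  # counting oracle: per A-line sum of out-of-band samples (zero-span
  # A-lines count as fully masked)
  depth <- (seq_len(n_depth) - 1) * 10
  expected <- 0L
  for (r in 1:3) for (cc in 1:4)
    expected <- expected +
      if (bm[r, cc] <= ilm[r, cc]) n_depth
      else sum(depth < ilm[r, cc] | depth > bm[r, cc])
  expect_identical(sum(is.na(out$intensity)), as.integer(expected))
  # within-retina intensities unchanged
  keep <- !is.na(out$intensity)
  expect_identical(out$intensity[keep], v$intensity[keep])
  # ILM == BM masks the entire A-line
  expect_true(all(is.na(out$intensity[1, , 2])))
})

test_that("fovea detection finds the minimum, with centroid tie-break", {
  geom <- oct_geometry()
  # brute-force argmin oracle on the synthetic pit
  tpl <- tiny_template()
  raw_argmin <- which(tpl$maps$Retina$values ==
                        min(tpl$maps$Retina$values), arr.ind = TRUE)
  expect_equal(detect_fovea(tpl$maps$Retina, sigma_um = 0),
               as.integer(raw_argmin[1, ]))
  expect_equal(detect_fovea(tpl$maps$Retina), tpl$fovea_center)
  # single perturbed minimum on a constant map
  v <- matrix(300, 25, 1024)
  v[3, 7] <- 200
  m <- thickness_map(v, "Retina", "L", geom)
  expect_equal(detect_fovea(m, sigma_um = 0), c(3L, 7L))
  # plateau of minima rows 10-12 at col 500 -> centroid (11, 500)
  v2 <- matrix(300, 25, 1024)
  v2[10:12, 500] <- 200
  m2 <- thickness_map(v2, "Retina", "L", geom)
  expect_equal(detect_fovea(m2, sigma_um = 0), c(11L, 500L))
  # all-invalid map errors
  expect_error(detect_fovea(thickness_map(matrix(NA_real_, 25, 1024),
                                          "Retina", "L", geom)),
               "no-fovea")
})

test_that("global translation is the fovea difference and composes exactly", {
  tg <- target_grid(25, 1024, c(12, 512),
                    geometry = oct_geometry())
  expect_identical(compute_global_translation(c(10, 500), tg), c(2L, 12L))
  expect_identical(compute_global_translation(c(12, 512), tg), c(0L, 0L))
  # composition oracle: detect_fovea(translate(map, delta)) == target fovea
  tpl <- tiny_template()
  tg2 <- tiny_target()
  delta <- compute_global_translation(c(10, 50), tg2)
  shifted <- translate_map(tpl$maps$Retina, c(10, 50) - tpl$fovea_center)
  back <- translate_map(shifted, delta)
  expect_equal(detect_fovea(back, sigma_um = 0), tg2$fovea_position)
})

test_that("per-A-line affine maps its anchor surfaces exactly", {
  expect_equal(fit_aline_affine(100, 400, 110, 410), list(a = 1, b = 10))
  expect_equal(fit_aline_affine(100, 400, 100, 250), list(a = 0.5, b = 50))
  set.seed(4)
  for (i in 1:50) {
    si <- runif(1, 50, 150); sb <- si + runif(1, 100, 400)
    ti <- runif(1, 50, 150); tb <- ti + runif(1, 100, 400)
    f <- fit_aline_affine(si, sb, ti, tb)
    expect_lt(abs(f$a * si + f$b - ti), 1e-9)
    expect_lt(abs(f$a * sb + f$b - tb), 1e-9)
  }
  expect_error(fit_aline_affine(100, 100, 50, 60), "degenerate")
})

test_that("registration recovers integer shifts of the template exactly", {
  tpl <- tiny_template()
  tg <- tiny_target()
  for (delta in list(c(0, 0), c(2, 5), c(-3, -5), c(5, 1))) {
    s <- sample_subject(tpl, noise_sd_um = 0, jitter = delta)
    r <- register_scan(s$maps, s$boundaries, tg)
    expect_identical(r$transform$translation, -as.integer(delta))
    # registered map equals template at mutually valid voxels
    ok <- !is.na(r$maps$GCIPL$values)
    expect_equal(r$maps$GCIPL$values[ok], tpl$maps$GCIPL$values[ok],
                 tolerance = 1e-12)
    expect_true(r$maps$GCIPL$registered)
  }
})

test_that("integer translation never alters surviving voxel values", {
  tpl <- tiny_template()
  m <- tpl$maps$RNFL
  t1 <- translate_map(m, c(2, -3))
  ok <- !is.na(t1$values)
  src <- m$values[1:23, 4:128]
  expect_identical(t1$values[3:25, 1:125], src)
  expect_true(all(is.na(t1$values[1:2, ])))
})

test_that("one shared transform registers all four maps consistently", {
  tpl <- tiny_template()
  tg <- tiny_target()
  s <- sample_subject(tpl, noise_sd_um = 0, jitter = c(1, -4))
  r <- register_scan(s$maps, s$boundaries, tg)
  expect_length(r$transform$translation, 2L)
  for (layer in c("RNFL", "GCIPL", "INL", "Retina")) {
    ok <- !is.na(r$maps[[layer]]$values)
    expect_equal(r$maps[[layer]]$values[ok], tpl$maps[[layer]]$values[ok],
                 tolerance = 1e-12)
  }
  # identity case: no translation, unchanged values
  r0 <- register_scan(tpl$maps, tpl$boundaries, tg)
  expect_identical(r0$transform$translation, c(0L, 0L))
  expect_equal(r0$maps$INL$values, tpl$maps$INL$values, tolerance = 1e-12)
})

test_that("registering identical maps gives order-independent group maps", {
  tpl <- tiny_template()
  tg <- tiny_target()
  subs <- lapply(1:4, function(i) {
    s <- sample_subject(tpl, noise_sd_um = 0, jitter = c(i %% 3 - 1, i - 2))
    register_scan(s$maps, s$boundaries, tg)$maps$GCIPL
  })
  mean_map <- function(maps) {
    arr <- simplify2array(lapply(maps, `[[`, "values"))
    apply(arr, c(1, 2), mean)
  }
  expect_equal(mean_map(subs), mean_map(rev(subs)))
})

test_that("cohort-mean target lands on the same fovea as the reference", {
  tpl <- tiny_template()
  set.seed(77)
  scans <- lapply(1:5, function(i)
    sample_subject(tpl, noise_sd_um = 1, jitter_max = c(1, 3)))
  tg <- build_target(scans, policy = "cohort-mean-template")
  expect_identical(tg$source, "cohort-mean-template")
  expect_lte(max(abs(tg$fovea_position - scans[[1]]$fovea_center)), 2)
  expect_false(is.null(tg$ilm))
})
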