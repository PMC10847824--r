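test_that("the template is deterministic and anatomically consistent", {
  spec <- template_spec(geometry = tiny_geom())
  t1 <- make_template(spec)
  t2 <- make_template(spec)
  expect_identical(t1$maps$Retina$values, t2$maps$Retina$values)
  # the pit is the unique retinal minimum at the declared fovea
  expect_equal(detect_fovea(t1$maps$Retina, sigma_um = 0), spec$fovea_center)
  # boundaries satisfy the surface-order invariant (constructor enforces it)
  expect_s3_class(t1$boundaries, "boundary_set")
  # thickness maps recomputed from boundaries match the emitted maps
  maps_b <- thickness_from_boundaries(t1$boundaries)
  for (layer in c("RNFL", "GCIPL", "INL", "Retina"))
    expect_equal(maps_b[[layer]]$values, t1$maps[[layer]]$values,
                 tolerance = 1e-9)
  # pit depth 0 removes the pit: Retina constant up to the RNFL gradient
  flat <- make_template(template_spec(geometry = tiny_geom(),
                                      pit_depth_um = 0,
                                      texture_amp_um = 0))
  rng <- range(flat$maps$Retina$values - flat$components$RNFL)
  expect_lt(diff(rng), 1e-9)
  # RNFL increases toward the ONH (left) side
  prof <- colMeans(flat$maps$RNFL$values)
  expect_false(is.unsorted(-prof))
})

test_that("subject sampling honours jitter, noise level, and determinism", {
  tpl <- tiny_template()
  # noise 0, jitter (0,0): equals the template
  set.seed(50)
  s0 <- sample_subject(tpl, noise_sd_um = 0, jitter = c(0, 0))
  expect_equal(s0$maps$Retina$values, tpl$maps$Retina$values,
               tolerance = 1e-12)
  # noise 0, known jitter: registration recovers the negative
  s1 <- sample_subject(tpl, noise_sd_um = 0, jitter = c(2, 12))
  r <- register_scan(s1$maps, s1$boundaries, tiny_target())
  expect_identical(r$transform$translation, c(-2L, -12L))
  # per-voxel SD of the noise ~ the requested level (Monte-Carlo, n = 100)
  set.seed(51)
  vox <- replicate(100, {
    s <- sample_subject(tpl, noise_sd_um = 1, jitter = c(0, 0))
    s$maps$GCIPL$values[5, 20]
  })
  expect_equal(sd(vox), 1, tolerance = 0.3)
  # same seed -> identical subject
  set.seed(52); a <- sample_subject(tpl, 1.5)
  set.seed(52); b <- sample_subject(tpl, 1.5)
  expect_identical(a$maps$Retina$values, b$maps$Retina$values)
  expect_identical(a$jitter, b$jitter)
  # jitter beyond the margin errors
  expect_error(sample_subject(tpl, jitter = c(50, 0)), "out of range")
})

test_that("cohorts are reproducible, labelled, and carry ground truth", {
  tpl <- tiny_template()
  groups <- list(list(label = "HC", n = 3),
                 list(label = "RMS", n = 2,
                      effects = list(effect_spec("GCIPL", -5, "disc",
                                                 radius_vox = 5))))
  c1 <- make_cohort(tpl, groups, seed = 60)
  c2 <- make_cohort(tpl, groups, seed = 60)
  expect_identical(c1$covariates, c2$covariates)
  expect_identical(c1$subjects[[5]]$maps$GCIPL$values,
                   c2$subjects[[5]]$maps$GCIPL$values)
  expect_identical(c1$covariates$group, rep(c("HC", "RMS"), c(3, 2)))
  expect_identical(dim(c1$ground_truth$jitters), c(5L, 2L))
  expect_true(all(vapply(c1$subjects,
                         function(s) inherits(s$boundaries, "boundary_set"),
                         TRUE)))
  expect_error(make_cohort(tpl, list(list(label = "HC", n = 1),
                                     list(label = "HC", n = 1))),
               "unique")
})

test_that("group means recover the template and the injected effect", {
  tpl <- tiny_template()
  disc <- effect_spec("GCIPL", -5, "disc",
                      center = tpl$fovea_center + c(0, 30), radius_vox = 8)
  coh <- make_cohort(tpl, list(list(label = "HC", n = 40),
                               list(label = "RMS", n = 40,
                                    effects = list(disc))),
                     noise_sd_um = 1.5, jitter_max = c(0, 0),
                     subject_scale_sd = 0, seed = 61)
  is_hc <- coh$covariates$group == "HC"
  hc_mean <- Reduce(`+`, lapply(coh$subjects[is_hc],
                                function(s) s$maps$GCIPL$values)) / 40
  # CLT oracle: HC mean ~ template within ~4 SE
  se <- 1.5 / sqrt(40)
  expect_lt(max(abs(hc_mean - tpl$maps$GCIPL$values)), 5 * se)
  # Eq-style arithmetic on the known baseline inside the disc
  msk <- coh$ground_truth$effect_masks$RMS[[1]]
  rms_mean <- Reduce(`+`, lapply(coh$subjects[!is_hc],
                                 function(s) s$maps$GCIPL$values)) / 40
  pct <- (mean(rms_mean[msk]) - mean(hc_mean[msk])) / mean(hc_mean[msk]) * 100
  expect_equal(pct, -5 / mean(tpl$maps$GCIPL$values[msk]) * 100,
               tolerance = 0.75)
})

test_that("retest stacks realize the requested variance components", {
  tpl <- tiny_template()
  # zero within-noise -> Sw = 0 and ICC ~ 1
  s0 <- make_retest(tpl, n_subjects = 8, between_sd_um = 5,
                    within_sd_um = 0, seed = 70)
  expect_true(all(voxelwise_sw(s0) == 0))
  expect_true(all(voxelwise_icc(s0) > 0.999, na.rm = TRUE))
  # equal components -> ICC ~ 0.5 at n = 50 (variance-component formula)
  s1 <- make_retest(tpl, n_subjects = 50, between_sd_um = 5,
                    within_sd_um = 5, seed = 71)
  expect_equal(mean(voxelwise_icc(s1)), 0.5, tolerance = 0.05)
  expect_equal(attr(s1, "ground_truth")$icc, 0.5)
  # determinism
  s2 <- make_retest(tpl, n_subjects = 5, seed = 72)
  s3 <- make_retest(tpl, n_subjects = 5, seed = 72)
  expect_identical(s2$data, s3$data)
})

test_that("effect footprints match their geometric definitions", {
  geom <- tiny_geom()
  ctr <- c(13, 64)
  m_disc <- effect_mask(effect_spec("RNFL", -1, "disc", center = ctr,
                                    radius_vox = 4), geom, ctr)
  for (r in seq_len(geom$n_bscans)) for (cc in seq_len(geom$n_ascans))
    expect_identical(m_disc[r, cc],
                     sqrt((r - 13)^2 + (cc - 64)^2) <= 4)
  m_ann <- effect_mask(effect_spec("INL", 2, "annulus", r_in_um = 500,
                                   r_out_um = 1500), geom, ctr)
  expect_false(m_ann[13, 64])
  expect_gt(sum(m_ann), 0)
  m_sec <- effect_mask(effect_spec("RNFL", -2, "sector",
                                   angle_deg = c(315, 45)), geom, ctr)
  expect_true(m_sec[13, 100])         # temporal (right) side, angle ~ 0
  expect_false(m_sec[13, 20])         # nasal side, angle ~ 180
})
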