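test_that("thickness surface follows its closed form", {
  p <- default_surface()
  # flat limit: no pit, no dome
  flat <- simulate_thickness_surface(
    retina_surface_params(pit_depth_um = 0, dome_amplitude_um = 0), 16, 16)
  expect_true(all(flat$thickness_um == 300))

  map <- simulate_thickness_surface(p, 64, 64)
  centre_truth <- surface_formula(p, 0)  # plateau + dome term at 0 - pit
  expect_equal(centre_truth, 300 + 20 * exp(-2) - 75)
  # nearest raster point to the centre
  co <- map_coordinates(map)
  i <- which.min(abs(co$y_mm)); j <- which.min(abs(co$x_mm))
  r_ij <- sqrt(co$y_mm[i]^2 + co$x_mm[j]^2)
  expect_equal(map$thickness_um[i, j], surface_formula(p, r_ij))
  # grid corners lie at exactly r = sqrt(2) * 3 mm
  expect_equal(map$thickness_um[1, 1], surface_formula(p, sqrt(2) * 3))

  # doubling the pit depth moves the centre but barely the corner
  p2 <- retina_surface_params(pit_depth_um = 150)
  expect_lt(surface_formula(p2, 0), surface_formula(p, 0))
  expect_equal(surface_formula(p, 0) - surface_formula(p2, 0), 75)
  expect_lt(abs(surface_formula(p2, sqrt(2) * 3) -
                surface_formula(p, sqrt(2) * 3)), 1)
})

test_that("surface parameter invariants are enforced", {
  expect_error(retina_surface_params(plateau_thickness_um = 50,
                                     pit_depth_um = 75),
               "positive")
  expect_error(retina_surface_params(pit_depth_um = -1))
  expect_error(retina_surface_params(pit_width_mm = 0))
})

test_that("rendered volumes put the brightest voxels at the truth surfaces", {
  map <- small_map()
  r <- render_oct_volume(map, seed = 1)
  for (idx in list(c(3, 5), c(16, 16), c(30, 2))) {
    prof <- r$volume$intensities[idx[1], idx[2], ]
    top2 <- sort(order(prof, decreasing = TRUE)[1:2])
    expect_equal(top2, sort(c(r$truth$ilm[idx[1], idx[2]],
                              r$truth$bm[idx[1], idx[2]])))
  }
  # determinism: byte-identical repeat renders
  r2 <- render_oct_volume(map, seed = 1)
  expect_identical(r$volume$intensities, r2$volume$intensities)
  r3 <- render_oct_volume(map, noise_sd = 5, seed = 4)
  r4 <- render_oct_volume(map, noise_sd = 5, seed = 4)
  expect_identical(r3$volume$intensities, r4$volume$intensities)
})

test_that("render artifacts behave as specified", {
  map <- small_map()
  # blink: bands suppressed to the background level
  rb <- render_oct_volume(map, blink_bscans = 10:12, seed = 1)
  expect_true(all(rb$volume$intensities[10:12, , ] <=
                    max(rb$volume$intensities[10:12, , 1])))
  expect_true(all(rb$volume$intensities[10:12, , ] == 10))
  # clip: truth invalidated on the margin columns
  rc <- render_oct_volume(map, clip_ascans = 1:3, seed = 1)
  expect_true(all(!rc$truth$valid[, 1:3]))
  expect_true(all(rc$truth$valid[, 4:32]))
  # motion: truth shifted with the B-scan
  rm_ <- render_oct_volume(map, motion_bscans = 7, seed = 2)
  s <- rm_$motion_shifts[["7"]]
  r0 <- render_oct_volume(map, seed = 2)
  expect_equal(rm_$truth$ilm[7, ], r0$truth$ilm[7, ] + s)
  # depth range too small without clip flag -> render error
  expect_error(render_oct_volume(map, n_depth = 100), "depth range")
})

test_that("genotype dosages follow Hardy-Weinberg and are reproducible", {
  v <- variant_spec("rs1", maf = 0.5)
  g <- simulate_genotypes(1e5, v, seed = 1)
  expect_true(all(g %in% 0:2))
  # mean dosage within 3 binomial SE of 2 * maf
  se <- sqrt(2 * 0.5 * 0.5 / 1e5)
  expect_lt(abs(mean(g) - 1.0), 3 * se)
  # genotype-class frequencies match HWE within 3 SE
  v2 <- variant_spec("rs2", maf = 0.2)
  g2 <- simulate_genotypes(5e4, v2, seed = 2)
  for (k in 0:2) {
    p_exp <- choose(2, k) * 0.2^k * 0.8^(2 - k)
    se_k <- sqrt(p_exp * (1 - p_exp) / 5e4)
    expect_lt(abs(mean(g2 == k) - p_exp), 3 * se_k)
  }
  expect_identical(simulate_genotypes(100, v, seed = 9),
                   simulate_genotypes(100, v, seed = 9))
  expect_error(variant_spec("bad", maf = 0.6), "maf")
  expect_error(simulate_genotypes(10, data.frame(id = "x", maf = 0)), "maf")
})

test_that("cohort simulation injects effects and respects degenerate limits", {
  # degenerate: no genetics, no noise, no covariate effects
  cfg0 <- cohort_config(20, variants = variant_spec("rs0"),
                        covariate_effects = NULL, noise_sd_um = 0,
                        map_noise_sd_um = 0, seed = 3)
  coh0 <- simulate_cohort(cfg0, keep_maps = FALSE)
  expect_equal(length(unique(coh0$eyes$cft_true_um)), 1)

  # eye_correlation = 1: left and right truth identical per participant
  cfg1 <- cohort_config(30, variants = variant_spec("rs0"),
                        covariate_effects = NULL, eye_correlation = 1,
                        seed = 4)
  coh1 <- simulate_cohort(cfg1, keep_maps = FALSE)
  left <- coh1$eyes[coh1$eyes$eye == "left", ]
  right <- coh1$eyes[coh1$eyes$eye == "right", ]
  expect_equal(left$plateau_um, right$plateau_um)
  expect_equal(left$cft_true_um, right$cft_true_um)

  # foveal variant at 10 um/allele: truth group contrast ~ 20 um (dosage 2 vs 0)
  v <- variant_spec("rs_fov", 1, 1e6, 0.3, "foveal", beta_um_per_allele = 10)
  cfg <- cohort_config(2000, variants = v, seed = 5)
  coh <- simulate_cohort(cfg, keep_maps = FALSE)
  eL <- coh$eyes[coh$eyes$eye == "left", ]
  d <- coh$dosages[, "rs_fov"]
  diff20 <- mean(eL$cft_true_um[d == 2]) - mean(eL$cft_true_um[d == 0])
  mc_se <- sqrt(var(eL$cft_true_um[d == 2]) / sum(d == 2) +
                var(eL$cft_true_um[d == 0]) / sum(d == 0))
  expect_lt(abs(diff20 - 20), 3 * mc_se)

  # determinism
  expect_identical(simulate_cohort(cfg, keep_maps = FALSE)$eyes, coh$eyes)
  # config validation
  expect_error(cohort_config(1), "n_participants")
  expect_error(cohort_config(10, eye_correlation = 2), "eye_correlation")
  expect_error(cohort_config(10, artifact_rates = c(blink = 1.5)),
               "probabilities")
})

test_that("MR summary simulation has the stated structure", {
  # noiseless limit: ratios equal the causal effect exactly
  s0 <- simulate_mr_summary(10, 0.7, se_outcome = 0, pleiotropy_sd = 0,
                            seed = 1)
  expect_equal(s0$outcome$beta / s0$exposure$beta, rep(0.7, 10))
  # null effect: exposure and outcome effects uncorrelated
  s1 <- simulate_mr_summary(2000, 0, seed = 2)
  expect_lt(abs(cor(s1$exposure$beta, s1$outcome$beta)), 3 / sqrt(2000))
  # determinism
  expect_identical(simulate_mr_summary(10, 0.5, seed = 3),
                   simulate_mr_summary(10, 0.5, seed = 3))
  expect_error(simulate_mr_summary(2, 0.5))
})
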