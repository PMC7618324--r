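test_that("creep generator honours the protocol and ground truth", {
  # elastic solid: no creep during the hold
  rec <- gen_creep_experiment(ground_truth(beta_true = 0))
  hold <- rec$indentation_um[rec$phase == "hold"]
  expect_lt(diff(range(hold)), 1e-9)
  # alpha = 1: force exactly linear in t during the ramp
  rec1 <- gen_creep_experiment(ground_truth(alpha_true = 1))
  ramp <- rec1$phase == "ramp"
  fit <- lm(rec1$force_nN[ramp] ~ rec1$time_s[ramp])
  expect_lt(max(abs(residuals(fit))), 1e-9)
  # default protocol: 50 nN hold, 3 s, 89.3 um bead
  expect_equal(max(rec$force_nN), 50)
  expect_equal(rec$bead_radius_um, 89.3 / 2)
  expect_equal(max(rec$time_s) - min(rec$time_s[rec$phase == "hold"]), 3,
               tolerance = 0.02)
})

test_that("generators are bit-identical under a fixed seed", {
  gt <- ground_truth(k0_true = 1000, beta_true = 0.3, noise_sd = 0.1,
                     seed = 7L)
  r1 <- gen_creep_experiment(gt)
  r2 <- gen_creep_experiment(gt)
  expect_identical(r1$indentation_um, r2$indentation_um)
  c1 <- gen_cohort(3L, seed = 11L, records = FALSE)
  c2 <- gen_cohort(3L, seed = 11L, records = FALSE)
  expect_identical(c1$beta_true, c2$beta_true)
  st <- droplet_site()
  gt2 <- ground_truth(noise_sd = 0.3, seed = 5L)
  dp <- list(volume_nl = 4, gamma_N_m = 0.001)
  s1 <- gen_droplet_series(gt2, st, dp, duration_h = 6, n_frames = 6L)
  s2 <- gen_droplet_series(gt2, st, dp, duration_h = 6, n_frames = 6L)
  expect_identical(s1$frames$aspect, s2$frames$aspect)
})

test_that("ground truth validates its fields by name", {
  expect_error(ground_truth(beta_true = 1.5), "beta_true")
  expect_error(ground_truth(alpha_true = 0.5), "alpha_true")
  expect_error(ground_truth(k0_true = NaN), "k0_true")
  expect_error(ground_truth(k0_true = -5), "k0_true")
  expect_error(ground_truth(noise_sd = -1), "noise_sd")
})

test_that("cross-section generator: constant annulus and dorsal thinning", {
  sec <- gen_cross_section(list(kind = "annulus", R_inner = 50,
                                thickness = 10, n_points = 360L))
  pr <- thickness_profile(sec, n_samples = 60L)
  expect_equal(pr$samples$thickness, rep(10, nrow(pr$samples)),
               tolerance = 1e-3)
  # dorsally thinned: profile increases monotonically from s=0 to s=1
  sec2 <- gen_cross_section(list(kind = "dorsally_thinned", R_inner = 50,
                                 thickness_dorsal = 10,
                                 thickness_ventral = 40, n_points = 360L))
  pr2 <- thickness_profile(sec2, n_samples = 60L)
  left <- pr2$samples[pr2$samples$side == "left", ]
  expect_true(all(diff(left$thickness[order(left$s_norm)]) > -1e-6))
  # discretisation refinement: 36 vs 720 boundary points agree within 2%
  prof_of <- function(n) {
    s <- gen_cross_section(list(kind = "dorsally_thinned", R_inner = 50,
                                thickness_dorsal = 10,
                                thickness_ventral = 40, n_points = n))
    p <- thickness_profile(s, n_samples = 40L)$samples
    p$thickness[p$side == "left"]
  }
  expect_lt(max(abs(prof_of(36L) / prof_of(720L) - 1)), 0.02)
})

test_that("cross-section constructor rejects invalid geometry", {
  expect_error(gen_cross_section(list(kind = "annulus", R_inner = 50,
                                      thickness = 10, n_points = 12L)),
               "n_points")
  expect_error(gen_cross_section(list(kind = "annulus", R_inner = 50,
                                      thickness = -2)), "thickness")
  # bowtie outer contour (transversal self-crossing) is rejected
  bowtie <- rbind(c(0, 0), c(10, 10), c(10, 0), c(0, 10))
  expect_error(cross_section(circle_contour(2, center = c(5, 5)), bowtie),
               "self-intersecting")
})

test_that("droplet series generator enforces the elongation precondition", {
  st <- droplet_site("hindbrain") # R0 = 60 um -> lumen sphere ~0.9 nl
  gt <- ground_truth(eta_dorsal = 1e7, eta_rest = 1e7)
  expect_error(
    gen_droplet_series(gt, st, list(volume_nl = 0.5, gamma_N_m = 0.001),
                       duration_h = 6, n_frames = 6L),
    "does not exceed the sphere")
  # rigid wall (both viscosities huge, stiff shell): aspect stays put
  gt_rigid <- ground_truth(eta_dorsal = 1e15, eta_rest = 1e15,
                           E_shell = 1e9)
  ser <- gen_droplet_series(gt_rigid, st,
                            list(volume_nl = 4, gamma_N_m = 0.001),
                            duration_h = 12, n_frames = 6L)
  expect_lt(max(ser$frames$aspect_true) - min(ser$frames$aspect_true),
            1e-4)
  # noiseless relaxation is monotone toward 1
  gt0 <- ground_truth(eta_dorsal = 1e7, eta_rest = 1e7)
  ser0 <- gen_droplet_series(gt0, st, list(volume_nl = 4,
                                           gamma_N_m = 0.001),
                             duration_h = 12, n_frames = 9L)
  expect_true(all(diff(ser0$frames$aspect_true) <= 1e-12))
  expect_true(all(ser0$frames$aspect_true >= 1 - 1e-12))
})

test_that("cohort generator pairs regions per embryo and recovers effects", {
  coh <- gen_cohort(9L, effects = list(beta_hindbrain_mean = 0.35,
                                       beta_spinalcord_mean = 0.15,
                                       sd = 0.05),
                    seed = 3L, records = FALSE)
  bt <- coh$beta_true
  expect_equal(nrow(bt), 18L)
  expect_true(all(table(bt$embryo) == 2L))
  expect_true(all(bt$beta >= 0 & bt$beta <= 1))
  # minimal n runs
  expect_error(gen_cohort(2L, records = FALSE), NA)
  expect_error(gen_cohort(1L), "n_per_group")
  # truncation warning when sd pushes draws outside [0, 1]
  expect_warning( # both groups need resampling at these means/sd
    expect_warning(gen_cohort(50L,
                              effects = list(beta_hindbrain_mean = 0.05,
                                             beta_spinalcord_mean = 0.9,
                                             sd = 0.2),
                              seed = 1L, records = FALSE),
                   "truncation"),
    "truncation")
})

test_that("creep CSV round-trips through the shared schema", {
  rec <- gen_creep_experiment(ground_truth(noise_sd = 0.05, seed = 2L))
  path <- withr::local_tempfile(fileext = ".csv")
  write_creep_csv(rec, path)
  back <- read_creep_csv(path)
  expect_equal(back$indentation_um, rec$indentation_um, tolerance = 1e-9)
  expect_identical(back$phase, rec$phase)
  expect_equal(back$bead_radius_um, rec$bead_radius_um)
})

test_that("contour CSV round-trips cross-sections", {
  sec <- gen_cross_section(list(kind = "annulus", R_inner = 40,
                                thickness = 12, n_points = 72L))
  path <- withr::local_tempfile(fileext = ".csv")
  write_contours_csv(sec, path)
  back <- read_cross_section_csv(path)
  expect_equal(back$inner, sec$inner, tolerance = 1e-9)
  expect_equal(back$outer, sec$outer, tolerance = 1e-9)
})
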