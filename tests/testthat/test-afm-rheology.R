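test_that("force-ramp fit recovers linear, quadratic and intermediate ramps", {
  # exactly linear ramp -> alpha = 1
  rec <- oracle_record(alpha = 1)
  fit <- fit_force_ramp(rec)
  expect_true(fit$converged)
  expect_equal(fit$alpha, 1, tolerance = 1e-3)
  expect_equal(fit$F_C, 50, tolerance = 1e-3)
  expect_equal(fit$dt_A, 1, tolerance = 1e-2)

  # quadratic ramp -> alpha at its upper bound
  rec2 <- oracle_record(alpha = 2)
  expect_equal(fit_force_ramp(rec2)$alpha, 2, tolerance = 1e-3)

  # synthetic generator round trip at alpha = 1.5
  rec3 <- gen_creep_experiment(ground_truth(alpha_true = 1.5))
  expect_equal(fit_force_ramp(rec3)$alpha, 1.5, tolerance = 0.01)
})

test_that("ramp fit refuses records without enough ramp samples", {
  rec <- oracle_record(rate_hz = 100)
  few <- creep_record(rec$time_s[95:400], rec$force_nN[95:400],
                      rec$indentation_um[95:400], rec$bead_radius_um,
                      phase = rec$phase[95:400])
  expect_error(fit_force_ramp(few), "fewer than 10 ramp samples")
})

test_that("closed-form creep indentation matches the hereditary oracle", {
  # frozen oracle value: alpha=1, beta=0.3, F_C=50 nN, k0=1 kPa,
  # R=44.65 um, t = t_C + dt_A + 3 s
  expect_equal(creep_model_indentation(std_ramp(), 1000, 0.3, 1, 44.65, 4),
               4.055267, tolerance = 1e-6)
  # elastic limit: time-independent Hertz value after the ramp
  d_el <- creep_model_indentation(std_ramp(), 1000, 0, 1, 44.65,
                                  c(1, 2, 4))
  hertz <- (3 * 50e-9 / (4 * 1000 * sqrt(44.65e-6)))^(2 / 3) * 1e6
  expect_equal(d_el, rep(hertz, 3L), tolerance = 1e-9)
  # k0 scaling: doubling k0 scales indentation by 2^(-2/3)
  d1 <- creep_model_indentation(std_ramp(), 1000, 0.4, 1, 44.65, 3)
  d2 <- creep_model_indentation(std_ramp(), 2000, 0.4, 1, 44.65, 3)
  expect_equal(d2 / d1, 2^(-2 / 3), tolerance = 1e-12)
})

test_that("hereditary oracle: elastic limit, refinement, viscous asymptote", {
  tg <- seq(1.2, 4, by = 0.4)
  # beta = 0 reproduces the Hertz response at every time
  d0 <- hereditary_creep_oracle(std_ramp(), 1000, 0, 1, 44.65, tg)
  hertz <- (3 * ramp_force(tg, 50, 0, 1, 1) * 1e-9 /
              (4 * 1000 * sqrt(44.65e-6)))^(2 / 3) * 1e6
  expect_equal(d0, hertz, tolerance = 1e-10)
  # quadrature refinement: coarse vs fine nodes agree far below 0.1%
  d16 <- hereditary_creep_oracle(std_ramp(), 1000, 0.55, 1, 44.65, tg,
                                 n_nodes = 16L)
  d256 <- hereditary_creep_oracle(std_ramp(), 1000, 0.55, 1, 44.65, tg,
                                  n_nodes = 256L)
  expect_lt(max(abs(d16 / d256 - 1)), 1e-3)
  # beta = 1: delta^(3/2) grows affinely as F_C (t - t_C - dt_A/2)/(k0 t0)
  late <- c(20, 30, 40)
  d1 <- hereditary_creep_oracle(std_ramp(), 1000, 1, 1, 44.65, late)
  pred <- (3 * 50e-9 / (4 * sqrt(44.65e-6) * 1000)) * (late - 0.5)
  expect_equal((d1 * 1e-6)^1.5, pred, tolerance = 1e-10)
})

test_that("creep power-law fit recovers the fluidity limits", {
  rec_el <- oracle_record(beta = 0)
  ramp_el <- fit_force_ramp(rec_el)
  expect_lt(abs(fit_creep_powerlaw(rec_el, ramp_el)$beta), 0.02)
  rec_fl <- oracle_record(beta = 1)
  ramp_fl <- fit_force_ramp(rec_fl)
  expect_gt(fit_creep_powerlaw(rec_fl, ramp_fl)$beta, 0.98)
})

test_that("creep fit round-trips a (k0, beta) grid and is monotone in beta", {
  betas <- c(0.1, 0.3, 0.5)
  k0s <- c(500, 1000, 2000)
  est <- matrix(NA_real_, length(k0s), length(betas))
  for (i in seq_along(k0s)) for (j in seq_along(betas)) {
    rec <- oracle_record(k0 = k0s[i], beta = betas[j], alpha = 1.2)
    fit <- fit_creep_powerlaw(rec, fit_force_ramp(rec))
    est[i, j] <- fit$beta
    expect_equal(fit$beta, betas[j], tolerance = 0.05 * betas[j] + 1e-3)
    expect_equal(fit$k0, k0s[i], tolerance = 0.05 * k0s[i])
  }
  # fitted beta increases with true beta within every k0 row
  for (i in seq_along(k0s)) expect_true(all(diff(est[i, ]) > 0))
})

test_that("creep fit refuses short hold phases and unconverged ramps", {
  rec <- oracle_record()
  bad_ramp <- std_ramp(); bad_ramp$converged <- FALSE
  expect_error(fit_creep_powerlaw(rec, bad_ramp), "refused")
  short <- creep_record(rec$time_s[1:105], rec$force_nN[1:105],
                        rec$indentation_um[1:105], rec$bead_radius_um,
                        phase = rec$phase[1:105])
  expect_error(fit_creep_powerlaw(short, std_ramp()), "hold phase")
})

test_that("Hertz fit is exact on Hertzian data and scales dimensionally", {
  R <- 44.65
  d <- seq(0.05, 3, length.out = 80)
  f <- (4 / 3) * 1000 * sqrt(R * 1e-6) * (d * 1e-6)^1.5 / 1e-9
  t <- seq_along(d) * 0.01
  rec <- creep_record(t, f, d, R, phase = rep("ramp", length(d)))
  expect_error(fit_hertz_instantaneous(rec), NA)
  expect_equal(fit_hertz_instantaneous(rec)$K, 1000, tolerance = 1e-6)
  # delta and F both doubled -> K scales by 2^(-1/2)
  rec2 <- creep_record(t, 2 * f, 2 * d, R, phase = rep("ramp", length(d)))
  expect_equal(fit_hertz_instantaneous(rec2)$K, 1000 * 2^(-1 / 2),
               tolerance = 1e-6)
  # weak creep: K close to k0
  rec3 <- oracle_record(beta = 0.1)
  expect_equal(fit_hertz_instantaneous(rec3)$K, 1000, tolerance = 0.15)
})

test_that("Hertz fit re-sorts non-monotone ramp indentation with a warning", {
  R <- 44.65
  d <- seq(0.05, 3, length.out = 40)
  f <- (4 / 3) * 1000 * sqrt(R * 1e-6) * (d * 1e-6)^1.5 / 1e-9
  o <- c(2L, 1L, seq(3L, 40L))
  rec <- creep_record(seq_along(d) * 0.01, f[o], d[o], R,
                      phase = rep("ramp", 40L))
  expect_warning(fit <- fit_hertz_instantaneous(rec), "re-sorted")
  expect_equal(fit$K, 1000, tolerance = 1e-6)
})

test_that("paired comparison reports t, p and normality; handles degeneracy", {
  # known two-sample fixture: t matches the closed-form Welch statistic
  a <- c(0.31, 0.35, 0.29, 0.40, 0.33, 0.37, 0.36, 0.30, 0.34)
  b <- c(0.15, 0.18, 0.12, 0.20, 0.16, 0.14, 0.17, 0.13, 0.19)
  res <- paired_group_compare(a, b, paired = FALSE)
  t_hand <- (mean(a) - mean(b)) /
    sqrt(var(a) / length(a) + var(b) / length(b))
  expect_equal(res$statistic, t_hand, tolerance = 1e-12)
  expect_true(res$significant)
  expect_length(res$normality_p, 2L)
  # unpaired test is invariant to within-group reordering
  res_perm <- paired_group_compare(a, b[sample(9L)], paired = FALSE)
  expect_equal(res_perm$p_value, res$p_value, tolerance = 1e-12)
  # swapped groups: t flips sign, p unchanged
  res_sw <- paired_group_compare(b, a, paired = FALSE)
  expect_equal(res_sw$statistic, -res$statistic, tolerance = 1e-12)
  expect_equal(res_sw$p_value, res$p_value, tolerance = 1e-12)
  # tiny groups: normality test skipped with a warning, not an error
  expect_warning( # one warning per undersized group
    expect_warning(paired_group_compare(c(0.1, 0.2), c(0.3, 0.1)),
                   "n < 3"),
    "n < 3")
  # identical paired lists -> degenerate, flagged not silent
  res_id <- paired_group_compare(a, a, paired = TRUE)
  expect_true(is.na(res_id$p_value))
  expect_match(res_id$note, "degenerate")
  # accepts lists of rheology fits
  fits <- lapply(a, function(x) structure(list(beta = x),
                                          class = "rheology_fit"))
  res_f <- paired_group_compare(fits, b, paired = TRUE)
  expect_s3_class(res_f$statistic, NA)
  expect_true(res_f$p_value < 0.001)
})
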