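test_that("thickness profile endpoints and symmetry conventions hold", {
  sec <- gen_cross_section(list(kind = "dorsally_thinned", R_inner = 50,
                                thickness_dorsal = 12,
                                thickness_ventral = 30, n_points = 360L))
  pr <- thickness_profile(sec, n_samples = 50L)
  s <- pr$samples
  expect_equal(min(s$s_norm), 0)
  expect_equal(max(s$s_norm), 1)
  # mirror-symmetric section: left and right profiles agree
  left <- s[s$side == "left", ]
  right <- s[s$side == "right", ]
  expect_equal(left$thickness, right$thickness, tolerance = 1e-6)
  # dorsal end thin, ventral end thick
  expect_equal(left$thickness[left$s_norm == 0], 12, tolerance = 0.05)
  expect_equal(left$thickness[left$s_norm == 1], 30, tolerance = 0.05)
})

test_that("eccentric annulus thickness matches the closed form within 2%", {
  off <- 5
  sec <- gen_cross_section(list(kind = "eccentric", R_inner = 50,
                                thickness = 15, offset = off,
                                n_points = 720L))
  pr <- thickness_profile(sec, n_samples = 100L)
  left <- pr$samples[pr$samples$side == "left", ]
  th <- left$s_norm * pi # circular inner contour: arc prop. to angle
  b <- 50 + 15
  uc <- -off * cos(th)
  analytic <- -50 + uc + sqrt(b^2 - off^2 + uc^2)
  expect_lt(max(abs(left$thickness / analytic - 1)), 0.02)
})

test_that("profile sampling density does not change the answer", {
  sec <- gen_cross_section(list(kind = "dorsally_thinned", R_inner = 50,
                                thickness_dorsal = 10,
                                thickness_ventral = 40, n_points = 720L))
  p50 <- thickness_profile(sec, n_samples = 50L)$samples
  p500 <- thickness_profile(sec, n_samples = 500L)$samples
  l50 <- p50[p50$side == "left", ]
  l500 <- p500[p500$side == "left", ]
  interp <- approx(l500$s_norm, l500$thickness, xout = l50$s_norm)$y
  expect_lt(max(abs(l50$thickness / interp - 1)), 0.02)
})

test_that("normalise_and_average recovers constants and known quartics", {
  sec <- gen_cross_section(list(kind = "annulus", R_inner = 50,
                                thickness = 10, n_points = 360L))
  pr <- thickness_profile(sec, n_samples = 60L)
  avg <- normalise_and_average(list(pr, pr))
  expect_equal(unname(avg$poly_coef[1L]), 10, tolerance = 1e-3)
  expect_lt(max(abs(avg$poly_coef[-1L])), 1e-3)
  # exact quartic data: coefficients recovered to numerical precision
  s <- seq(0, 1, length.out = 60L)
  quartic <- 12 + 3 * s - 7 * s^2 + 4 * s^3 + 9 * s^4
  prof <- profile_from_values(s * 200, quartic, side_length = 200)
  avg2 <- normalise_and_average(prof)
  expect_equal(unname(avg2$poly_coef), c(12, 3, -7, 4, 9),
               tolerance = 1e-6)
  # group contrast: thin-dorsal vs thick-dorsal fitted curves differ most
  # near s = 0
  mk <- function(hd) {
    sec <- gen_cross_section(list(kind = "dorsally_thinned", R_inner = 50,
                                  thickness_dorsal = hd,
                                  thickness_ventral = 40,
                                  n_points = 240L))
    thickness_profile(sec, n_samples = 50L)
  }
  a <- normalise_and_average(mk(8))
  b <- normalise_and_average(mk(30))
  gap <- abs(a$fitted - b$fitted)
  # largest divergence within the dorsal-most 10% of the axis
  expect_lte(which.max(gap), 10L)
  expect_gt(gap[1L], gap[51L]) # dorsal gap exceeds the mid-axis gap
  # short profiles are excluded with a warning
  stub <- profile_from_values(c(0, 100), c(10, 10))
  stub$samples <- stub$samples[1:3, ]
  expect_warning(expect_error(normalise_and_average(list(stub)),
                              "no usable"),
                 "excluded")
})

test_that("roof metrics: window means and single-cell roof length", {
  # constant 10 um profile
  s <- seq(0, 500, by = 10)
  cst <- profile_from_values(s, rep(10, length(s)))
  m <- roof_metrics(cst, window = 100)
  expect_equal(m$mean_roof_thickness, 10)
  # step fixture: 8 um up to 150 um arc, 40 um beyond, threshold 10
  step <- profile_from_values(s, ifelse(s <= 150, 8, 40))
  m2 <- roof_metrics(step, window = 100, single_cell_thickness = 10)
  expect_equal(m2$roof_length, 300)
  expect_equal(m2$mean_roof_thickness, 8)
  # monotone thinning: window means ordered, mean(100) <= mean(300)
  mono <- profile_from_values(s, 10 + s / 20)
  expect_lte(roof_metrics(mono, 100)$mean_roof_thickness,
             roof_metrics(mono, 300)$mean_roof_thickness)
  # uncovered window omitted with a reason
  expect_warning(m3 <- roof_metrics(cst, window = 1000), "omitted")
  expect_true(is.na(m3$mean_roof_thickness))
})

test_that("roof metrics respond to generator-controlled dorsal thinning", {
  metric <- function(hd) {
    sec <- gen_cross_section(list(kind = "dorsally_thinned", R_inner = 60,
                                  thickness_dorsal = hd,
                                  thickness_ventral = 40,
                                  n_points = 360L))
    roof_metrics(thickness_profile(sec, n_samples = 120L), window = 100)
  }
  thin <- metric(6); thick <- metric(20)
  expect_lt(thin$mean_roof_thickness, thick$mean_roof_thickness)
  expect_gt(thin$roof_length, thick$roof_length)
})

test_that("apical intensity binning is analytic on ramps and flat traces", {
  # constant trace: all bins equal
  cst <- data.frame(position_um = seq(0, 300, by = 2), intensity = 7)
  expect_equal(apical_intensity_bins(cst, 3L)$mean_norm_intensity,
               rep(1, 3L))
  # linear ramp 0 -> 1, two bins: means exactly 0.25 and 0.75
  ramp <- data.frame(position_um = seq(0, 300, by = 2),
                     intensity = seq(0, 300, by = 2) / 300)
  expect_equal(apical_intensity_bins(ramp, 2L)$mean_norm_intensity,
               c(0.25, 0.75), tolerance = 1e-12)
  # dorsally depleted synthetic trace: dorsal bin dimmest
  tr <- gen_intensity_trace(noise_sd = 0.02, seed = 4L)
  bins <- apical_intensity_bins(tr, 3L)
  expect_lt(bins$mean_norm_intensity[1L], bins$mean_norm_intensity[3L])
  # sparse trace: a bin with no samples is refused
  sparse <- data.frame(position_um = c(0, 1, 300), intensity = c(1, 1, 1))
  expect_error(apical_intensity_bins(sparse, 3L), "too sparse")
  expect_error(apical_intensity_bins(ramp, 5L), "2 or 3")
})

test_that("two-group test matches the closed-form t and symmetry", {
  a <- c(10.2, 11.5, 9.8, 10.9, 11.1)
  b <- c(8.1, 8.9, 7.5, 8.4, 9.0)
  res <- two_group_test(a, b)
  t_hand <- (mean(a) - mean(b)) / sqrt(var(a) / 5 + var(b) / 5)
  expect_equal(res$statistic, t_hand, tolerance = 1e-12)
  # equal constant groups: degenerate, not significant
  res_eq <- two_group_test(rep(5, 4L), rep(5, 4L))
  expect_false(isTRUE(res_eq$significant))
})
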