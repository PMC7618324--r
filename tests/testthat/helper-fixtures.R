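# Shared fixtures, all generated in code.

# noiseless creep record built directly from the hereditary oracle with a
# known ramp (bypasses gen_creep_experiment when a bare-bones record with
# arbitrary parameters is wanted)
oracle_record <- function(k0 = 1000, beta = 0.3, alpha = 1, F_C = 50,
                          dt_A = 1, hold = 3, R = 44.65, rate_hz = 100,
                          t0 = 1) {
  ramp <- list(F_C = F_C, t_C = 0, dt_A = dt_A, alpha = alpha,
               converged = TRUE)
  t <- seq(1 / rate_hz, dt_A + hold, by = 1 / rate_hz)
  f <- ramp_force(t, F_C, 0, dt_A, alpha)
  d <- hereditary_creep_oracle(ramp, k0, beta, t0, R, t)
  creep_record(t, f, d, R, phase = ifelse(t < dt_A, "ramp", "hold"))
}

std_ramp <- function(alpha = 1, F_C = 50, dt_A = 1) {
  list(F_C = F_C, t_C = 0, dt_A = dt_A, alpha = alpha, converged = TRUE)
}

circle_contour <- function(r = 50, n = 100, center = c(0, 0)) {
  th <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  cbind(center[1L] + r * cos(th), center[2L] + r * sin(th))
}

# thickness_profile-shaped object built directly from (s, thickness) pairs,
# mirrored on both sides — for metric tests that need exact step profiles
profile_from_values <- function(s_raw, thickness, side_length = max(s_raw)) {
  samples <- rbind(
    data.frame(side = "left", s_raw = s_raw,
               s_norm = s_raw / side_length, thickness = thickness),
    data.frame(side = "right", s_raw = s_raw,
               s_norm = s_raw / side_length, thickness = thickness))
  structure(list(samples = samples,
                 side_lengths = c(left = side_length, right = side_length),
                 metadata = list()),
            class = "thickness_profile")
}

droplet_site <- function(region = "hindbrain", n_segments = 24L) {
  tube_preset(region, stage = "droplet_site", n_segments = n_segments)
}
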