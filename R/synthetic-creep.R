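#' Ground-truth parameter set for synthetic data generation
#'
#' Bundles the true material and protocol parameters from which synthetic
#' experiments are generated, so every generated dataset carries a known
#' answer. Identical seeds give bit-identical output.
#'
#' @param k0_true Reduced instantaneous stiffness (Pa), > 0.
#' @param beta_true Fluidity, in \[0, 1\].
#' @param alpha_true Ramp-shape exponent, in \[1, 2\].
#' @param eta_dorsal,eta_rest Maxwell viscosities (Pa s), > 0
#'   (`Inf` allowed to encode a purely elastic compartment).
#' @param E_shell Shell elastic modulus (Pa), > 0.
#' @param noise_sd Additive Gaussian noise sd, in the units of the signal it
#'   is applied to (um for indentation and contour coordinates).
#' @param seed Integer RNG seed.
#' @return An object of class `ground_truth` (named list).
#' @export
ground_truth <- function(k0_true = 1000, beta_true = 0.3, alpha_true = 1.2,
                         eta_dorsal = nt_defaults()$materials$eta_dorsal_Pa_s,
                         eta_rest = nt_defaults()$materials$eta_rest_Pa_s,
                         E_shell = nt_defaults()$materials$E_Pa,
                         noise_sd = 0, seed = 1L) {
  num <- list(k0_true = k0_true, beta_true = beta_true,
              alpha_true = alpha_true, eta_dorsal = eta_dorsal,
              eta_rest = eta_rest, E_shell = E_shell, noise_sd = noise_sd)
  for (nm in names(num)) {
    v <- num[[nm]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || is.nan(v)) {
      stop(sprintf("ground truth field '%s' is not a finite number", nm),
           call. = FALSE)
    }
  }
  if (!is.finite(k0_true) || k0_true <= 0) {
    stop("ground truth field 'k0_true' must be finite and positive",
         call. = FALSE)
  }
  if (beta_true < 0 || beta_true > 1) {
    stop("ground truth field 'beta_true' must lie in [0, 1]", call. = FALSE)
  }
  if (alpha_true < 1 || alpha_true > 2) {
    stop("ground truth field 'alpha_true' must lie in [1, 2]", call. = FALSE)
  }
  if (eta_dorsal <= 0 || eta_rest <= 0 || !is.finite(E_shell) ||
      E_shell <= 0) {
    stop("ground truth moduli and viscosities must be positive",
         call. = FALSE)
  }
  if (!is.finite(noise_sd) || noise_sd < 0) {
    stop("ground truth field 'noise_sd' must be finite and non-negative",
         call. = FALSE)
  }
  structure(c(num, list(seed = as.integer(seed))), class = "ground_truth")
}

#' Generate a synthetic AFM creep experiment
#'
#' Builds the force trace from the piecewise ramp model with the
#' ground-truth ramp exponent, computes the noiseless indentation through
#' the hereditary-integral oracle ([hereditary_creep_oracle()]) and adds
#' Gaussian noise of sd `gt$noise_sd` (um). The default protocol mirrors
#' the lab protocol: 10 um/s approach to a 50 or 75 nN hold maintained for
#' 3 s with an 89.3 um diameter bead.
#'
#' @param gt A [ground_truth()].
#' @param protocol List with `F_hold` (nN), `ramp_time` (s), `hold_time`
#'   (s), `bead_diameter` (um), `sample_rate` (Hz).
#' @param t0 Reference time of the creep compliance (s).
#' @return A [creep_record()]; ground truth is attached as
#'   `metadata$ground_truth`.
#' @export
gen_creep_experiment <- function(gt,
                                 protocol = list(),
                                 t0 = nt_defaults()$protocol$t0_s) {
  stopifnot(inherits(gt, "ground_truth"))
  def <- nt_defaults()$protocol
  proto <- modifyList(
    list(F_hold = def$hold_forces_nN[1L], ramp_time = 1,
         hold_time = def$hold_time_s,
         bead_diameter = def$bead_diameter_um,
         sample_rate = def$sample_rate_hz),
    protocol)
  for (nm in names(proto)) stopifnot_positive(proto[[nm]], nm)

  R <- proto$bead_diameter / 2
  dt <- 1 / proto$sample_rate
  t <- seq(dt, proto$ramp_time + proto$hold_time, by = dt)
  ramp <- list(F_C = proto$F_hold, t_C = 0, dt_A = proto$ramp_time,
               alpha = gt$alpha_true)
  f <- ramp_force(t, ramp$F_C, ramp$t_C, ramp$dt_A, ramp$alpha)
  d <- hereditary_creep_oracle(ramp, gt$k0_true, gt$beta_true, t0, R, t)
  if (gt$noise_sd > 0) {
    # seeded draw that leaves the caller's RNG stream untouched
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed",
                                                       .GlobalEnv) else NULL
    set.seed(gt$seed)
    d <- d + rnorm(length(d), sd = gt$noise_sd)
    if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
  }
  phase <- ifelse(t < proto$ramp_time, "ramp", "hold")
  creep_record(t, f, d, R, phase = phase,
               metadata = list(ground_truth = gt, protocol = proto, t0 = t0))
}

#' Generate a paired synthetic cohort of creep experiments
#'
#' Emulates the paired design of the AFM study: each synthetic embryo
#' contributes one hindbrain and one spinal-cord measurement, with
#' per-embryo fluidity drawn from group-specific normal distributions
#' truncated to \[0, 1\] (out-of-range draws are resampled with a warning).
#'
#' @param n_per_group Number of embryos (>= 2).
#' @param effects List with `beta_hindbrain_mean`, `beta_spinalcord_mean`
#'   (both in \[0, 1\]) and `sd`.
#' @param seed Integer seed.
#' @param records If `TRUE` (default) generate full [creep_record()]s via
#'   [gen_creep_experiment()]; if `FALSE` return only the drawn beta values
#'   (fast path for Monte-Carlo calibration studies).
#' @param gt_base [ground_truth()] template supplying the remaining
#'   parameters (k0, alpha, noise).
#' @return A list of class `creep_cohort` with elements `beta_true`
#'   (data.frame embryo/region/beta) and, when `records = TRUE`,
#'   `records` (nested list `[[embryo]][[region]]`).
#' @export
gen_cohort <- function(n_per_group,
                       effects = list(beta_hindbrain_mean = 0.35,
                                      beta_spinalcord_mean = 0.15,
                                      sd = 0.05),
                       seed = 1L, records = TRUE,
                       gt_base = ground_truth()) {
  if (n_per_group < 2L) stop("'n_per_group' must be >= 2", call. = FALSE)
  mh <- effects$beta_hindbrain_mean; ms <- effects$beta_spinalcord_mean
  if (any(c(mh, ms) < 0) || any(c(mh, ms) > 1)) {
    stop("group beta means must lie in [0, 1]", call. = FALSE)
  }
  set.seed(seed)
  draw_trunc <- function(mean, sd, n) {
    out <- rnorm(n, mean, sd)
    bad <- out < 0 | out > 1
    tries <- 0L
    while (any(bad)) {
      if (tries == 0L) {
        warning("beta draws outside [0, 1]; resampled with truncation",
                call. = FALSE)
      }
      out[bad] <- rnorm(sum(bad), mean, sd)
      bad <- out < 0 | out > 1
      tries <- tries + 1L
      if (tries > 1000L) { # hard truncation fallback
        out[bad] <- pmin(pmax(out[bad], 0), 1); break
      }
    }
    out
  }
  b_h <- draw_trunc(mh, effects$sd, n_per_group)
  b_s <- draw_trunc(ms, effects$sd, n_per_group)
  beta_true <- data.frame(
    embryo = rep(seq_len(n_per_group), each = 2L),
    region = rep(c("hindbrain", "spinal_cord"), n_per_group),
    beta = as.vector(rbind(b_h, b_s)))
  recs <- NULL
  if (records) {
    sub_seeds <- sample.int(.Machine$integer.max, 2L * n_per_group)
    recs <- lapply(seq_len(n_per_group), function(i) {
      list(
        hindbrain = gen_creep_experiment(
          ground_truth(k0_true = gt_base$k0_true, beta_true = b_h[i],
                       alpha_true = gt_base$alpha_true,
                       noise_sd = gt_base$noise_sd,
                       seed = sub_seeds[2L * i - 1L])),
        spinal_cord = gen_creep_experiment(
          ground_truth(k0_true = gt_base$k0_true, beta_true = b_s[i],
                       alpha_true = gt_base$alpha_true,
                       noise_sd = gt_base$noise_sd,
                       seed = sub_seeds[2L * i])))
    })
  }
  structure(list(beta_true = beta_true, records = recs,
                 effects = effects, seed = seed),
            class = "creep_cohort")
}
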