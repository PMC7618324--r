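# Power-law creep rheology of spherical indentation.
#
# The material is a power-law viscoelastic solid with creep compliance
#   J(t) = (1/k0) * (t/t0)^beta,
# where k0 is the reduced instantaneous elastic stiffness (Pa), beta the
# fluidity (0 = elastic solid, 1 = viscous fluid) and t0 a fixed reference
# time. For a spherical probe under the monotonically non-decreasing
# piecewise force ramp, the Lee-Radok hereditary integral
#   delta^{3/2}(t) = (3/(4 sqrt(R))) * int_0^t J(t - t') dF/dt' dt'
# has the closed form (x = min(dt_A/(t - t_C), 1); B the incomplete beta)
#   delta^{3/2}(t) = (3/(4 k0 sqrt(R))) * F_C * alpha *
#                    (t - t_C)^(alpha+beta) / (dt_A^alpha t0^beta) *
#                    B(x; alpha, beta + 1).
# All internal algebra is SI; arguments and returns use lab units
# (nN, um, s, Pa).

.NN <- 1e-9   # nN -> N
.UM <- 1e-6   # um -> m

# incomplete (non-regularised) beta function B(x; a, b)
.ibeta <- function(x, a, b) stats::pbeta(x, a, b) * beta(a, b)

#' Closed-form indentation of a power-law material under the piecewise ramp
#'
#' Evaluates the analytic creep-indentation solution for a power-law
#' viscoelastic half-space indented by a sphere under the piecewise
#' force-ramp protocol (see [ramp_force()]). Valid for both the ramp and the
#' hold phase; the incomplete-beta argument is capped at 1 during the ramp,
#' where the integral is complete.
#'
#' @param ramp A [fit_force_ramp()] result (or any list with `F_C`, `t_C`,
#'   `dt_A`, `alpha`).
#' @param k0 Reduced instantaneous elastic stiffness (Pa).
#' @param beta Fluidity, in \[0, 1\].
#' @param t0 Reference time of the creep compliance (s); the package default
#'   is 1 s, so `k0` is the stiffness at 1 s.
#' @param R Bead radius (um).
#' @param t Times (s), all > `ramp$t_C`.
#' @return Indentation (um) at `t`.
#' @seealso [hereditary_creep_oracle()] for the independent numerical
#'   evaluation this closed form is verified against.
#' @export
creep_model_indentation <- function(ramp, k0, beta, t0, R, t) {
  stopifnot_positive(k0, "k0")
  stopifnot_positive(t0, "t0")
  stopifnot_positive(R, "R")
  if (beta < 0 || beta > 1) stop("'beta' must lie in [0, 1]", call. = FALSE)
  if (any(t <= ramp$t_C)) {
    stop("all times must exceed the ramp onset t_C", call. = FALSE)
  }
  ts <- t - ramp$t_C
  x <- pmin(ramp$dt_A / ts, 1)
  pref <- 3 * ramp$F_C * .NN * ramp$alpha /
    (4 * k0 * sqrt(R * .UM) * ramp$dt_A^ramp$alpha * t0^beta)
  d32 <- pref * ts^(ramp$alpha + beta) * .ibeta(x, ramp$alpha, beta + 1)
  d32^(2 / 3) / .UM
}

#' Hereditary-integral oracle for creep indentation
#'
#' Independent numerical ground truth for [creep_model_indentation()]:
#' direct Gauss-Legendre quadrature of the Lee-Radok hereditary integral
#' \deqn{\delta^{3/2}(t) = \frac{3}{4\sqrt{R}} \int_0^t J(t-t')\,
#'   \frac{dF}{dt'}\,dt'} with power-law creep compliance
#' \eqn{J(t) = (1/k_0)(t/t_0)^\beta}. Valid for monotonically
#' non-decreasing load, which the ramp-then-hold protocol guarantees.
#' With the default 64 nodes the quadrature error is far below 0.1%
#' (the integrand is smooth for \eqn{\alpha \ge 1}); refine with
#' `n_nodes` to check.
#'
#' @inheritParams creep_model_indentation
#' @param t_grid Times (s) at which to evaluate the indentation.
#' @param n_nodes Gauss-Legendre node count per evaluation.
#' @return Indentation series (um) on `t_grid`.
#' @export
hereditary_creep_oracle <- function(ramp, k0, beta, t0, R, t_grid,
                                    n_nodes = 64L) {
  stopifnot_positive(k0, "k0")
  stopifnot_positive(t0, "t0")
  stopifnot_positive(R, "R")
  if (ramp$F_C <= 0 || ramp$dt_A <= 0) {
    stop("ramp must encode a non-decreasing force (F_C > 0, dt_A > 0)",
         call. = FALSE)
  }
  gl <- pracma::gaussLegendre(n_nodes, 0, 1)
  k0_si <- k0
  pref <- 3 / (4 * sqrt(R * .UM) * k0_si)
  sapply(t_grid, function(t) {
    if (t <= ramp$t_C) return(0)
    # dF/dt' is non-zero only on (t_C, t_C + dt_A)
    hi <- min(t, ramp$t_C + ramp$dt_A)
    a <- ramp$t_C
    tp <- a + (hi - a) * gl$x
    dF <- ramp$F_C * .NN * ramp$alpha *
      (tp - ramp$t_C)^(ramp$alpha - 1) / ramp$dt_A^ramp$alpha
    J <- ((t - tp) / t0)^beta
    d32 <- pref * (hi - a) * sum(gl$w * J * dF)
    d32^(2 / 3) / .UM
  })
}

#' Fit the power-law creep model to hold-phase indentation
#'
#' Second stage of the two-stage creep analysis: given the fitted force
#' ramp, bounded nonlinear least squares of [creep_model_indentation()]
#' against the measured indentation over (`k0`, `beta`), with `beta`
#' constrained to \[0, 1\] and `t0` held fixed. Three starts
#' (`beta` = 0.1, 0.4, 0.7) are tried; ties broken by lowest residual.
#' By default only the hold phase is fitted.
#'
#' @param rec A [creep_record()].
#' @param ramp The [fit_force_ramp()] result for the same record
#'   (must have converged).
#' @param t0 Reference time (s), fixed during the fit.
#' @param fit_phase `"hold"` (default) or `"all"` (include the ramp phase).
#' @return An object of class `rheology_fit`: list with `k0` (Pa), `beta`,
#'   `t0` (s), `residual_rms` (um), `converged`, `beta_at_bound`.
#' @export
fit_creep_powerlaw <- function(rec, ramp, t0 = nt_defaults()$protocol$t0_s,
                               fit_phase = c("hold", "all")) {
  stopifnot(inherits(rec, "creep_record"))
  fit_phase <- match.arg(fit_phase)
  if (!isTRUE(ramp$converged)) {
    stop("ramp fit did not converge; creep fit refused", call. = FALSE)
  }
  keep <- rec$time_s > ramp$t_C + sqrt(.Machine$double.eps)
  if (fit_phase == "hold") {
    keep <- keep & rec$time_s >= ramp$t_C + ramp$dt_A
  }
  t <- rec$time_s[keep]
  d <- rec$indentation_um[keep]
  if (fit_phase == "hold" && length(t) < 10L) {
    stop("hold phase shorter than 10 samples; creep fit refused",
         call. = FALSE)
  }
  R <- rec$bead_radius_um
  # elastic first guess for k0 from the first fitted sample
  d0 <- max(d[1L], 1e-3)
  k0_init <- 3 * ramp$F_C * .NN / (4 * sqrt(R * .UM) * (d0 * .UM)^1.5)
  obj <- function(p) {
    m <- creep_model_indentation(ramp, exp(p[1L]), p[2L], t0, R, t)
    sum((m - d)^2)
  }
  lower <- c(log(k0_init) - log(1e4), 0)
  upper <- c(log(k0_init) + log(1e4), 1)
  best <- NULL
  for (b0 in c(0.1, 0.4, 0.7)) {
    fit <- try(optim(c(log(k0_init), b0), obj, method = "L-BFGS-B",
                     lower = lower, upper = upper,
                     control = list(factr = 1e4, maxit = 500)),
               silent = TRUE)
    if (inherits(fit, "try-error")) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) stop("creep optimisation failed", call. = FALSE)
  beta_hat <- best$par[2L]
  at_bound <- beta_hat < 1e-6 || beta_hat > 1 - 1e-6
  structure(
    list(k0 = exp(best$par[1L]), beta = beta_hat, t0 = t0,
         residual_rms = sqrt(best$value / length(t)),
         converged = best$convergence == 0L,
         beta_at_bound = at_bound,
         n_fitted = length(t), fit_phase = fit_phase),
    class = "rheology_fit"
  )
}

#' @export
print.rheology_fit <- function(x, ...) {
  cat(sprintf(
    "<rheology_fit> k0 = %.4g Pa, beta = %.4f (t0 = %g s, rms %.3g um%s%s)\n",
    x$k0, x$beta, x$t0, x$residual_rms,
    if (x$converged) "" else ", NOT converged",
    if (x$beta_at_bound) ", beta at bound" else ""))
  invisible(x)
}

#' Hertz instantaneous fit
#'
#' Least-squares fit of the Hertz contact model
#' \eqn{F = (4/3) K \sqrt{R}\,\delta^{3/2}} to the approach (ramp) portion
#' of a creep record, giving the reduced apparent elastic modulus
#' \eqn{K = E_0/(1-\nu^2)}. For a weakly creeping material K is expected to
#' be close to the reduced instantaneous stiffness `k0` of the power-law
#' fit. The fit is linear in K so it is solved in closed form.
#'
#' @param rec A [creep_record()] with ramp samples.
#' @return An object of class `hertz_fit`: list with `K` (Pa),
#'   `residual_rms` (nN), `n_fitted`.
#' @export
fit_hertz_instantaneous <- function(rec) {
  stopifnot(inherits(rec, "creep_record"))
  sel <- rec$phase == "ramp" & rec$indentation_um > 0
  if (sum(sel) < 3L) stop("no usable ramp-phase samples", call. = FALSE)
  d <- rec$indentation_um[sel]
  f <- rec$force_nN[sel]
  if (any(diff(d) < 0)) {
    warning("non-monotone indentation during ramp; samples re-sorted by depth",
            call. = FALSE)
    o <- order(d); d <- d[o]; f <- f[o]
  }
  x <- (4 / 3) * sqrt(rec$bead_radius_um * .UM) * (d * .UM)^1.5
  K <- sum(f * .NN * x) / sum(x^2)
  res <- f - K * x / .NN
  structure(
    list(K = K, residual_rms = sqrt(mean(res^2)), n_fitted = length(d)),
    class = "hertz_fit"
  )
}

#' @export
print.hertz_fit <- function(x, ...) {
  cat(sprintf("<hertz_fit> K = %.4g Pa (rms %.3g nN, n = %d)\n",
              x$K, x$residual_rms, x$n_fitted))
  invisible(x)
}
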