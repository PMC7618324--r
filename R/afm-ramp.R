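#' Piecewise force-ramp model
#'
#' The applied force during an AFM creep experiment is modelled as a
#' piecewise power-law ramp followed by a constant hold:
#' \deqn{F(t) = F_C \cdot \begin{cases} 0 & t < t_C \\
#'   ((t - t_C)/\Delta t_A)^\alpha & t_C \le t < t_C + \Delta t_A \\
#'   1 & t \ge t_C + \Delta t_A \end{cases}}
#' where \eqn{F_C} is the hold force, \eqn{t_C} the ramp onset,
#' \eqn{\Delta t_A} the ramp duration and \eqn{\alpha \in [1, 2]} the
#' ramp-shape exponent (1 = linear ramp, 2 = quadratic).
#'
#' @param t Times (s).
#' @param F_C Hold force (nN).
#' @param t_C Ramp onset time (s).
#' @param dt_A Ramp duration (s), > 0.
#' @param alpha Ramp-shape exponent, in \[1, 2\].
#' @return Force at `t` (nN).
#' @export
ramp_force <- function(t, F_C, t_C, dt_A, alpha) {
  stopifnot_positive(dt_A, "dt_A")
  u <- (t - t_C) / dt_A
  F_C * ifelse(u <= 0, 0, ifelse(u >= 1, 1, u^alpha))
}

#' Fit the piecewise force-ramp model to a creep record
#'
#' Bounded nonlinear least squares of [ramp_force()] against the recorded
#' force trace, yielding the hold force, ramp onset, ramp duration and
#' ramp-shape exponent. `alpha` is constrained to \[1, 2\] by the bounded
#' optimiser itself, not clipped afterwards. Three starting values of
#' `alpha` are tried and the lowest-residual solution kept.
#'
#' @param rec A [creep_record()] containing both ramp and hold samples.
#' @return An object of class `ramp_fit`: list with `F_C` (nN), `t_C` (s),
#'   `dt_A` (s), `alpha`, `residual_rms` (nN), `converged`.
#' @export
fit_force_ramp <- function(rec) {
  stopifnot(inherits(rec, "creep_record"))
  t <- rec$time_s; f <- rec$force_nN
  if (sum(rec$phase == "ramp") < 10L) {
    stop("fewer than 10 ramp samples; ramp fit refused", call. = FALSE)
  }
  if (sum(rec$phase == "hold") < 1L) {
    stop("record contains no hold samples", call. = FALSE)
  }
  f_max <- max(f)
  # moment-style initial guesses from the trace itself
  i_hold <- which(f >= 0.99 * f_max)[1L]
  pre <- which(f <= 0.01 * f_max & t < t[i_hold])
  t_c0 <- if (length(pre)) t[max(pre)] else t[1L]
  dt0 <- max(t[i_hold] - t_c0, diff(range(t)) / 100)

  obj <- function(p) {
    m <- ramp_force(t, p[1L], p[2L], p[3L], p[4L])
    sum((m - f)^2)
  }
  dt_t <- min(diff(t))
  lower <- c(0.5 * f_max, min(t) - dt0, dt_t, 1)
  upper <- c(1.5 * f_max, t[i_hold], 2 * (t[i_hold] - min(t)) + dt_t, 2)
  best <- NULL
  for (a0 in c(1.05, 1.5, 1.95)) {
    p0 <- pmin(pmax(c(f_max, t_c0, dt0, a0), lower), upper)
    fit <- try(optim(p0, obj, method = "L-BFGS-B", lower = lower,
                     upper = upper,
                     control = list(factr = 1e4, maxit = 500,
                                    parscale = c(f_max, max(dt0, dt_t),
                                                 dt0, 1))),
               silent = TRUE)
    if (inherits(fit, "try-error")) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) {
    stop("force-ramp optimisation failed from every start", call. = FALSE)
  }
  converged <- best$convergence == 0L
  if (!converged) {
    # the piecewise model is non-smooth in t_C; the line search can abort
    # at the optimum. Accept if a restart makes no further progress.
    re <- try(optim(best$par, obj, method = "L-BFGS-B", lower = lower,
                    upper = upper, control = list(factr = 1e7)),
              silent = TRUE)
    if (!inherits(re, "try-error")) {
      if (re$value <= best$value * (1 + 1e-10) + 1e-300) converged <- TRUE
      if (re$value < best$value) best <- re
    }
  }
  if (!converged) {
    warning("force-ramp fit did not converge: ", best$message, call. = FALSE)
  }
  structure(
    list(F_C = best$par[1L], t_C = best$par[2L], dt_A = best$par[3L],
         alpha = best$par[4L],
         residual_rms = sqrt(best$value / length(t)),
         converged = converged),
    class = "ramp_fit"
  )
}

#' @export
print.ramp_fit <- function(x, ...) {
  cat(sprintf(
    "<ramp_fit> F_C = %.4g nN, t_C = %.4g s, dt_A = %.4g s, alpha = %.4f (rms %.3g nN%s)\n",
    x$F_C, x$t_C, x$dt_A, x$alpha, x$residual_rms,
    if (x$converged) "" else ", NOT converged"))
  invisible(x)
}
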