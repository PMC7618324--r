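#' Thin-shell hoop stress
#'
#' Laplace law for a thin-walled pressurized tube: the circumferential wall
#' stress is proportional to both the luminal pressure and the tube radius,
#' \eqn{\sigma = P R / h}.
#'
#' @param P Lumen pressure (Pa).
#' @param R Lumen radius (um).
#' @param h Wall thickness (um), > 0.
#' @return Hoop stress (Pa).
#' @export
hoop_stress <- function(P, R, h) {
  if (any(h <= 0)) stop("wall thickness must be positive", call. = FALSE)
  P * R / h
}

# Damped fixed-point iteration to the instantaneous elastic equilibrium at
# fixed pressure (the Maxwell spring responds instantly; used to apply the
# t = 0 elastic jump before viscous time stepping).
.equilibrate_elastic <- function(state, mat, P, tol = 1e-10,
                                 max_iter = 1000L, omega = 0.5) {
  segs <- state$segments
  E <- mat$E[segs$compartment]
  l_init <- segs$l
  # additional elastic strain beyond the currently stored stress state
  delta <- rep(0, nrow(segs))
  for (i in seq_len(max_iter)) {
    l <- l_init * (1 + delta)
    R <- sum(l) / (2 * pi)
    if (R > 3 * state$R) {
      stop(paste("elastic instability: pressure load exceeds the elastic",
                 "stability limit of the shell"), call. = FALSE)
    }
    sigma <- hoop_stress(P, R, state$lh0 / l)
    step <- omega * ((sigma - segs$stress) / E - delta)
    delta <- delta + step
    if (max(abs(step)) < tol) break
  }
  segs$strain <- (1 + segs$strain) * (1 + delta) - 1
  segs$l <- l_init * (1 + delta)
  segs$h <- state$lh0 / segs$l
  state$R <- sum(segs$l) / (2 * pi)
  segs$stress <- hoop_stress(P, state$R, segs$h)
  state$segments <- segs
  state
}

#' Advance the tube one Maxwell time step
#'
#' Explicit first-order update of the Maxwell constitutive law per segment,
#' \deqn{d\varepsilon/dt = \sigma/\eta + (1/E)\, d\sigma/dt,}
#' with the hoop stress from [hoop_stress()]. Segment arc lengths grow as
#' \eqn{l \to l(1 + d\varepsilon)}; thickness follows from exact
#' conservation of each segment's arc-length x thickness product
#' (cross-sectional incompressibility); the lumen radius is recomputed
#' from the total circumference. Strains are re-referenced each step
#' (hypoelastic convention). If the step would produce a non-positive
#' thickness or an excessive strain increment it is rejected and retried
#' as two half steps; after 20 nested halvings the simulation aborts with
#' the offending state attached to the error condition.
#'
#' @param state A [tube_state()].
#' @param mat A [material_params()].
#' @param P Lumen pressure (Pa).
#' @param dt Time step (s).
#' @param deps_max Largest admissible strain increment per step.
#' @return The updated [tube_state()].
#' @export
maxwell_step <- function(state, mat, P, dt, deps_max = 0.2) {
  .maxwell_step_impl(state, mat, P, dt, deps_max, depth = 0L)
}

.maxwell_step_impl <- function(state, mat, P, dt, deps_max, depth) {
  segs <- state$segments
  eta <- mat$eta[segs$compartment]
  E <- mat$E[segs$compartment]
  sigma <- hoop_stress(P, state$R, segs$h)
  deps <- dt * sigma / eta + (sigma - segs$stress) / E
  h_new <- state$lh0 / (segs$l * (1 + deps))
  if (any(!is.finite(deps)) || max(abs(deps)) > deps_max ||
      any(h_new <= 0)) {
    if (depth >= 20L) {
      cond <- simpleError(
        "maxwell_step: step rejected after 20 halvings; simulation aborted")
      cond$state <- state
      stop(cond)
    }
    half <- .maxwell_step_impl(state, mat, P, dt / 2, deps_max, depth + 1L)
    return(.maxwell_step_impl(half, mat, P, dt / 2, deps_max, depth + 1L))
  }
  segs$l <- segs$l * (1 + deps)
  segs$h <- state$lh0 / segs$l
  segs$stress <- sigma
  segs$strain <- (1 + segs$strain) * (1 + deps) - 1
  state$segments <- segs
  state$R <- sum(segs$l) / (2 * pi)
  state
}

#' Simulate a pressurized Maxwell tube over developmental time
#'
#' Integrates [maxwell_step()] under a piecewise-linear pressure schedule
#' with adaptive time-stepping (the step is chosen so the largest viscous
#' strain increment stays near `deps_target`; rejected steps are halved).
#' The instantaneous elastic response to the initial pressure is applied
#' before viscous stepping begins. With a dorsal viscosity 10-100x lower
#' than the rest of the wall this reproduces the qualitative headline of
#' hindbrain morphogenesis: the dorsal wall thins under rising lumen
#' pressure while the rest of the wall barely changes, and thinning is
#' stronger for larger initial radius (hindbrain) than smaller
#' (spinal cord).
#'
#' @param initial A [tube_state()].
#' @param mat A [material_params()].
#' @param schedule A [pressure_schedule()].
#' @param duration_h Simulated time (h).
#' @param n_save Number of equally spaced snapshots to keep (>= 2).
#' @param deps_target Target strain increment per time step.
#' @return Object of class `tube_trajectory`: list with `time_h`,
#'   `states` (list of [tube_state()] snapshots), `series` (data.frame
#'   `time_h`, `P_Pa`, `R_um`, `lumen_area_um2`, `h_dorsal_um`,
#'   `h_rest_um`, `dorsal_ratio`, `rest_ratio`), `truncated` flag with
#'   `truncation_reason` (radius blow-up or wall collapse).
#' @export
simulate_tube <- function(initial, mat, schedule, duration_h,
                          n_save = 81L, deps_target = 5e-4) {
  stopifnot(inherits(initial, "tube_state"),
            inherits(mat, "material_params"),
            inherits(schedule, "pressure_schedule"))
  stopifnot_positive(duration_h, "duration_h")
  .check_tube_invariants(initial)
  t_save <- seq(0, duration_h, length.out = max(2L, n_save))
  state <- .equilibrate_elastic(initial, mat, schedule(0))
  states <- vector("list", length(t_save))
  states[[1L]] <- state
  truncated <- FALSE
  t <- 0 # hours
  dt_cap <- duration_h * 3600 / 200
  for (k in 2L:length(t_save)) {
    while (t < t_save[k] - 1e-12) {
      P <- schedule(t)
      segs <- state$segments
      rate <- hoop_stress(P, state$R, segs$h) / mat$eta[segs$compartment]
      rate_max <- max(rate, 0)
      dt_s <- if (rate_max > 0) deps_target / rate_max else dt_cap
      dt_s <- min(dt_s, dt_cap, (t_save[k] - t) * 3600)
      state <- maxwell_step(state, mat, P, dt_s)
      t <- t + dt_s / 3600
      if (state$R > 10 * state$R0) {
        truncated <- "radius exceeded 10x initial"
        break
      }
      if (min(state$segments$h / initial$segments$h) < 0.02) {
        # finite-time wall collapse (runaway thinning of a Maxwell shell)
        truncated <- "wall thinned below 2% of initial"
        break
      }
      sg <- state$segments
      if (max(hoop_stress(P, state$R, sg$h) / mat$E[sg$compartment]) >
          0.45) {
        # a pressure-controlled shell loses elastic equilibrium when the
        # hoop stress approaches the modulus (limit-point instability)
        truncated <- "approaching the elastic stability limit (stress ~ E/2)"
        break
      }
    }
    states[[k]] <- state
    if (!isFALSE(truncated)) {
      states <- states[seq_len(k)]
      t_save[k] <- t
      t_save <- t_save[seq_len(k)]
      warning("trajectory truncated at ", signif(t, 4), " h: ", truncated,
              call. = FALSE)
      break
    }
  }
  series <- do.call(rbind, lapply(seq_along(states), function(i) {
    s <- states[[i]]$segments
    data.frame(
      time_h = t_save[i], P_Pa = schedule(t_save[i]), R_um = states[[i]]$R,
      lumen_area_um2 = pi * states[[i]]$R^2,
      h_dorsal_um = mean(s$h[s$compartment == "dorsal"]),
      h_rest_um = mean(s$h[s$compartment == "rest"]))
  }))
  series$dorsal_ratio <- series$h_dorsal_um / series$h_dorsal_um[1L]
  series$rest_ratio <- series$h_rest_um / series$h_rest_um[1L]
  structure(list(time_h = t_save, states = states, series = series,
                 truncated = !isFALSE(truncated),
                 truncation_reason = if (isFALSE(truncated)) NULL else
                   truncated,
                 region = initial$region),
            class = "tube_trajectory")
}

.check_tube_invariants <- function(state, tol = 1e-3) {
  segs <- state$segments
  if (any(segs$h <= 0)) stop("tube state has non-positive thickness",
                             call. = FALSE)
  if (abs(sum(segs$l) - 2 * pi * state$R) > tol * 2 * pi * state$R) {
    stop("segment arc lengths inconsistent with lumen radius",
         call. = FALSE)
  }
  drift <- max(abs(segs$l * segs$h / state$lh0 - 1))
  if (drift > tol) {
    stop(sprintf("l*h conservation violated (drift %.2g)", drift),
         call. = FALSE)
  }
  invisible(state)
}

#' @export
print.tube_trajectory <- function(x, ...) {
  s <- x$series
  cat(sprintf(
    "<tube_trajectory> %s, %.3g h in %d snapshots%s\n", x$region,
    max(s$time_h), nrow(s), if (x$truncated) " (truncated)" else ""))
  cat(sprintf("  R: %.3g -> %.3g um; dorsal h ratio %.3f; rest h ratio %.3f\n",
              s$R_um[1L], s$R_um[nrow(s)], s$dorsal_ratio[nrow(s)],
              s$rest_ratio[nrow(s)]))
  invisible(x)
}

#' @export
plot.tube_trajectory <- function(x, ...) {
  s <- x$series
  plot(s$time_h, s$dorsal_ratio, type = "l", col = "firebrick",
       ylim = range(c(s$dorsal_ratio, s$rest_ratio, 1)),
       xlab = "time (h)", ylab = "thickness ratio (h / h0)",
       main = sprintf("%s tube under pressure", x$region), ...)
  lines(s$time_h, s$rest_ratio, col = "steelblue")
  abline(h = 1, lty = 3)
  legend("bottomleft", c("dorsal", "rest"), lty = 1,
         col = c("firebrick", "steelblue"), bty = "n")
  invisible(x)
}
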