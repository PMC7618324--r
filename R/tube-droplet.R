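# Ferrofluid droplet relaxing inside a viscoelastic tube.
#
# A droplet whose volume exceeds the largest sphere that fits the lumen is
# squeezed into a capsule (a cylinder of length L_cyl capped by two
# hemispheres of the lumen radius). Its caps carry a Laplace pressure
# 2*gamma/r_cap that loads the wall under the droplet; the Maxwell wall
# creeps, the local radius grows, and volume conservation shortens the
# capsule, so the aspect ratio relaxes toward 1 on the slow tissue
# timescale (hours), orders of magnitude longer than the droplet's own
# surface-tension/viscosity timescale.

.NL_UM3 <- 1e6 # 1 nl = 1e6 um^3

.capsule_geometry <- function(volume_um3, R_um) {
  v_sphere <- (4 / 3) * pi * R_um^3
  if (volume_um3 <= v_sphere) {
    return(list(L_cyl = 0, L = 2 * (3 * volume_um3 / (4 * pi))^(1 / 3),
                aspect = 1, elongated = FALSE))
  }
  L_cyl <- (volume_um3 - v_sphere) / (pi * R_um^2)
  list(L_cyl = L_cyl, L = L_cyl + 2 * R_um,
       aspect = (L_cyl + 2 * R_um) / (2 * R_um), elongated = TRUE)
}

#' Forward model: droplet rounding inside a Maxwell tube
#'
#' Quasi-static capsule model. At each instant the droplet cap (a
#' hemisphere of the current lumen radius) exerts the Laplace pressure
#' \eqn{\Delta P = 2\gamma/r_{cap}} on the wall; the wall creeps by
#' [maxwell_step()], the lumen radius under the droplet grows, and the
#' capsule length follows from droplet volume conservation (exact by
#' construction). Loading stops once the droplet fits the lumen as a
#' sphere (aspect ratio 1). The instantaneous elastic wall response is
#' applied before the first frame.
#'
#' @param state A [tube_state()] describing the wall at the droplet site.
#' @param mat A [material_params()].
#' @param droplet List with `volume_nl` and `gamma_N_m` (interfacial
#'   tension; 0 switches the driving force off).
#' @param t_grid_h Frame times (h), starting at 0, strictly increasing.
#' @param deps_target Target strain increment per internal time step.
#' @return Object of class `droplet_forward`: data.frame with `time_h`,
#'   `R_um` (droplet cap radius: the lumen radius while squeezed, the
#'   sphere radius once round), `R_lumen_um`, `L_um`, `aspect`, `dP_Pa`,
#'   `h_dorsal_um`; plus attributes `volume_nl`, `gamma_N_m`.
#' @export
droplet_in_tube_forward <- function(state, mat, droplet, t_grid_h,
                                    deps_target = 1e-3) {
  stopifnot(inherits(state, "tube_state"), inherits(mat, "material_params"))
  stopifnot_positive(droplet$volume_nl, "volume_nl")
  if (droplet$gamma_N_m < 0) stop("'gamma_N_m' must be >= 0", call. = FALSE)
  if (length(t_grid_h) < 2L || any(diff(t_grid_h) <= 0) || t_grid_h[1L] < 0) {
    stop("'t_grid_h' must be increasing and start at >= 0", call. = FALSE)
  }
  V <- droplet$volume_nl * .NL_UM3
  if (V <= (4 / 3) * pi * state$R^3) {
    stop(paste("droplet volume does not exceed the sphere that fits the",
               "lumen; no wall load, nothing to relax"), call. = FALSE)
  }
  gamma <- droplet$gamma_N_m
  lap_P <- function(R_um) if (gamma > 0) 2 * gamma / (R_um * .UM) else 0

  # instantaneous elastic response to the initial cap pressure
  st <- .equilibrate_elastic(state, mat, lap_P(state$R))
  rows <- vector("list", length(t_grid_h))
  fill <- function(i, st, t) {
    g <- .capsule_geometry(V, st$R)
    segs <- st$segments
    # cap radius: lumen radius while squeezed, sphere radius once round
    r_cap <- if (g$elongated) st$R else g$L / 2
    rows[[i]] <<- data.frame(
      time_h = t, R_um = r_cap, R_lumen_um = st$R, L_um = g$L,
      aspect = g$aspect,
      dP_Pa = if (g$elongated) lap_P(st$R) else 0,
      h_dorsal_um = mean(segs$h[segs$compartment == "dorsal"]))
  }
  t <- t_grid_h[1L]
  fill(1L, st, t)
  v0_check <- V
  for (k in 2L:length(t_grid_h)) {
    while (t < t_grid_h[k] - 1e-12) {
      g <- .capsule_geometry(V, st$R)
      if (!g$elongated || gamma == 0) { t <- t_grid_h[k]; break }
      P <- lap_P(st$R)
      segs <- st$segments
      rate <- hoop_stress(P, st$R, segs$h) / mat$eta[segs$compartment]
      rate_max <- max(rate, 0)
      dt_s <- if (rate_max > 0) deps_target / rate_max else
        (t_grid_h[k] - t) * 3600
      dt_s <- min(dt_s, (t_grid_h[k] - t) * 3600)
      st <- maxwell_step(st, mat, P, dt_s)
      t <- t + dt_s / 3600
    }
    fill(k, st, t_grid_h[k])
  }
  out <- do.call(rbind, rows)
  # droplet volume is conserved by construction; assert the capsule
  # geometry closes the loop to numerical precision
  v_back <- pi * out$R_um^2 * pmax(out$L_um - 2 * out$R_um, 0) +
    (4 / 3) * pi * out$R_um^3 * (out$L_um >= 2 * out$R_um)
  if (max(abs(v_back / v0_check - 1)) > 0.005) {
    stop("droplet volume conservation drift exceeded 0.5%", call. = FALSE)
  }
  structure(out, class = c("droplet_forward", "data.frame"),
            volume_nl = droplet$volume_nl, gamma_N_m = gamma,
            region = state$region)
}

#' Estimate wall viscosity from a droplet rounding series
#'
#' Simulation-based least squares: the effective Maxwell viscosity of the
#' wall is the value for which [droplet_in_tube_forward()] (run with a
#' single uniform viscosity; all other parameters fixed) best matches the
#' observed aspect-ratio series. A bootstrap over frame residuals gives a
#' confidence interval. A flat series (no measurable relaxation) is
#' declared unidentifiable and returns a lower bound flag instead of a
#' point estimate.
#'
#' @param series A `droplet_series` (see [gen_droplet_series()]), a
#'   `droplet_forward` data.frame, or any data.frame with `time_h` and
#'   `aspect` columns.
#' @param state The [tube_state()] at the droplet site (initial geometry).
#' @param mat_prior A [material_params()] supplying the elastic modulus and
#'   the centre of the viscosity search range.
#' @param droplet List with `volume_nl`, `gamma_N_m`.
#' @param n_boot Bootstrap replicates for the CI (0 disables).
#' @param search_decades Half-width of the log10 search interval around the
#'   prior viscosity.
#' @return List with `eta_hat` (Pa s), `ci` (2-vector), `residual_rms`,
#'   `lower_bound` flag, `n_frames`.
#' @export
estimate_viscosity_from_droplet <- function(series, state, mat_prior,
                                            droplet, n_boot = 50L,
                                            search_decades = 2) {
  obs <- .aspect_frame(series)
  if (nrow(obs) < 5L) stop("need >= 5 frames", call. = FALSE)
  if (obs$aspect[1L] <= 1) {
    stop("aspect ratio must exceed 1 at t = 0", call. = FALSE)
  }
  relax <- max(obs$aspect) - min(obs$aspect)
  if (relax < 0.02 * (obs$aspect[1L] - 1) || relax < 1e-4) {
    return(list(eta_hat = NA_real_, ci = c(NA_real_, NA_real_),
                residual_rms = NA_real_, lower_bound = TRUE,
                n_frames = nrow(obs)))
  }
  eta0 <- unname(mat_prior$eta["dorsal"])
  model_aspect <- function(log10_eta) {
    m <- material_params(eta_dorsal = 10^log10_eta,
                         eta_rest = 10^log10_eta,
                         E_dorsal = unname(mat_prior$E["dorsal"]),
                         E_rest = unname(mat_prior$E["rest"]))
    droplet_in_tube_forward(state, m, droplet, obs$time_h)$aspect
  }
  # model curves vary smoothly in log-viscosity: precompute them on a grid
  # once, then every (bootstrap) fit is a grid search with parabolic
  # refinement of log10(SSE) around the minimum
  le_grid <- seq(log10(eta0) - search_decades,
                 log10(eta0) + search_decades, length.out = 33L)
  curves <- vapply(le_grid, model_aspect, numeric(nrow(obs)))
  fit_once <- function(target) {
    sse <- colSums((curves - target)^2)
    i <- which.min(sse)
    if (i == 1L || i == length(le_grid)) return(10^le_grid[i])
    # parabola through the bracketing triple
    y <- sse[(i - 1L):(i + 1L)]
    dx <- le_grid[2L] - le_grid[1L]
    denom <- y[1L] - 2 * y[2L] + y[3L]
    shift <- if (denom > 0) 0.5 * (y[1L] - y[3L]) / denom else 0
    10^(le_grid[i] + max(min(shift, 1), -1) * dx)
  }
  eta_hat <- fit_once(obs$aspect)
  # polish the point estimate with a narrow continuous search
  o <- optimize(function(le) sum((model_aspect(le) - obs$aspect)^2),
                interval = log10(eta_hat) + c(-0.2, 0.2), tol = 1e-4)
  eta_hat <- 10^o$minimum
  pred <- model_aspect(log10(eta_hat))
  res <- obs$aspect - pred
  ci <- c(NA_real_, NA_real_)
  if (n_boot > 0L) {
    boots <- vapply(seq_len(n_boot), function(b) {
      synth <- pred + sample(res, length(res), replace = TRUE)
      log10(fit_once(synth))
    }, numeric(1L))
    # pivot on the grid-method estimate so its small systematic offset
    # from the polished estimate cancels in the interval
    b0 <- log10(fit_once(obs$aspect))
    ci <- 10^(log10(eta_hat) +
                unname(quantile(boots, c(0.025, 0.975))) - b0)
  }
  list(eta_hat = eta_hat, ci = ci,
       residual_rms = sqrt(mean(res^2)), lower_bound = FALSE,
       n_frames = nrow(obs))
}

# extract a (time_h, aspect) frame from the accepted series types
.aspect_frame <- function(series) {
  if (inherits(series, "droplet_series")) {
    return(data.frame(time_h = series$frames$time_h,
                      aspect = series$frames$aspect))
  }
  d <- as.data.frame(series)
  if (!all(c("time_h", "aspect") %in% names(d))) {
    stop("series must provide 'time_h' and 'aspect'", call. = FALSE)
  }
  d[, c("time_h", "aspect")]
}
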