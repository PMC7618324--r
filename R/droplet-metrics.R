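# Contour-based droplet metrics: cap curvature -> Laplace pressure,
# aspect ratio, and rounding-timescale fits. Contours are ordered 2-D
# point sets (um) in arbitrary orientation; every derived quantity is
# invariant to rotation and translation.

#' Capsule (stadium) contour generator
#'
#' Builds the closed outline of a capsule: a cylinder of length
#' `L - 2 * R` capped by two semicircles of radius `R`, major axis along
#' `angle_rad`. Used to synthesise droplet outlines.
#'
#' @param L Total length (um), >= `2 * R`.
#' @param R Cap radius (um).
#' @param n_points Number of contour points (>= 16).
#' @param angle_rad Major-axis orientation (rad).
#' @param center Centre (um), length-2.
#' @return Matrix `n_points x 2` of ordered (counter-clockwise) points.
#' @export
capsule_contour <- function(L, R, n_points = 200L, angle_rad = 0,
                            center = c(0, 0)) {
  stopifnot_positive(R, "R")
  if (L < 2 * R) stop("'L' must be >= 2 * R", call. = FALSE)
  if (n_points < 16L) stop("'n_points' must be >= 16", call. = FALSE)
  a <- L / 2 - R # half-length of the straight section
  per <- 2 * pi * R + 4 * a
  s <- seq(0, per, length.out = n_points + 1L)[-(n_points + 1L)]
  pt <- function(si) {
    if (si < a) return(c(si, -R))                     # bottom, right-going
    si <- si - a
    if (si < pi * R) {                                 # right cap
      th <- -pi / 2 + si / R
      return(c(a + R * cos(th), R * sin(th)))
    }
    si <- si - pi * R
    if (si < 2 * a) return(c(a - si, R))               # top, left-going
    si <- si - 2 * a
    if (si < pi * R) {                                 # left cap
      th <- pi / 2 + si / R
      return(c(-a + R * cos(th), R * sin(th)))
    }
    c(-a + (si - pi * R), -R)                          # bottom, to start
  }
  xy <- t(vapply(s, pt, numeric(2L)))
  rot <- matrix(c(cos(angle_rad), sin(angle_rad),
                  -sin(angle_rad), cos(angle_rad)), 2L, 2L)
  sweep(xy %*% t(rot), 2L, center, "+")
}

#' Circle fit to a droplet cap
#'
#' Least-squares (Kasa algebraic) circle fit to the cap arc at one end of
#' a closed droplet contour. The cap arc is the set of points whose
#' distance along the contour from the end extremum (the extreme point
#' along the major principal axis) is within 25% of the total contour
#' length. Collinear points give an infinite radius with a flag.
#'
#' @param contour Matrix/data.frame of ordered contour points (um).
#' @param end `"anterior"` (positive major-axis extreme) or
#'   `"posterior"`.
#' @return List with `r` (um), `center`, `fit_rms` (um), `degenerate`
#'   flag.
#' @export
cap_curvature <- function(contour, end = c("anterior", "posterior")) {
  end <- match.arg(end)
  xy <- .as_contour(contour)
  n <- nrow(xy)
  ctr <- colMeans(xy)
  cen <- sweep(xy, 2L, ctr)
  ax <- eigen(crossprod(cen) / n, symmetric = TRUE)$vectors[, 1L]
  proj <- cen %*% ax
  i_ext <- if (end == "anterior") which.max(proj) else which.min(proj)
  # arc distance from the extremum along the closed contour
  seg <- sqrt(rowSums((xy - xy[c(2:n, 1L), ])^2))
  per <- sum(seg)
  cum <- c(0, cumsum(seg))[seq_len(n)]
  d <- abs(cum - cum[i_ext])
  d <- pmin(d, per - d)
  sel <- d <= 0.125 * per # 25% of the contour length, centred on the tip
  if (sum(sel) < 8L) stop("fewer than 8 points in the cap arc",
                          call. = FALSE)
  .circle_fit(xy[sel, , drop = FALSE])
}

# Kasa algebraic circle fit; returns Inf radius with flag when the normal
# equations are singular (collinear points)
.circle_fit <- function(p) {
  x <- p[, 1L]; y <- p[, 2L]
  A <- cbind(2 * x, 2 * y, 1)
  b <- x^2 + y^2
  sol <- try(solve(crossprod(A), crossprod(A, b)), silent = TRUE)
  if (inherits(sol, "try-error") ||
      kappa(crossprod(A)) > 1e12) {
    return(list(r = Inf, center = c(NA_real_, NA_real_),
                fit_rms = NA_real_, degenerate = TRUE))
  }
  cx <- sol[1L]; cy <- sol[2L]
  r <- sqrt(sol[3L] + cx^2 + cy^2)
  res <- sqrt((x - cx)^2 + (y - cy)^2) - r
  list(r = r, center = c(cx, cy), fit_rms = sqrt(mean(res^2)),
       degenerate = FALSE)
}

#' Laplace pressure of a spherical cap
#'
#' Pressure jump across a curved interface of surface tension `gamma` and
#' cap radius `r`: \eqn{\Delta P = 2\gamma/r}. A smaller cap radius (as
#' observed for droplets in the narrow spinal cord) means a higher
#' pressure exerted on the surrounding tissue.
#'
#' @param r Cap radius (um), > 0.
#' @param gamma Interfacial tension (N/m).
#' @return Pressure (Pa).
#' @export
laplace_pressure <- function(r, gamma) {
  if (any(r <= 0)) stop("cap radius must be positive", call. = FALSE)
  2 * gamma / (r * .UM)
}

#' Aspect ratio of droplet contours over time
#'
#' For each frame, the aspect ratio is the extent along the major
#' principal axis divided by the maximal width perpendicular to it
#' (so a circle gives exactly 1 and a capsule of length L and width w
#' gives L/w). Degenerate (zero-area) contours are skipped with a
#' warning.
#'
#' @param series A `droplet_series` (see [gen_droplet_series()]) or a list
#'   of contour matrices.
#' @param times_h Frame times, required when `series` is a plain list.
#' @return data.frame with `time_h`, `aspect`.
#' @export
aspect_ratio_series <- function(series, times_h = NULL) {
  if (inherits(series, "droplet_series")) {
    contours <- series$contours
    times_h <- series$frames$time_h
  } else {
    contours <- series
    if (is.null(times_h)) times_h <- seq_along(contours) - 1
  }
  vals <- vapply(seq_along(contours), function(i) {
    xy <- .as_contour(contours[[i]])
    a <- .polygon_area(xy)
    if (!is.finite(a) || abs(a) < 1e-9) {
      warning(sprintf("frame %d: degenerate contour skipped", i),
              call. = FALSE)
      return(NA_real_)
    }
    cen <- sweep(xy, 2L, colMeans(xy))
    ev <- eigen(crossprod(cen) / nrow(cen), symmetric = TRUE)$vectors
    u <- cen %*% ev # rotate into principal frame
    diff(range(u[, 1L])) / diff(range(u[, 2L]))
  }, numeric(1L))
  out <- data.frame(time_h = times_h, aspect = vals)
  out[!is.na(out$aspect), , drop = FALSE]
}

.polygon_area <- function(xy) {
  n <- nrow(xy)
  j <- c(2:n, 1L)
  0.5 * sum(xy[, 1L] * xy[j, 2L] - xy[j, 1L] * xy[, 2L])
}

.as_contour <- function(x) {
  m <- as.matrix(as.data.frame(x))
  if (ncol(m) > 2L) m <- m[, c("x_um", "y_um")]
  storage.mode(m) <- "double"
  if (nrow(m) < 4L) stop("contour needs >= 4 points", call. = FALSE)
  unname(m)
}

#' Exponential rounding-timescale fit
#'
#' Fits \eqn{A(t) = A_\infty + (A_0 - A_\infty) e^{-t/\tau}} to an
#' aspect-ratio series by nonlinear least squares. The slow tissue-limited
#' timescale `tau` initialises the full simulation-based viscosity fit.
#' A series that does not span at least one relaxation e-fold is flagged
#' as a lower bound; an increasing series violates the relaxation model
#' and is refused.
#'
#' @param series Anything accepted by [aspect_ratio_series()] or a
#'   data.frame with `time_h` and `aspect`.
#' @return List with `tau_h`, `A_inf`, `A_0`, `residual_rms`,
#'   `lower_bound` flag.
#' @export
fit_rounding_timescale <- function(series) {
  d <- .aspect_frame(series)
  if (nrow(d) < 5L) stop("need >= 5 frames", call. = FALSE)
  a <- d$aspect; t <- d$time_h
  if (a[length(a)] > a[1L] + 1e-9) {
    stop("aspect ratio increases over time; relaxation fit refused",
         call. = FALSE)
  }
  span <- a[1L] - min(a)
  if (span < 1e-9 || (a[1L] - a[length(a)]) < (1 - exp(-1)) * (a[1L] - 1)) {
    # has not decayed one e-fold toward round: tau only bounded below
    lower <- TRUE
  } else lower <- FALSE
  if (span < 1e-9) {
    return(list(tau_h = NA_real_, A_inf = a[1L], A_0 = a[1L],
                residual_rms = 0, lower_bound = TRUE))
  }
  obj <- function(p) {
    m <- p[2L] + (p[1L] - p[2L]) * exp(-t / exp(p[3L]))
    sum((m - a)^2)
  }
  tau0 <- max(t[length(t)] / 3, 1e-3)
  fit <- optim(c(a[1L], min(a), log(tau0)), obj,
               control = list(maxit = 2000, reltol = 1e-12))
  list(tau_h = exp(fit$par[3L]), A_inf = fit$par[2L], A_0 = fit$par[1L],
       residual_rms = sqrt(fit$value / length(a)), lower_bound = lower)
}

#' Roof thickness at a droplet site
#'
#' The dorsal roof thickness at the point of maximum deformation,
#' operationalised as the minimum thickness within `window` um of arc
#' length from the dorsal midpoint (both sides). `window = 0` returns the
#' thickness exactly at the dorsal midpoint.
#'
#' @param section A `cross_section` (see [gen_cross_section()]).
#' @param window Arc-length window from the dorsal midpoint (um).
#' @param n_samples Profile sampling density per side.
#' @return Minimum dorsal thickness (um).
#' @export
roof_thickness_at_droplet <- function(section, window = 100,
                                      n_samples = 200L) {
  prof <- thickness_profile(section, n_samples = n_samples)
  if (window < 0) stop("'window' must be >= 0", call. = FALSE)
  if (window == 0) {
    i <- which.min(prof$samples$s_raw)
    return(prof$samples$thickness[i])
  }
  s_max <- max(prof$samples$s_raw)
  if (window > s_max) {
    warning("window exceeds contour extent; clipped", call. = FALSE)
    window <- s_max
  }
  sel <- prof$samples$s_raw <= window
  min(prof$samples$thickness[sel])
}
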