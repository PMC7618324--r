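# Cross-section geometry and circumferential thickness profilometry.
#
# Convention shared across the package: contours are ordered
# counter-clockwise with point 1 at the dorsal midpoint (12 o'clock);
# angles are measured from the dorsal midpoint, counter-clockwise
# positive. The ventral midpoint lies half the perimeter away.

#' Neural-tube cross-section contours
#'
#' @param inner,outer Matrices (n x 2) of ordered (counter-clockwise)
#'   contour points (um), point 1 at the dorsal midpoint.
#' @param metadata Named list (`embryo_id`, `region`, `stage`, ...).
#' @return Object of class `cross_section`.
#' @export
cross_section <- function(inner, outer, metadata = list()) {
  inner <- .as_contour(inner); outer <- .as_contour(outer)
  if (!.is_simple_polygon(outer)) {
    stop("outer contour is self-intersecting", call. = FALSE)
  }
  if (!.point_in_polygon(colMeans(inner), outer)) {
    stop("inner contour centroid not inside outer contour", call. = FALSE)
  }
  inside <- vapply(seq_len(nrow(inner)), function(i) {
    .point_in_polygon(inner[i, ], outer)
  }, logical(1L))
  if (!all(inside)) {
    stop("inner contour must lie strictly inside the outer contour",
         call. = FALSE)
  }
  structure(list(inner = inner, outer = outer, dorsal_index = 1L,
                 metadata = metadata),
            class = "cross_section")
}

#' @export
print.cross_section <- function(x, ...) {
  cat(sprintf("<cross_section> inner %d pts, outer %d pts%s\n",
              nrow(x$inner), nrow(x$outer),
              if (length(x$metadata$region))
                paste0(" (", x$metadata$region, ")") else ""))
  invisible(x)
}

# all-pairs segment intersection test (adjacent segments skipped);
# quadratic but vectorised, fine for contour-sized polygons
.is_simple_polygon <- function(poly) {
  n <- nrow(poly)
  if (n > 2000L) return(TRUE) # too large to check exhaustively
  a <- poly
  b <- poly[c(2:n, 1L), , drop = FALSE]
  idx <- which(outer(seq_len(n), seq_len(n), function(i, j) {
    j > i + 1L & !(i == 1L & j == n)
  }), arr.ind = TRUE)
  i <- idx[, 1L]; j <- idx[, 2L]
  d1 <- b[i, ] - a[i, ]; d2 <- b[j, ] - a[j, ]
  w <- a[j, ] - a[i, ]
  den <- d1[, 1L] * d2[, 2L] - d1[, 2L] * d2[, 1L]
  t1 <- (w[, 1L] * d2[, 2L] - w[, 2L] * d2[, 1L]) / den
  t2 <- (w[, 1L] * d1[, 2L] - w[, 2L] * d1[, 1L]) / den
  hit <- is.finite(t1) & is.finite(t2) &
    t1 > 1e-12 & t1 < 1 - 1e-12 & t2 > 1e-12 & t2 < 1 - 1e-12
  !any(hit)
}

.point_in_polygon <- function(p, poly) {
  n <- nrow(poly); j <- c(n, seq_len(n - 1L))
  xi <- poly[, 1L]; yi <- poly[, 2L]
  xj <- poly[j, 1L]; yj <- poly[j, 2L]
  cross <- ((yi > p[2L]) != (yj > p[2L])) &
    (p[1L] < (xj - xi) * (p[2L] - yi) / (yj - yi) + xi)
  sum(cross) %% 2L == 1L
}

#' Generate a synthetic neural-tube cross-section
#'
#' Radial construction around a circular lumen: the inner contour is a
#' circle of radius `R_inner` and the outer contour sits at
#' `R_inner + thickness(angle)` along the same radial direction, so the
#' ground-truth radial thickness is known exactly at every angle. Angle 0
#' is the dorsal midpoint (12 o'clock), counter-clockwise positive.
#'
#' Kinds: `"annulus"` (constant thickness), `"eccentric"` (outer circle of
#' radius `R_inner + thickness` whose centre is displaced ventrally by
#' `offset`), `"dorsally_thinned"` (thickness interpolating from
#' `thickness_dorsal` at angle 0 to `thickness_ventral` at the ventral
#' midpoint via `(1 - cos(angle))/2`). Any kind accepts `thickness_fn`,
#' a function of angle (rad), overriding the built-in thickness law —
#' e.g. to dimple the roof at a droplet site.
#'
#' @param shape List with `kind`, `R_inner` (um), `n_points` (>= 36) and
#'   kind-specific fields: `thickness` (annulus/eccentric),
#'   `offset` (eccentric), `thickness_dorsal`/`thickness_ventral`
#'   (dorsally_thinned), optional `thickness_fn`.
#' @param metadata Passed to [cross_section()].
#' @return A [cross_section()] with ground-truth thickness attached as
#'   `metadata$thickness_fn`.
#' @export
gen_cross_section <- function(shape, metadata = list()) {
  kind <- match.arg(shape$kind, c("annulus", "eccentric",
                                  "dorsally_thinned"))
  R <- shape$R_inner
  stopifnot_positive(R, "R_inner")
  n <- shape$n_points %||% 360L
  if (n < 36L) stop("'n_points' must be >= 36", call. = FALSE)
  theta <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  u <- cbind(-sin(theta), cos(theta)) # ccw from 12 o'clock
  inner <- R * u
  h_fn <- shape$thickness_fn
  if (is.null(h_fn)) {
    h_fn <- switch(kind,
      annulus = {
        h <- shape$thickness; stopifnot_positive(h, "thickness")
        function(th) rep_len(h, length(th))
      },
      eccentric = {
        h <- shape$thickness; stopifnot_positive(h, "thickness")
        off <- shape$offset %||% 0
        b <- R + h
        if (off >= h) stop("eccentric offset must be smaller than thickness",
                           call. = FALSE)
        # outer circle centred 'off' um ventrally (straight down)
        function(th) {
          uc <- -off * cos(th) # dot(u, c) with c = (0, -off)
          -R + (uc + sqrt(b^2 - off^2 + uc^2))
        }
      },
      dorsally_thinned = {
        hd <- shape$thickness_dorsal; hv <- shape$thickness_ventral
        stopifnot_positive(hd, "thickness_dorsal")
        stopifnot_positive(hv, "thickness_ventral")
        function(th) hd + (hv - hd) * (1 - cos(th)) / 2
      })
  }
  h <- h_fn(theta)
  if (any(!is.finite(h)) || any(h <= 0)) {
    stop("thickness function must be positive and finite on [0, 2*pi)",
         call. = FALSE)
  }
  # radial construction with positive radii is star-shaped, hence simple
  outer <- (R + h) * u
  md <- modifyList(metadata, list(thickness_fn = h_fn, kind = kind,
                                  R_inner = R))
  cross_section(inner, outer, metadata = md)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Circumferential thickness profile of a cross-section
#'
#' The quantification behind the dorsal-thinning readout: at equally
#' spaced arc positions along the inner (lumenal) contour, the tissue
#' thickness is the distance from the inner point to the outer contour
#' along the local inner-surface normal (nearest intersection wins).
#' Positions run from the dorsal midpoint (arc distance 0) to the ventral
#' midpoint on each side; `s_norm` rescales each side to \[0, 1\]
#' (0 = dorsal midpoint, 1 = ventral midpoint).
#'
#' @param section A [cross_section()].
#' @param n_samples Samples per side.
#' @return Object of class `thickness_profile`: list with `samples`
#'   (data.frame `side` in left/right, `s_raw` um, `s_norm`, `thickness`
#'   um), `side_lengths` (um), `metadata`. Samples whose normal misses the
#'   outer contour are dropped with a warning; more than 10% dropped
#'   refuses the profile.
#' @export
thickness_profile <- function(section, n_samples = 100L) {
  stopifnot(inherits(section, "cross_section"))
  inner <- section$inner; outer <- section$outer
  n <- nrow(inner)
  seg <- sqrt(rowSums((inner[c(2:n, 1L), ] - inner)^2))
  cum <- c(0, cumsum(seg)) # cum[i] = arc length from point 1 to point i
  per <- cum[n + 1L]
  half <- per / 2 # ventral midpoint arc position
  pos_at <- function(s) { # position and unit tangent at arc length s
    s <- s %% per
    i <- findInterval(s, cum, rightmost.closed = TRUE)
    i <- pmin(pmax(i, 1L), n)
    frac <- (s - cum[i]) / seg[i]
    p1 <- inner[i, , drop = FALSE]
    p2 <- inner[ifelse(i == n, 1L, i + 1L), , drop = FALSE]
    list(p = p1 + frac * (p2 - p1),
         tang = (p2 - p1) / seg[i])
  }
  sample_side <- function(side) {
    s <- seq(0, half, length.out = n_samples)
    s_c <- if (side == "left") s else (per - s) %% per # ccw vs cw
    at <- pos_at(s_c)
    # outward normal for a ccw contour: rotate tangent clockwise
    nrm <- cbind(at$tang[, 2L], -at$tang[, 1L])
    th <- vapply(seq_len(n_samples), function(j) {
      .ray_polygon_distance(at$p[j, ], nrm[j, ], outer)
    }, numeric(1L))
    data.frame(side = side, s_raw = s, s_norm = s / half, thickness = th)
  }
  samples <- rbind(sample_side("left"), sample_side("right"))
  miss <- !is.finite(samples$thickness)
  if (any(miss)) {
    warning(sprintf("%d sample(s) dropped: normal missed the outer contour",
                    sum(miss)), call. = FALSE)
    if (mean(miss) > 0.10) {
      stop("more than 10% of samples dropped; profile refused",
           call. = FALSE)
    }
    samples <- samples[!miss, , drop = FALSE]
  }
  structure(list(samples = samples,
                 side_lengths = c(left = half, right = half),
                 metadata = section$metadata),
            class = "thickness_profile")
}

# distance along ray p + t*d (t > 0) to nearest crossing of the polygon
.ray_polygon_distance <- function(p, d, poly) {
  n <- nrow(poly)
  a <- poly
  b <- poly[c(2:n, 1L), , drop = FALSE]
  ex <- b[, 1L] - a[, 1L]; ey <- b[, 2L] - a[, 2L]
  den <- d[1L] * (-ey) + d[2L] * ex
  wx <- a[, 1L] - p[1L]; wy <- a[, 2L] - p[2L]
  tt <- (wx * (-ey) + wy * ex) / den
  vv <- (d[1L] * wy - d[2L] * wx) / den
  ok <- is.finite(tt) & tt > 1e-9 & vv >= 0 & vv < 1
  if (!any(ok)) return(NA_real_)
  min(tt[ok])
}

#' @export
print.thickness_profile <- function(x, ...) {
  s <- x$samples
  cat(sprintf(
    "<thickness_profile> %d samples, thickness %.3g-%.3g um, side length %.3g um\n",
    nrow(s), min(s$thickness), max(s$thickness), x$side_lengths[1L]))
  invisible(x)
}

#' Normalise and average thickness profiles
#'
#' Resamples every profile onto a common normalised-arc grid
#' (`s_norm` in \[0, 1\], 0 = dorsal, 1 = ventral midpoint), pools the
#' samples from all profiles and both sides, and least-squares fits a
#' 4th-degree polynomial to give an average thickness profile for the
#' group. Profiles with fewer than 5 usable samples are excluded with a
#' warning.
#'
#' @param profiles A [thickness_profile()] or list of them.
#' @param n_grid Grid resolution on \[0, 1\].
#' @return List with `grid` (s values), `mean_profile` (pooled mean
#'   thickness per grid point), `poly_coef` (named, intercept first),
#'   `poly_fit` (the `lm`), `fitted` (polynomial evaluated on the grid),
#'   `n_profiles`.
#' @export
normalise_and_average <- function(profiles, n_grid = 101L) {
  if (inherits(profiles, "thickness_profile")) profiles <- list(profiles)
  if (!length(profiles)) stop("need at least one profile", call. = FALSE)
  grid <- seq(0, 1, length.out = n_grid)
  resampled <- list()
  pooled <- list()
  kept <- 0L
  for (pr in profiles) {
    if (nrow(pr$samples) < 5L) {
      warning("profile with < 5 samples excluded", call. = FALSE)
      next
    }
    kept <- kept + 1L
    per_side <- lapply(split(pr$samples, pr$samples$side), function(d) {
      approx(d$s_norm, d$thickness, xout = grid, rule = 2)$y
    })
    resampled[[kept]] <- rowMeans(do.call(cbind, per_side))
    pooled[[kept]] <- pr$samples[, c("s_norm", "thickness")]
  }
  if (!kept) stop("no usable profiles", call. = FALSE)
  pooled <- do.call(rbind, pooled)
  fit <- lm(thickness ~ s_norm + I(s_norm^2) + I(s_norm^3) + I(s_norm^4),
            data = pooled)
  list(grid = grid,
       mean_profile = rowMeans(do.call(cbind, resampled)),
       poly_coef = coef(fit),
       poly_fit = fit,
       fitted = unname(predict(fit, data.frame(s_norm = grid))),
       n_profiles = kept)
}
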