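#' Dorsal roof metrics from a thickness profile
#'
#' Two readouts of roof morphology: the mean thickness of the first
#' `window` um of dorsal roof tissue from the dorsal midpoint (100 um for
#' intubation-style comparisons, 300 um for osmotic-pressure comparisons),
#' averaged over both sides; and the single-cell-thick roof length, the
#' total arc length (both sides) over which the tissue stays at or below
#' `single_cell_thickness`, measured contiguously from the dorsal
#' midpoint (per side, the arc position of the last contiguous sample
#' satisfying the threshold).
#'
#' @param profile A [thickness_profile()].
#' @param window Arc-length window (um); the conventional choices are 100
#'   and 300.
#' @param single_cell_thickness Threshold (um) defining "single-cell
#'   thick"; default 10.
#' @return List with `mean_roof_thickness` (um; `NA` with a reason if the
#'   window is uncovered), `roof_length` (um), `window`,
#'   `single_cell_thickness`.
#' @export
roof_metrics <- function(profile, window = 100,
                         single_cell_thickness =
                           nt_defaults()$shape$single_cell_thickness_um) {
  stopifnot(inherits(profile, "thickness_profile"))
  s <- profile$samples
  mean_thick <- NA_real_
  reason <- NULL
  if (window > max(s$s_raw)) {
    reason <- "window exceeds profile extent; metric omitted"
    warning(reason, call. = FALSE)
  } else {
    sel <- s$s_raw <= window
    mean_thick <- mean(s$thickness[sel])
  }
  roof_len <- sum(vapply(split(s, s$side), function(d) {
    d <- d[order(d$s_raw), , drop = FALSE]
    ok <- d$thickness <= single_cell_thickness
    if (!length(ok) || !ok[1L]) return(0)
    run_end <- which(!ok)[1L]
    last <- if (is.na(run_end)) nrow(d) else run_end - 1L
    d$s_raw[last]
  }, numeric(1L)))
  list(mean_roof_thickness = mean_thick, roof_length = roof_len,
       window = window, single_cell_thickness = single_cell_thickness,
       omitted_reason = reason)
}

#' Bin apical intensity along the dorsoventral axis
#'
#' Splits an apical-surface intensity trace (measured from the dorsal
#' midpoint moving ventrally) into 2 or 3 equal-arc-length bins and
#' returns the mean normalised intensity per bin. Normalisation divides by
#' the trace maximum (default) or mean. Bin means are arc-length-weighted
#' (trapezoidal) averages of the linearly interpolated trace, so a linear
#' ramp from 0 to 1 gives exactly 0.25 and 0.75 with two bins.
#'
#' @param trace data.frame with `position_um` (increasing, from the dorsal
#'   midpoint) and `intensity` (arbitrary units, >= 0).
#' @param n_bins 2 or 3.
#' @param normalise `"max"` or `"mean"`.
#' @return data.frame with `bin`, `from_um`, `to_um`,
#'   `mean_norm_intensity`.
#' @export
apical_intensity_bins <- function(trace, n_bins = 3L,
                                  normalise = c("max", "mean")) {
  normalise <- match.arg(normalise)
  if (!all(c("position_um", "intensity") %in% names(trace))) {
    stop("trace needs 'position_um' and 'intensity' columns", call. = FALSE)
  }
  if (!nrow(trace)) stop("empty trace", call. = FALSE)
  if (!(n_bins %in% c(2L, 3L))) stop("'n_bins' must be 2 or 3",
                                     call. = FALSE)
  p <- trace$position_um; y <- trace$intensity
  if (any(diff(p) <= 0)) stop("'position_um' must be increasing",
                              call. = FALSE)
  y <- switch(normalise, max = y / max(y), mean = y / mean(y))
  edges <- seq(p[1L], p[length(p)], length.out = n_bins + 1L)
  out <- lapply(seq_len(n_bins), function(b) {
    lo <- edges[b]; hi <- edges[b + 1L]
    inside <- p > lo & p < hi
    if (!any(p >= lo & p <= hi)) {
      stop(sprintf("bin %d contains no samples; trace too sparse", b),
           call. = FALSE)
    }
    xs <- c(lo, p[inside], hi)
    ys <- approx(p, y, xout = xs, rule = 2)$y
    m <- sum(diff(xs) * (head(ys, -1L) + tail(ys, -1L)) / 2) / (hi - lo)
    data.frame(bin = b, from_um = lo, to_um = hi, mean_norm_intensity = m)
  })
  do.call(rbind, out)
}

#' Synthetic apical intensity trace
#'
#' Emulates an apical actin/myosin intensity trace with dorsal depletion:
#' intensity rises from `dorsal_level` at the dorsal midpoint to
#' `ventral_level` ventrally (smooth cosine interpolation) with additive
#' Gaussian noise, mimicking the reduced apical actin of a fluidised
#' dorsal roof.
#'
#' @param length_um Trace length (um).
#' @param n_points Samples.
#' @param dorsal_level,ventral_level Intensity levels (a.u.).
#' @param noise_sd Additive noise sd (a.u.).
#' @param seed Integer seed.
#' @return data.frame with `position_um`, `intensity`.
#' @export
gen_intensity_trace <- function(length_um = 300, n_points = 150L,
                                dorsal_level = 0.3, ventral_level = 1,
                                noise_sd = 0, seed = 1L) {
  stopifnot_positive(length_um, "length_um")
  p <- seq(0, length_um, length.out = n_points)
  base <- dorsal_level + (ventral_level - dorsal_level) *
    (1 - cos(pi * p / length_um)) / 2
  if (noise_sd > 0) {
    set.seed(seed)
    base <- pmax(base + rnorm(n_points, sd = noise_sd), 0)
  }
  data.frame(position_um = p, intensity = base)
}
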