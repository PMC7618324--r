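#' Material parameters of the tube wall
#'
#' Maxwell viscoelastic parameters per angular compartment. The tube wall
#' carries a dorsal compartment (less viscous in the hindbrain, emulating
#' neural-crest-associated fluidisation) and a "rest" compartment. `Inf`
#' viscosity encodes a purely elastic compartment.
#'
#' @param eta_dorsal,eta_rest Maxwell viscosities (Pa s), > 0 or `Inf`.
#' @param E_dorsal,E_rest Elastic moduli (Pa), > 0.
#' @return Object of class `material_params`.
#' @export
material_params <- function(eta_dorsal = nt_defaults()$materials$eta_dorsal_Pa_s,
                            eta_rest = nt_defaults()$materials$eta_rest_Pa_s,
                            E_dorsal = nt_defaults()$materials$E_Pa,
                            E_rest = E_dorsal) {
  for (v in c(eta_dorsal, eta_rest, E_dorsal, E_rest)) {
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v <= 0) {
      stop("moduli and viscosities must be positive (Inf allowed to switch a branch off)",
           call. = FALSE)
    }
  }
  structure(list(eta = c(dorsal = eta_dorsal, rest = eta_rest),
                 E = c(dorsal = E_dorsal, rest = E_rest)),
            class = "material_params")
}

#' Angularly discretised thin-shell tube state
#'
#' The tube cross-section is a circular lumen of radius `R` surrounded by a
#' thin shell discretised into angular segments, each carrying its arc
#' length, thickness, compartment label (dorsal sector vs rest), hoop
#' stress and accumulated strain. The dorsal midpoint is at angle 0
#' (12 o'clock) and angles increase counter-clockwise; the dorsal sector is
#' centred on it. Tissue is incompressible in cross-section, so each
#' segment's arc-length x thickness product is conserved as it deforms.
#'
#' @param R0 Initial lumen radius (um).
#' @param h0 Initial wall thickness (um), scalar or per segment.
#' @param n_segments Number of angular segments (>= 8).
#' @param dorsal_sector_deg Angular width of the dorsal compartment
#'   (degrees, centred on the dorsal midpoint).
#' @param region Label, e.g. `"hindbrain"` or `"spinal_cord"`.
#' @return Object of class `tube_state`: list with `segments` (data.frame
#'   `angle`, `l`, `h`, `compartment`, `stress`, `strain`), `R`, `region`,
#'   and the conserved reference `lh0 = l0 * h0` per segment.
#' @export
tube_state <- function(R0, h0, n_segments = 36L, dorsal_sector_deg = 60,
                       region = "hindbrain") {
  stopifnot_positive(R0, "R0")
  if (n_segments < 8L) stop("'n_segments' must be >= 8", call. = FALSE)
  if (any(h0 <= 0)) stop("'h0' must be positive", call. = FALSE)
  n <- as.integer(n_segments)
  # segment centres, wrapped to (-pi, pi]; 0 = dorsal midpoint
  ang <- ((seq_len(n) - 0.5) / n) * 2 * pi
  ang <- ifelse(ang > pi, ang - 2 * pi, ang)
  l <- rep(2 * pi * R0 / n, n)
  h <- rep_len(h0, n)
  comp <- ifelse(abs(ang) <= (dorsal_sector_deg / 2) * pi / 180,
                 "dorsal", "rest")
  segs <- data.frame(angle = ang, l = l, h = h, compartment = comp,
                     stress = 0, strain = 0)
  structure(list(segments = segs, R = R0, region = region,
                 lh0 = l * h, R0 = R0),
            class = "tube_state")
}

#' Geometry presets for the tube model
#'
#' `"hindbrain"` is a large-radius tube, `"spinal_cord"` a small-radius
#' tube (its higher dorsal curvature enters the thin-shell model only
#' through the radius); both have 40 um walls and a 60 degree dorsal
#' sector. `stage = "droplet_site"` gives the smaller pre-expansion radii
#' used for droplet experiments.
#'
#' @param region `"hindbrain"` or `"spinal_cord"`.
#' @param stage `"expansion"` (default) or `"droplet_site"`.
#' @param n_segments Number of angular segments.
#' @return A [tube_state()].
#' @export
tube_preset <- function(region = c("hindbrain", "spinal_cord"),
                        stage = c("expansion", "droplet_site"),
                        n_segments = 36L) {
  region <- match.arg(region)
  stage <- match.arg(stage)
  g <- nt_defaults()$geometry
  geo <- if (stage == "expansion") g[[region]] else g$droplet_site[[region]]
  tube_state(geo$R0_um, geo$h0_um, n_segments = n_segments,
             dorsal_sector_deg = geo$dorsal_sector_deg, region = region)
}

#' @export
print.tube_state <- function(x, ...) {
  s <- x$segments
  cat(sprintf(
    "<tube_state> %s: R = %.3g um, %d segments (%d dorsal), h = [%.3g, %.3g] um\n",
    x$region, x$R, nrow(s), sum(s$compartment == "dorsal"),
    min(s$h), max(s$h)))
  invisible(x)
}

#' Piecewise-linear lumen-pressure schedule
#'
#' @param times_h Knot times (h), strictly increasing.
#' @param pressures_Pa Pressure at each knot (Pa, >= 0). Values are
#'   interpolated linearly and held constant beyond the last knot.
#' @return Object of class `pressure_schedule` (callable: `sched(t_h)`).
#' @export
pressure_schedule <- function(times_h, pressures_Pa) {
  if (length(times_h) != length(pressures_Pa) || length(times_h) < 1L) {
    stop("times and pressures must have equal positive length",
         call. = FALSE)
  }
  if (any(pressures_Pa < 0)) stop("pressures must be >= 0", call. = FALSE)
  if (length(times_h) > 1L && any(diff(times_h) <= 0)) {
    stop("'times_h' must be strictly increasing", call. = FALSE)
  }
  f <- if (length(times_h) == 1L) {
    function(t) rep_len(pressures_Pa, length(t))
  } else {
    function(t) approx(times_h, pressures_Pa, xout = t, rule = 2)$y
  }
  structure(f, class = c("pressure_schedule", "function"),
            knots = data.frame(time_h = times_h, P_Pa = pressures_Pa))
}

#' @rdname pressure_schedule
#' @param preset One of `"onset_to_late"` (15 Pa rising linearly to 25 Pa
#'   over `duration_h`), `"intubation"` (0 Pa: lumen open to ambient) or
#'   `"bdx"` (1.3 x the onset-to-late baseline, the osmotic pressure
#'   increase).
#' @param duration_h Duration over which the rise occurs (h).
#' @export
pressure_schedule_preset <- function(preset = c("onset_to_late",
                                                "intubation", "bdx"),
                                     duration_h = 20) {
  preset <- match.arg(preset)
  p <- nt_defaults()$pressure_Pa
  switch(preset,
    onset_to_late = pressure_schedule(c(0, duration_h), c(p$onset, p$late)),
    intubation = pressure_schedule(0, p$intubation),
    bdx = pressure_schedule(c(0, duration_h),
                            p$bdx_factor * c(p$onset, p$late)))
}
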