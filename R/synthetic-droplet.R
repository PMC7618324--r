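#' Generate a synthetic droplet rounding series
#'
#' Runs the droplet-in-tube forward model ([droplet_in_tube_forward()])
#' with the ground-truth wall material, builds a capsule contour for every
#' frame and adds Gaussian noise of sd `gt$noise_sd` (um) to the contour
#' coordinates. The observed per-frame aspect ratio is then re-measured
#' from the noisy contours through [aspect_ratio_series()], so the series
#' exercises the same contour pipeline as real data; the noiseless truth
#' is kept alongside. Presets follow the experimental volumes: 4 nl in the
#' larger hindbrain lumen, 1 nl in the smaller spinal-cord lumen.
#'
#' @param gt A [ground_truth()] (wall viscosities, shell modulus, noise,
#'   seed).
#' @param tube A [tube_state()] at the droplet site; the droplet volume
#'   must exceed the largest sphere fitting its lumen.
#' @param droplet List with `volume_nl`, `gamma_N_m`.
#' @param duration_h Observation window (h).
#' @param n_frames Number of frames (>= 5).
#' @param n_contour_points Points per frame contour.
#' @return Object of class `droplet_series`: list with `frames`
#'   (data.frame `time_h`, `aspect` measured from noisy contours,
#'   `aspect_true`, `R_um`, `L_um`), `contours` (list of n x 2 matrices),
#'   `gt`, `droplet`.
#' @export
gen_droplet_series <- function(gt, tube,
                               droplet = list(volume_nl = 4,
                                              gamma_N_m =
                                                nt_defaults()$droplet$gamma_N_m),
                               duration_h = 12, n_frames = 13L,
                               n_contour_points = 200L) {
  stopifnot(inherits(gt, "ground_truth"), inherits(tube, "tube_state"))
  if (n_frames < 5L) stop("'n_frames' must be >= 5", call. = FALSE)
  mat <- material_params(eta_dorsal = gt$eta_dorsal,
                         eta_rest = gt$eta_rest,
                         E_dorsal = gt$E_shell)
  t_grid <- seq(0, duration_h, length.out = n_frames)
  fwd <- droplet_in_tube_forward(tube, mat, droplet, t_grid)
  set.seed(gt$seed)
  contours <- lapply(seq_len(nrow(fwd)), function(i) {
    xy <- capsule_contour(fwd$L_um[i], fwd$R_um[i],
                          n_points = n_contour_points)
    if (gt$noise_sd > 0) {
      xy <- xy + matrix(rnorm(length(xy), sd = gt$noise_sd), ncol = 2L)
    }
    xy
  })
  meas <- aspect_ratio_series(contours, times_h = fwd$time_h)
  frames <- data.frame(time_h = fwd$time_h,
                       aspect = meas$aspect[match(fwd$time_h,
                                                  meas$time_h)],
                       aspect_true = fwd$aspect,
                       R_um = fwd$R_um, L_um = fwd$L_um)
  structure(list(frames = frames, contours = contours, gt = gt,
                 droplet = droplet, region = tube$region),
            class = "droplet_series")
}

#' @export
print.droplet_series <- function(x, ...) {
  f <- x$frames
  cat(sprintf(
    "<droplet_series> %s: %d frames over %.3g h, aspect %.3f -> %.3f\n",
    x$region %||% "?", nrow(f), max(f$time_h),
    f$aspect_true[1L], f$aspect_true[nrow(f)]))
  invisible(x)
}
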