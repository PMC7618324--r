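#' AFM creep experiment record
#'
#' Container for a single AFM indentation creep experiment: a time series of
#' applied force and measured indentation together with the bead radius.
#' This is the object both the force-ramp fit and the creep fit consume.
#'
#' @param time_s Sample times (s), strictly increasing.
#' @param force_nN Applied force (nN), non-negative.
#' @param indentation_um Measured indentation (um).
#' @param bead_radius_um Radius of the spherical probe bead (um).
#' @param phase Optional character vector labelling each sample
#'   `"ramp"` or `"hold"`. If missing, samples at >= 99% of the maximum
#'   force are labelled `"hold"`.
#' @param metadata Optional named list (embryo id, region, ...).
#'
#' @return An object of class `creep_record`: a list with elements `time_s`,
#'   `force_nN`, `indentation_um`, `bead_radius_um`, `phase`, `metadata`.
#' @export
creep_record <- function(time_s, force_nN, indentation_um, bead_radius_um,
                         phase = NULL, metadata = list()) {
  time_s <- as.numeric(time_s)
  force_nN <- as.numeric(force_nN)
  indentation_um <- as.numeric(indentation_um)
  n <- length(time_s)
  if (length(force_nN) != n || length(indentation_um) != n) {
    stop("time, force and indentation must have equal length", call. = FALSE)
  }
  if (n < 2L || any(diff(time_s) <= 0)) {
    stop("'time_s' must be strictly increasing with at least 2 samples",
         call. = FALSE)
  }
  if (any(!is.finite(time_s)) || any(!is.finite(force_nN))) {
    stop("non-finite values in time or force", call. = FALSE)
  }
  if (any(force_nN < -sqrt(.Machine$double.eps))) {
    stop("'force_nN' must be non-negative", call. = FALSE)
  }
  stopifnot_positive(bead_radius_um, "bead_radius_um")
  if (is.null(phase)) {
    phase <- ifelse(force_nN >= 0.99 * max(force_nN), "hold", "ramp")
  }
  phase <- as.character(phase)
  if (length(phase) != n || !all(phase %in% c("ramp", "hold"))) {
    stop("'phase' must label every sample 'ramp' or 'hold'", call. = FALSE)
  }
  structure(
    list(time_s = time_s, force_nN = force_nN,
         indentation_um = indentation_um,
         bead_radius_um = bead_radius_um, phase = phase,
         metadata = metadata),
    class = "creep_record"
  )
}

#' @export
print.creep_record <- function(x, ...) {
  cat(sprintf(
    "<creep_record> %d samples, t = [%.3g, %.3g] s, F_max = %.3g nN, bead R = %.3g um\n",
    length(x$time_s), min(x$time_s), max(x$time_s), max(x$force_nN),
    x$bead_radius_um))
  cat(sprintf("  phases: %d ramp, %d hold\n",
              sum(x$phase == "ramp"), sum(x$phase == "hold")))
  invisible(x)
}

#' @export
as.data.frame.creep_record <- function(x, ...) {
  data.frame(time_s = x$time_s, force_nN = x$force_nN,
             indentation_um = x$indentation_um, phase = x$phase)
}

#' Read / write creep records as CSV
#'
#' CSV schema: columns `time_s`, `force_nN`, `indentation_um`, `phase`;
#' the bead radius is carried in a `# bead_radius_um: <value>` comment on
#' the first line so the file is self-contained.
#'
#' @param rec A [creep_record()].
#' @param path File path.
#' @return `write_creep_csv` returns `path` invisibly; `read_creep_csv`
#'   returns a [creep_record()].
#' @export
write_creep_csv <- function(rec, path) {
  stopifnot(inherits(rec, "creep_record"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# bead_radius_um: %.10g", rec$bead_radius_um), con)
  write.csv(as.data.frame(rec), con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_creep_csv
#' @export
read_creep_csv <- function(path) {
  first <- readLines(path, n = 1L)
  r <- NA_real_
  if (grepl("^#\\s*bead_radius_um:", first)) {
    r <- as.numeric(sub("^#\\s*bead_radius_um:\\s*", "", first))
  }
  if (!is.finite(r)) stop("missing '# bead_radius_um:' header in ", path,
                          call. = FALSE)
  d <- read.csv(path, comment.char = "#")
  creep_record(d$time_s, d$force_nN, d$indentation_um, r, phase = d$phase)
}
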