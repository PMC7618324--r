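# Shared CSV schemas for contour data and fit JSON output.
# Contour CSV columns: frame, boundary (inner|outer|droplet), point_index,
# x_um, y_um. Long/tidy, one row per point.

#' Write / read contour CSV (shared schema)
#'
#' @param x A [cross_section()], a `droplet_series`, or a named list of
#'   contour matrices (names become the `boundary` column).
#' @param path File path.
#' @return `write_contours_csv` returns `path` invisibly;
#'   `read_contours_csv` returns the contour data.frame, and
#'   `read_cross_section_csv` reassembles a [cross_section()] from it.
#' @export
write_contours_csv <- function(x, path) {
  rows <- NULL
  if (inherits(x, "cross_section")) {
    rows <- rbind(
      .contour_rows(x$inner, 1L, "inner"),
      .contour_rows(x$outer, 1L, "outer"))
  } else if (inherits(x, "droplet_series")) {
    rows <- do.call(rbind, lapply(seq_along(x$contours), function(i) {
      .contour_rows(x$contours[[i]], i, "droplet")
    }))
  } else if (is.list(x)) {
    if (is.null(names(x))) stop("contour list must be named", call. = FALSE)
    rows <- do.call(rbind, lapply(names(x), function(nm) {
      .contour_rows(x[[nm]], 1L, nm)
    }))
  } else stop("unsupported contour container", call. = FALSE)
  write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

.contour_rows <- function(xy, frame, boundary) {
  xy <- .as_contour(xy)
  data.frame(frame = frame, boundary = boundary,
             point_index = seq_len(nrow(xy)),
             x_um = xy[, 1L], y_um = xy[, 2L])
}

#' @rdname write_contours_csv
#' @export
read_contours_csv <- function(path) {
  d <- read.csv(path)
  need <- c("frame", "boundary", "point_index", "x_um", "y_um")
  if (!all(need %in% names(d))) {
    stop("contour CSV must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  d[order(d$frame, d$boundary, d$point_index), ]
}

#' @rdname write_contours_csv
#' @export
read_cross_section_csv <- function(path) {
  d <- read_contours_csv(path)
  pick <- function(b) {
    sub <- d[d$boundary == b, ]
    if (!nrow(sub)) stop("contour CSV lacks '", b, "' boundary",
                         call. = FALSE)
    as.matrix(sub[, c("x_um", "y_um")])
  }
  cross_section(pick("inner"), pick("outer"))
}

#' Write a fit object as JSON
#'
#' Serialises ramp/rheology/Hertz fits (or any named list of scalars) with
#' full numeric precision.
#'
#' @param fit A fit object or named list.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(fit, path) {
  jsonlite::write_json(unclass(fit), path, auto_unbox = TRUE, digits = NA,
                       null = "null", force = TRUE)
  invisible(path)
}
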