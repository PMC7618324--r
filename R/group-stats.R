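#' Two-group comparison with normality check
#'
#' The statistical recipe used throughout the analyses: a two-sided t test
#' (paired for within-embryo AFM comparisons, independent otherwise) with a
#' Shapiro-Wilk normality check per group and a fixed 0.05 significance
#' threshold reported alongside the p value rather than decided silently.
#'
#' Inputs may be numeric vectors or lists of `rheology_fit` objects, in
#' which case the fluidity `beta` of each fit is compared.
#'
#' @param fits_a,fits_b Numeric vectors, or lists of [fit_creep_powerlaw()]
#'   results.
#' @param paired Logical; paired test requires equal lengths in matched
#'   order.
#' @param alpha_level Significance threshold reported (default 0.05).
#' @return List with `statistic` (t), `p_value`, `df`,
#'   `normality_p` (named, per group; `NA` with a warning for n < 3),
#'   `paired`, `alpha_level`, `significant`, and `note` (e.g. zero-variance
#'   degenerate case, where the t test is undefined).
#' @export
paired_group_compare <- function(fits_a, fits_b, paired = TRUE,
                                 alpha_level = 0.05) {
  a <- .as_beta_vector(fits_a)
  b <- .as_beta_vector(fits_b)
  if (paired && length(a) != length(b)) {
    stop("paired comparison requires equal-length, matched groups",
         call. = FALSE)
  }
  shap <- function(x, label) {
    if (length(x) < 3L) {
      warning(sprintf("group %s has n < 3; normality test skipped", label),
              call. = FALSE)
      return(NA_real_)
    }
    if (var(x) == 0) return(NA_real_)
    shapiro.test(x)$p.value
  }
  norm_p <- c(a = shap(a, "a"), b = shap(b, "b"))
  note <- NULL
  tt <- try(t.test(a, b, paired = paired, var.equal = FALSE,
                   alternative = "two.sided"), silent = TRUE)
  if (inherits(tt, "try-error")) {
    # zero-variance degenerate data: t statistic undefined
    note <- "degenerate (zero-variance) data; t test undefined"
    stat <- NA_real_; p <- NA_real_; df <- NA_real_
  } else {
    stat <- unname(tt$statistic); p <- tt$p.value
    df <- unname(tt$parameter)
    if (!is.finite(p)) {
      note <- "degenerate (zero-variance) data; t test undefined"
      stat <- NA_real_; p <- NA_real_
    }
  }
  list(statistic = stat, p_value = p, df = df, normality_p = norm_p,
       paired = paired, alpha_level = alpha_level,
       significant = isTRUE(p < alpha_level), note = note)
}

#' @rdname paired_group_compare
#' @param values_a,values_b Numeric vectors of per-sample metric values.
#' @export
two_group_test <- function(values_a, values_b, paired = FALSE,
                           alpha_level = 0.05) {
  paired_group_compare(values_a, values_b, paired = paired,
                       alpha_level = alpha_level)
}

.as_beta_vector <- function(x) {
  if (is.numeric(x)) return(as.numeric(x))
  if (is.list(x)) {
    v <- vapply(x, function(el) {
      if (inherits(el, "rheology_fit")) return(el$beta)
      if (is.numeric(el) && length(el) == 1L) return(el)
      stop("list elements must be rheology_fit objects or scalars",
           call. = FALSE)
    }, numeric(1L))
    return(v)
  }
  stop("expected a numeric vector or a list of fits", call. = FALSE)
}
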