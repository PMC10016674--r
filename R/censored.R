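## Censored allele frequencies.
##
## Public frequency databases report very rare alleles only as a bound
## ("<0.001"). A censored frequency is stored as a pair (value, censored):
## when `censored` is TRUE the true frequency is known only to lie in
## [0, value). All comparisons and summaries in the package respect the
## censoring rather than imputing a point value.

#' Parse censored frequency strings
#'
#' Converts annotation strings such as `"0.005"` or `"<0.001"` into a
#' (value, censored) pair. Empty strings, `"."`, `"NA"` and `NA` are treated
#' as absent annotations.
#'
#' @param x Character vector.
#' @return A tibble with columns `value` (double) and `censored` (logical);
#'   absent entries have `value = NA` and `censored = NA`.
#' @examples
#' parse_censored(c("<0.001", "0.005", "."))
#' @export
parse_censored <- function(x) {
  x <- as.character(x)
  x[x %in% c("", ".", "NA")] <- NA_character_
  censored <- !is.na(x) & startsWith(x, "<")
  raw <- ifelse(censored, substring(x, 2L), x)
  value <- suppressWarnings(as.numeric(raw))
  bad <- !is.na(x) & is.na(value)
  if (any(bad)) {
    cs_abort(
      paste0("Unparseable frequency string(s): ",
             paste(unique(x[bad]), collapse = ", ")),
      "cosegscan_format_error"
    )
  }
  if (any(value < 0 | value > 1, na.rm = TRUE)) {
    cs_abort("Frequencies must lie in [0, 1].", "cosegscan_format_error")
  }
  censored[is.na(value)] <- NA
  tibble(value = value, censored = censored)
}

#' Format censored frequencies back to strings
#'
#' Inverse of [parse_censored()]: censored values render as `"<value"`,
#' absent values as `"."`.
#'
#' @param value Numeric vector.
#' @param censored Logical vector.
#' @return Character vector.
#' @export
format_censored <- function(value, censored) {
  fmt1 <- function(v) format(v, trim = TRUE, scientific = FALSE, digits = 15)
  out <- vapply(seq_along(value), function(i) {
    if (is.na(value[i])) return(".")
    if (isTRUE_v(censored[i])) paste0("<", fmt1(value[i])) else fmt1(value[i])
  }, character(1))
  out
}

isTRUE_v <- function(x) !is.na(x) & x

#' Compare censored frequencies against a threshold
#'
#' For an uncensored value `v` the comparison is the ordinary `v < threshold`.
#' For a censored value (true frequency anywhere in `[0, v)`) the comparison
#' is decidable only when `v <= threshold`, in which case it is `TRUE`; when
#' `v > threshold` the answer depends on the unknown true frequency and the
#' function raises an error rather than guessing.
#'
#' @param value,censored Parallel numeric/logical vectors.
#' @param threshold Single numeric threshold.
#' @param label Optional character vector naming each entry (used in the
#'   indeterminate-comparison error).
#' @return Logical vector; `NA` where the annotation is absent.
#' @export
censored_lt <- function(value, censored, threshold, label = NULL) {
  stopifnot(is.numeric(threshold), length(threshold) == 1L)
  censored <- isTRUE_v(censored)
  indeterminate <- censored & !is.na(value) & value > threshold
  if (any(indeterminate)) {
    who <- if (!is.null(label)) paste(label[indeterminate], collapse = ", ")
           else paste(which(indeterminate), collapse = ", ")
    cs_abort(
      paste0("Indeterminate censored comparison against threshold ", threshold,
             " for: ", who,
             " (bound exceeds the threshold; the true frequency is unknown)."),
      "cosegscan_censored_error"
    )
  }
  ifelse(censored, TRUE, value < threshold)
}

## Resolve a censored vector at its two extremes. Lower: censored values at 0;
## upper: censored values just below their bound. The median / quantiles of the
## data are monotone in every coordinate, so a summary that agrees at both
## extremes is exact for every admissible resolution.
censored_extremes <- function(value, censored) {
  censored <- isTRUE_v(censored)
  eps <- 1e-12
  list(
    lo = ifelse(censored, 0, value),
    hi = ifelse(censored, pmax(value - eps, 0), value)
  )
}

#' Censoring-aware median
#'
#' Median of a set of possibly censored frequencies. Censored entries are
#' positioned below their bound and below every uncensored value at or above
#' the bound. The median is computed under the two extreme resolutions of the
#' censored entries (all at zero; all just below their bound): if both agree
#' on an uncensored value it is returned uncensored; if the median position is
#' occupied by a censored entry, the result is returned censored at that
#' entry's bound (the median is then guaranteed to lie strictly below it);
#' any other configuration is ambiguous and raises an error.
#'
#' @param value Numeric vector of frequencies (bounds for censored entries).
#' @param censored Logical vector.
#' @return One-row tibble with columns `value` and `censored`.
#' @examples
#' # median of <0.001, <0.001, 0.002, 0.003, 0.004 is 0.002, uncensored
#' censored_median(c(0.001, 0.001, 0.002, 0.003, 0.004),
#'                 c(TRUE, TRUE, FALSE, FALSE, FALSE))
#' @export
censored_median <- function(value, censored) {
  keep <- !is.na(value)
  value <- value[keep]
  censored <- isTRUE_v(censored[keep])
  n <- length(value)
  if (n == 0L) cs_abort("No values to take a median of.", "cosegscan_input_error")
  if (n %% 2L == 1L) {
    pos <- (n + 1L) / 2L
    res <- censored_order_stat(value, censored, pos)
    if (is.null(res)) {
      cs_abort("Censoring makes the median position ambiguous.",
               "cosegscan_censored_error")
    }
    return(tibble(value = res$value, censored = res$censored))
  }
  lo <- censored_order_stat(value, censored, n %/% 2L)
  hi <- censored_order_stat(value, censored, n %/% 2L + 1L)
  if (is.null(lo) || is.null(hi)) {
    cs_abort("Censoring makes the median position ambiguous.",
             "cosegscan_censored_error")
  }
  if (!lo$censored && !hi$censored) {
    return(tibble(value = (lo$value + hi$value) / 2, censored = FALSE))
  }
  ## at least one censored middle element: the mean is bounded above by the
  ## mean of the two bounds, so report a censored result at that bound
  tibble(value = (lo$value + hi$value) / 2, censored = TRUE)
}

## k-th order statistic of a censored sample, or NULL when ambiguous.
## Returns list(value=, censored=).
censored_order_stat <- function(value, censored, k) {
  ext <- censored_extremes(value, censored)
  ## order under each extreme; censored entries tie-break below uncensored
  stat_lo <- sort(ext$lo, partial = k)[k]
  stat_hi <- sort(ext$hi, partial = k)[k]
  ## which element occupies position k under the upper extreme?
  ord_hi <- order(ext$hi, censored, method = "radix")
  elem_hi <- ord_hi[k]
  if (censored[elem_hi]) {
    ## the k-th order statistic is <= stat_hi < bound under every resolution,
    ## so "censored at this element's bound" is always a correct statement
    return(list(value = value[elem_hi], censored = TRUE))
  }
  if (identical(stat_lo, stat_hi)) {
    return(list(value = stat_hi, censored = FALSE))
  }
  NULL
}

#' Censoring-aware interquartile range
#'
#' Quartiles are computed by linear interpolation (the default quantile rule)
#' under both extreme resolutions of the censored entries. When the two
#' extremes agree the IQR is exact; otherwise the largest admissible IQR is
#' reported and flagged as an upper bound.
#'
#' @inheritParams censored_median
#' @return One-row tibble with columns `iqr` and `is_bound`.
#' @export
censored_iqr <- function(value, censored) {
  keep <- !is.na(value)
  value <- value[keep]
  censored <- isTRUE_v(censored[keep])
  if (length(value) == 0L) {
    cs_abort("No values to take an IQR of.", "cosegscan_input_error")
  }
  ext <- censored_extremes(value, censored)
  q <- function(x, p) unname(quantile(x, p, type = 7))
  iqr_max <- q(ext$hi, 0.75) - q(ext$lo, 0.25)
  iqr_min <- max(0, q(ext$lo, 0.75) - q(ext$hi, 0.25))
  exact <- isTRUE(all.equal(iqr_min, iqr_max))
  if (!exact) {
    cs_inform("IQR is censoring-dependent; reporting the upper bound.")
  }
  tibble(iqr = iqr_max, is_bound = !exact)
}
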