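`%||%` <- function(a, b) if (is.null(a)) b else a

#' Round half away from zero
#'
#' Decimal rounding with the "school" convention (0.5 rounds up in absolute
#' value), as used when formatting descriptive percentages.  Base R's
#' [round()] uses banker's rounding, which gives different results on exact
#' halves.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return numeric vector of the same length as `x`.
#' @examples
#' round_half_up(30.205, 2)  # 30.21
#' round(30.205, 2)          # 30.2 under IEC 60559
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + sqrt(.Machine$double.eps)) / p
}

#' Format a count as a percentage string
#'
#' Computes `100 * count / denom`, rounds half-up to two decimals and appends
#' a percent sign, matching the formatting of descriptive report tables
#' (e.g. 58 of 192 -> "30.21%").
#'
#' @param count integer vector of stratum counts.
#' @param denom denominator (scalar or vector recycled against `count`).
#' @return character vector; `NA` where `denom` is zero.
#' @examples
#' format_percent(58, 192)
#' @export
format_percent <- function(count, denom) {
  out <- rep(NA_character_, length(count))
  denom <- rep_len(denom, length(count))
  ok <- !is.na(denom) & denom > 0
  out[ok] <- sprintf("%.2f%%", round_half_up(100 * count[ok] / denom[ok], 2))
  out
}

# "2020Q2"-style quarter label from an IDate; NA-safe
quarter_label <- function(date) {
  ifelse(is.na(date), NA_character_,
         sprintf("%dQ%d", data.table::year(date),
                 (data.table::month(date) - 1L) %/% 3L + 1L))
}

# integer index of a "YYYYQn" label for window comparisons
quarter_index <- function(q) {
  ok <- grepl("^\\d{4}Q[1-4]$", q)
  idx <- rep(NA_integer_, length(q))
  idx[ok] <- as.integer(substr(q[ok], 1, 4)) * 4L +
    as.integer(substr(q[ok], 6, 6)) - 1L
  idx
}

pv_log <- function(fmt, ...) {
  if (isTRUE(getOption("pvdili.verbose", FALSE))) {
    message(sprintf(fmt, ...))
  }
  invisible(NULL)
}
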