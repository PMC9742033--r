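# Disproportionality statistics on the 2x2 report-count table:
#
#                      event of interest   other events
#   with the drug              a                b
#   without the drug           c                d
#
# ROR  = (a/c)/(b/d) = ad/bc,      95% CI = exp(ln ROR -/+ 1.96 s)
# PRR  = (a/(a+b)) / (c/(c+d)),    chi2 = Pearson, no continuity correction
# IC   = log2( a N / ((a+b)(a+c)) )
# EBGM = a N / ((a+b)(a+c))        (the relative reporting ratio; no
#                                   empirical-Bayes shrinkage is applied)
# with s = sqrt(1/a + 1/b + 1/c + 1/d).
#
# The IC025/EBGM05 bounds implemented as primary are the *multiplicative*
# form exp(ln X - z s) applied to the point estimate (z = 1.96 for IC, 1.64
# for EBGM).  This is not the conventional BCPNN/MGPS credibility bound; the
# conventional additive IC bound is available via method = "additive".

#' Construct a 2x2 contingency table of report counts
#'
#' @param a reports with both the drug and the event of interest.
#' @param b reports with the drug and other events only.
#' @param c reports without the drug carrying the event.
#' @param d reports with neither.
#' @return object of class `contingency_table` with fields `a`,`b`,`c`,`d`,`n`.
#' @export
contingency_table <- function(a, b, c, d) {
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(is.na(cells)) || any(cells < 0) ||
      any(abs(cells - round(cells)) > 1e-8)) {
    stop("contingency_table: cells must be non-negative integers", call. = FALSE)
  }
  structure(list(a = as.numeric(a), b = as.numeric(b), c = as.numeric(c),
                 d = as.numeric(d), n = as.numeric(a + b + c + d)),
            class = "contingency_table")
}

#' @export
print.contingency_table <- function(x, ...) {
  cat("<contingency_table> a =", x$a, " b =", x$b, " c =", x$c, " d =", x$d,
      " N =", x$n, "\n")
  invisible(x)
}

# zero-cell handling: strict refuses, haldane adds 0.5 to every cell
apply_zero_policy <- function(t, zero_cell = c("strict", "haldane")) {
  zero_cell <- match.arg(zero_cell)
  cells <- c(t$a, t$b, t$c, t$d)
  if (any(cells == 0)) {
    if (zero_cell == "strict") {
      stop("contingency table has a zero cell: statistic undefined under ",
           "zero_cell = 'strict' (use 'haldane' for the +0.5 correction)",
           call. = FALSE)
    }
    cells <- cells + 0.5
  }
  list(a = cells[1], b = cells[2], c = cells[3], d = cells[4],
       n = sum(cells))
}

se_log_or <- function(cl) sqrt(1 / cl$a + 1 / cl$b + 1 / cl$c + 1 / cl$d)

#' Multiplicative lower/upper bound on a ratio statistic
#'
#' `exp(log(x) - z * s)` — the bound form used for the ROR confidence
#' interval and (applied to the IC and EBGM point estimates) for the IC025
#' and EBGM05 bounds.
#'
#' @param x positive point estimate.
#' @param s standard error of the log reporting odds ratio,
#'   `sqrt(1/a + 1/b + 1/c + 1/d)`.
#' @param z normal quantile (1.96 two-sided 95%, 1.64 one-sided 90%/95%).
#' @return numeric bound; `NA` when `x <= 0`.
#' @export
mult_lower_bound <- function(x, s, z = 1.96) {
  ifelse(is.na(x) | x <= 0, NA_real_, exp(log(x) - z * s))
}

#' Reporting odds ratio with 95% confidence interval
#'
#' @param t a [contingency_table()].
#' @param zero_cell `"strict"` (zero cell is an error) or `"haldane"`
#'   (add 0.5 to every cell).
#' @param conf_level two-sided confidence level, default 0.95.
#' @return list with `ror`, `ci_low`, `ci_high`, `se_log`.
#' @examples
#' ror_with_ci(contingency_table(20, 10, 10, 20))
#' @export
ror_with_ci <- function(t, zero_cell = "strict", conf_level = 0.95) {
  cl <- apply_zero_policy(t, zero_cell)
  # the conventional printed constant (1.96) is used at the default level so
  # results match the formula as published
  z <- if (identical(conf_level, 0.95)) 1.96 else {
    stats::qnorm(1 - (1 - conf_level) / 2)
  }
  ror <- (cl$a * cl$d) / (cl$b * cl$c)
  s <- se_log_or(cl)
  list(ror = ror,
       ci_low = exp(log(ror) - z * s),
       ci_high = exp(log(ror) + z * s),
       se_log = s)
}

#' Proportional reporting ratio with Pearson chi-squared
#'
#' The chi-squared statistic is Pearson's `N (ad - bc)^2 /
#' ((a+b)(c+d)(a+c)(b+d))` without continuity correction by default.
#'
#' @inheritParams ror_with_ci
#' @param correct apply the Yates continuity correction.
#' @return list with `prr`, `chi2`.
#' @export
prr_with_chi2 <- function(t, zero_cell = "strict", correct = FALSE) {
  cl <- apply_zero_policy(t, zero_cell)
  prr <- (cl$a / (cl$a + cl$b)) / (cl$c / (cl$c + cl$d))
  dev <- abs(cl$a * cl$d - cl$b * cl$c)
  if (correct) dev <- max(0, dev - cl$n / 2)
  chi2 <- cl$n * dev^2 /
    ((cl$a + cl$b) * (cl$c + cl$d) * (cl$a + cl$c) * (cl$b + cl$d))
  list(prr = prr, chi2 = chi2)
}

#' Information component with lower bound
#'
#' `IC = log2(a N / ((a+b)(a+c)))`, the log2 observed/expected reporting
#' ratio.  The primary `IC025` is the multiplicative bound
#' `exp(ln(IC) - 1.96 s)` applied to the IC point estimate, which requires
#' `IC > 0`; otherwise the bound is `NA` with a warning.  `method =
#' "additive"` gives the conventional normal-approximation bound on the IC
#' scale, `IC - 1.96 s / ln 2`, defined for any IC.
#'
#' @inheritParams ror_with_ci
#' @param method `"multiplicative"` (primary) or `"additive"` (conventional).
#' @return list with `ic`, `ic025`, `se_log`, `method`.
#' @export
ic_with_bound <- function(t, zero_cell = "strict",
                          method = c("multiplicative", "additive")) {
  method <- match.arg(method)
  cl <- apply_zero_policy(t, zero_cell)
  rrr <- cl$a * cl$n / ((cl$a + cl$b) * (cl$a + cl$c))
  ic <- log2(rrr)
  s <- se_log_or(cl)
  ic025 <- if (method == "multiplicative") {
    if (ic <= 0) {
      warning("IC <= 0: multiplicative IC025 undefined (log of non-positive)",
              call. = FALSE)
      NA_real_
    } else {
      mult_lower_bound(ic, s, 1.96)
    }
  } else {
    ic - 1.96 * s / log(2)
  }
  list(ic = ic, ic025 = ic025, se_log = s, method = method)
}

#' EBGM (relative reporting ratio) with one-sided lower bound
#'
#' `EBGM = a N / ((a+b)(a+c))` — the unshrunk observed/expected reporting
#' ratio (note this is *not* the MGPS gamma-mixture shrinkage estimator; no
#' empirical-Bayes fitting is performed).  `EBGM05 = exp(ln(EBGM) - 1.64 s)`,
#' the lower one-sided 90% bound.
#'
#' @inheritParams ror_with_ci
#' @return list with `ebgm`, `ebgm05`, `se_log`.
#' @export
ebgm_with_bound <- function(t, zero_cell = "strict") {
  cl <- apply_zero_policy(t, zero_cell)
  ebgm <- cl$a * cl$n / ((cl$a + cl$b) * (cl$a + cl$c))
  s <- se_log_or(cl)
  list(ebgm = ebgm, ebgm05 = mult_lower_bound(ebgm, s, 1.64), se_log = s)
}

#' Signal criteria flags
#'
#' Applies the standard per-algorithm signal criteria:
#' ROR: CI lower bound > 1 and n >= 2;
#' PRR: PRR >= 2, chi2 >= 4 and n >= 3;
#' IC:  IC025 > 0;
#' EBGM: EBGM05 > 2 and n > 0;
#' where n is the co-occurrence count `a`.
#'
#' @param stats a `signal_statistics` object (or compatible list with fields
#'   `ror_ci_low`, `prr`, `chi2`, `ic025`, `ebgm05`, `n_events`).
#' @return named logical list: `ror_signal`, `prr_signal`, `ic_signal`,
#'   `ebgm_signal`.
#' @export
signal_flags <- function(stats) {
  list(
    ror_signal  = isTRUE(stats$ror_ci_low > 1 && stats$n_events >= 2),
    prr_signal  = isTRUE(stats$prr >= 2 && stats$chi2 >= 4 && stats$n_events >= 3),
    ic_signal   = isTRUE(!is.na(stats$ic025) && stats$ic025 > 0),
    ebgm_signal = isTRUE(stats$ebgm05 > 2 && stats$n_events > 0)
  )
}

#' All disproportionality statistics for one table
#'
#' @inheritParams ror_with_ci
#' @param ic_method passed to [ic_with_bound()].
#' @return object of class `signal_statistics`: a list with the four
#'   statistics, their bounds, `se_log`, `n_events` (= a) and the signal
#'   flags of [signal_flags()].
#' @export
signal_stats <- function(t, zero_cell = "strict",
                         ic_method = "multiplicative") {
  stopifnot(inherits(t, "contingency_table"))
  ror <- ror_with_ci(t, zero_cell)
  prr <- prr_with_chi2(t, zero_cell)
  ic <- suppressWarnings(ic_with_bound(t, zero_cell, ic_method))
  eb <- ebgm_with_bound(t, zero_cell)
  out <- list(a = t$a, b = t$b, c = t$c, d = t$d, n = t$n,
              n_events = t$a,
              ror = ror$ror, ror_ci_low = ror$ci_low,
              ror_ci_high = ror$ci_high, se_log = ror$se_log,
              prr = prr$prr, chi2 = prr$chi2,
              ic = ic$ic, ic025 = ic$ic025,
              ebgm = eb$ebgm, ebgm05 = eb$ebgm05)
  out <- c(out, signal_flags(out))
  structure(out, class = "signal_statistics")
}

#' @export
print.signal_statistics <- function(x, ...) {
  star <- function(flag) if (isTRUE(flag)) "*" else ""
  cat(sprintf(
    paste0("<signal_statistics> a=%g N=%g\n",
           "  ROR  %.2f (%.2f, %.2f)%s\n",
           "  PRR  %.2f (chi2 %.2f)%s\n",
           "  IC   %.2f (IC025 %s)%s\n",
           "  EBGM %.2f (EBGM05 %.2f)%s\n"),
    x$a, x$n,
    x$ror, x$ror_ci_low, x$ror_ci_high, star(x$ror_signal),
    x$prr, x$chi2, star(x$prr_signal),
    x$ic, if (is.na(x$ic025)) "NA" else sprintf("%.2f", x$ic025),
    star(x$ic_signal),
    x$ebgm, x$ebgm05, star(x$ebgm_signal)))
  invisible(x)
}

#' Build the contingency table of a drug against the DILI definition
#'
#' Counts deduplicated reports of the cohort: `a` = exposed with event, `b` =
#' exposed without, `c` = unexposed with event, `d` = neither.  Each report
#' contributes to exactly one cell.  The comparator universe is the COVID-19
#' cohort itself (every report retained by [build_cohort()], exposed or not).
#'
#' @param cohort a `study_cohort`.
#' @param drug canonical drug name (must be in the cohort dictionary).
#' @return a [contingency_table()].
#' @export
build_contingency <- function(cohort, drug) {
  stopifnot(inherits(cohort, "study_cohort"))
  if (!drug %in% names(cohort$dictionary)) {
    stop("drug not in dictionary: ", drug, call. = FALSE)
  }
  drug_name <- drug
  exposed_ids <- unique(cohort$exposure[drug == drug_name, primaryid])
  rep_dt <- cohort$reports
  exposed <- rep_dt$primaryid %in% exposed_ids
  event <- rep_dt$has_dili
  contingency_table(a = sum(exposed & event),
                    b = sum(exposed & !event),
                    c = sum(!exposed & event),
                    d = sum(!exposed & !event))
}

#' Signal table for several drugs
#'
#' One row per drug with cells, all four statistics, bounds and flags —
#' the layout of a signal-summary table.
#'
#' @inheritParams build_contingency
#' @param drugs canonical names; defaults to all dictionary entries.
#' @param zero_cell,ic_method passed to [signal_stats()].
#' @return `data.table`, one row per drug.
#' @export
signal_table <- function(cohort, drugs = NULL, zero_cell = "strict",
                         ic_method = "multiplicative") {
  drugs <- drugs %||% names(cohort$dictionary)
  rows <- lapply(drugs, function(d) {
    t <- build_contingency(cohort, d)
    # degenerate tables (zero cell under the strict policy) are reported as
    # NA statistics rather than aborting the whole table
    s <- tryCatch(
      signal_stats(t, zero_cell = zero_cell, ic_method = ic_method),
      error = function(e) {
        list(a = t$a, b = t$b, c = t$c, d = t$d, n = t$n, n_events = t$a,
             ror = NA_real_, ror_ci_low = NA_real_, ror_ci_high = NA_real_,
             se_log = NA_real_, prr = NA_real_, chi2 = NA_real_,
             ic = NA_real_, ic025 = NA_real_, ebgm = NA_real_,
             ebgm05 = NA_real_, ror_signal = FALSE, prr_signal = FALSE,
             ic_signal = FALSE, ebgm_signal = FALSE)
      })
    data.table::data.table(
      drug = d, a = s$a, b = s$b, c = s$c, d_cell = s$d, n_total = s$n,
      ror = s$ror, ror_ci_low = s$ror_ci_low, ror_ci_high = s$ror_ci_high,
      prr = s$prr, chi2 = s$chi2, ic = s$ic, ic025 = s$ic025,
      ebgm = s$ebgm, ebgm05 = s$ebgm05, se_log = s$se_log,
      ror_signal = s$ror_signal, prr_signal = s$prr_signal,
      ic_signal = s$ic_signal, ebgm_signal = s$ebgm_signal)
  })
  data.table::rbindlist(rows)[]
}
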