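# Time-to-onset, outcome profiles, fatality and between-group comparisons.

#' Time interval between suspect-drug start and event onset
#'
#' One report's onset interval in days: event date minus the earliest suspect
#' start date.  The report is excluded (with a recorded reason) when either
#' date is absent, when the relevant date has precision coarser than a day
#' (partial dates are never imputed), or when the interval is negative (an
#' erroneous entry).
#'
#' @param event_date `Date`/`IDate` (or `NA`).
#' @param event_precision `"day"`, `"month"`, `"year"` or `"absent"`.
#' @param start_dates vector of candidate start dates.
#' @param start_precisions their precision flags.
#' @return list with `interval_days` (integer or `NA`) and `reason` (`"ok"`
#'   or the exclusion reason: `no_event_date`, `event_date_partial`,
#'   `no_start_date`, `start_date_partial`, `negative_interval`).
#' @export
onset_interval <- function(event_date, event_precision,
                           start_dates, start_precisions) {
  excl <- function(reason) list(interval_days = NA_integer_, reason = reason)
  if (is.na(event_date) || identical(event_precision, "absent")) {
    return(excl("no_event_date"))
  }
  if (!identical(event_precision, "day")) return(excl("event_date_partial"))
  present <- !is.na(start_dates)
  if (!any(present)) return(excl("no_start_date"))
  day_ok <- present & start_precisions == "day"
  if (!any(day_ok)) return(excl("start_date_partial"))
  start <- min(start_dates[day_ok])
  interval <- as.integer(as.Date(event_date) - as.Date(start))
  if (interval < 0) return(excl("negative_interval"))
  list(interval_days = interval, reason = "ok")
}

#' Onset intervals of a drug's DILI cases
#'
#' For every case report of `drug` (exposed, with a DILI event), computes the
#' onset interval from the therapy start dates of the matching drug entries
#' (`THER` rows joined on the matched `drug_seq`).  Exclusions are counted by
#' reason; included plus excluded always equals the number of candidate
#' reports.
#'
#' @param cohort a `study_cohort`.
#' @param drug canonical drug name.
#' @return list of class `onset_records`: `records` (data.table `primaryid`,
#'   `drug`, `interval_days`), `exclusions` (named counts), `n_candidates`.
#' @export
compute_onset <- function(cohort, drug) {
  stopifnot(inherits(cohort, "study_cohort"))
  drug_name <- drug
  ids <- case_ids(cohort, drug_name)
  expo <- cohort$exposure[drug == drug_name & primaryid %in% ids]
  ther <- cohort$ther
  demo <- cohort$reports[primaryid %in% ids]

  st <- parse_partial_date(ther$start_dt, warn = FALSE)
  ther2 <- data.table::data.table(primaryid = ther$primaryid,
                                  dsg_drug_seq = ther$dsg_drug_seq,
                                  start_date = st$date,
                                  start_precision = st$precision)
  # therapy rows of the matched suspect-drug entries
  ther2 <- ther2[expo, on = c(primaryid = "primaryid",
                              dsg_drug_seq = "drug_seq"), nomatch = NULL]

  reasons <- c("no_event_date", "event_date_partial", "no_start_date",
               "start_date_partial", "negative_interval")
  excl <- stats::setNames(integer(length(reasons)), reasons)
  rows <- vector("list", nrow(demo))
  for (i in seq_len(nrow(demo))) {
    pid <- demo$primaryid[i]
    starts <- ther2[primaryid == pid]
    res <- onset_interval(demo$event_date[i], demo$event_precision[i],
                          starts$start_date, starts$start_precision)
    if (res$reason == "ok") {
      rows[[i]] <- data.table::data.table(primaryid = pid, drug = drug_name,
                                          interval_days = res$interval_days)
    } else {
      excl[res$reason] <- excl[res$reason] + 1L
    }
  }
  records <- data.table::rbindlist(rows[!vapply(rows, is.null, TRUE)])
  if (nrow(records) == 0) {
    records <- data.table::data.table(primaryid = character(0),
                                      drug = character(0),
                                      interval_days = integer(0))
  }
  structure(list(records = records, exclusions = excl,
                 n_candidates = nrow(demo)),
            class = "onset_records")
}

#' Summarise onset intervals
#'
#' Median (midpoint convention for even n), interquartile range (type-7
#' quantiles), min--max range and a per-day histogram.
#'
#' @param x integer vector of onset intervals in days (>= 0), or an
#'   `onset_records` object.
#' @return list with `n`, `median`, `q1`, `q3`, `min`, `max`, `histogram`
#'   (named integer vector, one bin per observed day).
#' @export
summarize_onset <- function(x) {
  if (inherits(x, "onset_records")) x <- x$records$interval_days
  x <- as.numeric(x)
  if (length(x) == 0 || any(is.na(x))) {
    stop("summarize_onset: need at least one non-missing interval", call. = FALSE)
  }
  q <- stats::quantile(x, c(0.25, 0.75), names = FALSE)
  h <- table(factor(x, levels = seq(min(x), max(x))))
  list(n = length(x), median = stats::median(x), q1 = q[1], q3 = q[2],
       min = min(x), max = max(x),
       histogram = stats::setNames(as.integer(h), names(h)))
}

#' Share of onsets within a horizon
#'
#' Proportion of records with `interval_days <= horizon_days`.
#'
#' @inheritParams summarize_onset
#' @param horizon_days non-negative horizon in days.
#' @return proportion in `[0, 1]`.
#' @examples
#' cumulative_share(c(0, 1, 5, 9), 4)  # 0.5
#' @export
cumulative_share <- function(x, horizon_days) {
  if (inherits(x, "onset_records")) x <- x$records$interval_days
  stopifnot(length(x) >= 1, horizon_days >= 0)
  mean(x <= horizon_days)
}

#' Two-sample t-test on onset intervals
#'
#' Two-tailed Student's t-test comparing two groups (pooled variance by
#' default; `var_equal = FALSE` gives Welch).
#'
#' @param group_a,group_b numeric vectors, each with n >= 2.
#' @param var_equal pooled (default) vs Welch variance.
#' @return list with `statistic` (t), `p_value`, `df`, `method`.
#' @export
compare_onset <- function(group_a, group_b, var_equal = TRUE) {
  stopifnot(length(group_a) >= 2, length(group_b) >= 2)
  if (stats::var(group_a) == 0 && stats::var(group_b) == 0 &&
      mean(group_a) == mean(group_b)) {
    # degenerate equal groups: no evidence of difference
    return(list(statistic = 0, p_value = 1,
                df = length(group_a) + length(group_b) - 2,
                method = if (var_equal) "pooled" else "welch"))
  }
  ht <- stats::t.test(group_a, group_b, var.equal = var_equal,
                      alternative = "two.sided")
  list(statistic = unname(ht$statistic), p_value = ht$p.value,
       df = unname(ht$parameter),
       method = if (var_equal) "pooled" else "welch")
}

#' Kruskal--Wallis rank test across three or more groups
#'
#' Rank-based H statistic with tie correction and chi-squared reference
#' distribution.  All-identical values give H = 0, p = 1.
#'
#' @param groups list of >= 3 numeric vectors, each non-empty.
#' @return list with `statistic` (H), `p_value`, `df`.
#' @export
kruskal_wallis <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 3,
            all(vapply(groups, length, 1L) >= 1))
  values <- unlist(groups, use.names = FALSE)
  if (length(unique(values)) == 1) {
    return(list(statistic = 0, p_value = 1, df = length(groups) - 1))
  }
  g <- factor(rep(seq_along(groups), vapply(groups, length, 1L)))
  ht <- stats::kruskal.test(values, g)
  list(statistic = unname(ht$statistic), p_value = ht$p.value,
       df = unname(ht$parameter))
}

#' Outcome profile of a drug's DILI cases
#'
#' Counts and proportions per outcome code; the fatality rate is the `DE`
#' (death) proportion.  By default the denominator is the number of case
#' reports carrying at least one outcome code (outcome codes are not a
#' partition: one report may carry several).
#'
#' @inheritParams compute_onset
#' @param denominator `"outcome_reports"` (default) or `"case_reports"`.
#' @return list of class `outcome_profile`: `counts` (named integer vector
#'   over the seven codes), `proportions`, `denominator`, `fatality_rate`,
#'   `n_cases`.
#' @export
outcome_profile <- function(cohort, drug,
                            denominator = c("outcome_reports", "case_reports")) {
  stopifnot(inherits(cohort, "study_cohort"))
  denominator <- match.arg(denominator)
  ids <- case_ids(cohort, drug)
  outc <- unique(cohort$outc[primaryid %in% ids, .(primaryid, outc_cod)])
  codes <- names(outcome_labels())
  counts <- vapply(codes, function(code) {
    length(unique(outc[outc_cod == code, primaryid]))
  }, integer(1))
  denom <- switch(denominator,
                  outcome_reports = length(unique(outc$primaryid)),
                  case_reports = length(ids))
  props <- if (denom > 0) counts / denom else stats::setNames(
    rep(NA_real_, length(codes)), codes)
  structure(list(counts = counts, proportions = props, denominator = denom,
                 denominator_rule = denominator,
                 fatality_rate = unname(props["DE"]), n_cases = length(ids),
                 drug = drug),
            class = "outcome_profile")
}

#' @export
print.outcome_profile <- function(x, ...) {
  cat("<outcome_profile>", x$drug, "-", x$n_cases, "cases,",
      x$denominator, "with outcomes\n")
  for (code in names(x$counts)) {
    cat(sprintf("  %-2s %4d (%s)\n", code, x$counts[[code]],
                format_percent(x$counts[[code]], x$denominator)))
  }
  invisible(x)
}

#' Compare two proportions
#'
#' 2x2 Pearson chi-squared without continuity correction by default;
#' `method = "yates"` applies the correction, `method = "fisher"` uses
#' Fisher's exact test.
#'
#' @param events_a,total_a,events_b,total_b counts (totals > 0).
#' @return list with `statistic` (chi-squared, `NA` for Fisher), `p_value`,
#'   `method`.
#' @examples
#' compare_proportions(30, 175, 30, 82)
#' @export
compare_proportions <- function(events_a, total_a, events_b, total_b,
                                method = c("pearson", "yates", "fisher")) {
  method <- match.arg(method)
  if (total_a <= 0 || total_b <= 0) stop("totals must be > 0", call. = FALSE)
  stopifnot(events_a >= 0, events_b >= 0,
            events_a <= total_a, events_b <= total_b)
  m <- matrix(c(events_a, total_a - events_a,
                events_b, total_b - events_b), nrow = 2, byrow = TRUE)
  if (method == "fisher") {
    ht <- stats::fisher.test(m)
    return(list(statistic = NA_real_, p_value = ht$p.value, method = method))
  }
  if (events_a / total_a == events_b / total_b) {
    # identical proportions: chi2 exactly 0 (avoid chisq.test zero-margin warnings)
    return(list(statistic = 0, p_value = 1, method = method))
  }
  ht <- suppressWarnings(stats::chisq.test(m, correct = method == "yates"))
  list(statistic = unname(ht$statistic), p_value = ht$p.value, method = method)
}
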