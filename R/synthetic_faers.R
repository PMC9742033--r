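# Synthetic FAERS-like quarter generator with planted statistical structure.
#
# Generative law, per report (independent across reports):
#   * exposure to each target drug j is Bernoulli(p_j), independent;
#   * for an event set S with marginal probability p_S and planted
#     associations (drug j, theta_j):
#       odds(event | exposures x) = odds_base * prod_j theta_j^{x_j},
#     with odds_base solved so that the marginal P(event) equals p_S.
#     Hence for a single planted drug, odds(event | exposed) /
#     odds(event | unexposed) = theta exactly;
#   * onset intervals follow a geometric law on {0, 1, 2, ...} days and the
#     event date of an exposed report equals suspect start date + interval;
#   * duplicates are emitted as a second case version with the same caseid
#     and a later FDA date, exercising the deduplication rule;
#   * demographics are missing completely at random at configurable rates.
#
# expected_contingency() computes the exact expected 2x2 cells under this
# law by enumerating exposure combinations of the planted drugs, so
# empirical cell frequencies converge to it by construction.

#' Build a validated generator configuration
#'
#' Defaults emulate the study world this package targets: a COVID-19
#' spontaneous-reporting universe in 2020Q2--2021Q4 with two IL-6 receptor
#' antagonists carrying planted reporting odds ratios against the DILI
#' preferred-term set (1.33 for tocilizumab, 12.94 for sarilumab), ~40%
#' missing demographics, 10% duplicate case versions and geometric
#' time-to-onset with median 1 day.
#'
#' @param n_reports number of distinct cases to simulate.
#' @param drugs named list: canonical name -> `list(synonyms =, prob =)`;
#'   `prob` is the marginal exposure probability.
#' @param background_drugs verbatim names for comparator drug entries.
#' @param background_events data.frame with columns `pt`, `weight`: the
#'   reaction vocabulary outside the event sets (every report draws at least
#'   one background reaction).
#' @param event_sets named list: set name -> `list(pts =, prob =)` with
#'   `prob` the marginal probability that a report carries any PT of the set.
#' @param planted list of `list(drug =, event_set =, theta =)` planted
#'   associations (theta > 0 is the true reporting odds ratio).
#' @param covid_fraction probability a report carries a COVID-19 indication.
#' @param duplicate_rate probability a case emits an extra version.
#' @param missing_age_rate,missing_sex_rate,missing_country_rate,missing_occupation_rate
#'   missing-completely-at-random rates for demographics.
#' @param missing_event_date_rate,missing_start_date_rate probabilities that
#'   the event / therapy start date is absent.
#' @param partial_date_rate probability a present date is truncated to month
#'   or year precision.
#' @param outcome_presence_rate probability a report carries >= 1 outcome code.
#' @param outcome_profile probability vector over the outcome codes
#'   `DE, LT, HO, DS, CA, RI, OT`; must sum to 1.
#' @param onset_law `list(name = "geometric", p =)`: onset-interval law on
#'   days >= 0.
#' @param date_window `c(start, end)` calendar dates covering the report
#'   window.
#' @param seed integer seed (mandatory; identical seeds give byte-identical
#'   output files).
#' @return validated list of class `generator_config`.
#' @export
generator_config <- function(
    n_reports = 20000,
    drugs = list(
      tocilizumab = list(synonyms = c("TOCILIZUMAB", "ACTEMRA", "ATLIZUMAB",
                                      "ROACTEMRA"), prob = 0.12),
      sarilumab = list(synonyms = c("SARILUMAB", "KEVZARA"), prob = 0.015)),
    background_drugs = c("REMDESIVIR", "DEXAMETHASONE", "AZITHROMYCIN",
                         "ENOXAPARIN", "HYDROXYCHLOROQUINE"),
    background_events = data.frame(
      pt = c("Pyrexia", "Dyspnoea", "Headache", "Nausea", "Fatigue",
             "Acute respiratory failure", "Pneumonia", "Cough"),
      weight = c(2, 2, 1, 1, 1, 1, 2, 1)),
    event_sets = list(dili = list(pts = dili_terms(), prob = 0.03)),
    planted = list(
      list(drug = "tocilizumab", event_set = "dili", theta = 1.33),
      list(drug = "sarilumab", event_set = "dili", theta = 12.94)),
    covid_fraction = 0.9,
    duplicate_rate = 0.1,
    missing_age_rate = 0.4,
    missing_sex_rate = 0.4,
    missing_country_rate = 0.05,
    missing_occupation_rate = 0.35,
    missing_event_date_rate = 0.15,
    missing_start_date_rate = 0.1,
    partial_date_rate = 0.1,
    outcome_presence_rate = 0.9,
    outcome_profile = c(DE = 60, LT = 35, HO = 64, DS = 2, CA = 1,
                        RI = 2, OT = 191) / 355,
    onset_law = list(name = "geometric", p = 0.3),
    date_window = c("2020-04-01", "2021-12-31"),
    seed = 20200401L) {

  fail <- function(field, msg) {
    stop(sprintf("generator_config: invalid '%s': %s", field, msg),
         call. = FALSE)
  }
  if (!is.numeric(n_reports) || length(n_reports) != 1 || n_reports < 1) {
    fail("n_reports", "must be a positive integer")
  }
  n_reports <- as.integer(n_reports)
  if (!is.list(drugs) || is.null(names(drugs))) fail("drugs", "must be a named list")
  for (nm in names(drugs)) {
    d <- drugs[[nm]]
    if (is.null(d$synonyms) || !length(d$synonyms)) {
      fail("drugs", paste0(nm, ": empty synonym set"))
    }
    if (is.null(d$prob) || d$prob < 0 || d$prob > 1) {
      fail("drugs", paste0(nm, ": prob must be in [0,1]"))
    }
  }
  if (!all(c("pt", "weight") %in% names(background_events)) ||
      nrow(background_events) == 0) {
    fail("background_events", "needs columns pt, weight and >= 1 row")
  }
  for (nm in names(event_sets)) {
    s <- event_sets[[nm]]
    if (is.null(s$pts) || !length(s$pts)) fail("event_sets", paste0(nm, ": empty PT set"))
    if (is.null(s$prob) || s$prob <= 0 || s$prob >= 1) {
      fail("event_sets", paste0(nm, ": prob must be in (0,1)"))
    }
  }
  for (p in planted) {
    if (!p$drug %in% names(drugs)) fail("planted", paste0("unknown drug ", p$drug))
    if (!p$event_set %in% names(event_sets)) {
      fail("planted", paste0("unknown event_set ", p$event_set))
    }
    if (is.null(p$theta) || p$theta <= 0) fail("planted", "theta must be > 0")
  }
  rates <- c(covid_fraction = covid_fraction, duplicate_rate = duplicate_rate,
             missing_age_rate = missing_age_rate,
             missing_sex_rate = missing_sex_rate,
             missing_country_rate = missing_country_rate,
             missing_occupation_rate = missing_occupation_rate,
             missing_event_date_rate = missing_event_date_rate,
             missing_start_date_rate = missing_start_date_rate,
             partial_date_rate = partial_date_rate,
             outcome_presence_rate = outcome_presence_rate)
  for (nm in names(rates)) {
    if (is.na(rates[[nm]]) || rates[[nm]] < 0 || rates[[nm]] > 1) {
      fail(nm, "must be a probability in [0,1]")
    }
  }
  codes <- c("DE", "LT", "HO", "DS", "CA", "RI", "OT")
  if (!setequal(names(outcome_profile), codes)) {
    fail("outcome_profile", paste("must be named over", paste(codes, collapse = ",")))
  }
  if (abs(sum(outcome_profile) - 1) > 1e-9 || any(outcome_profile < 0)) {
    fail("outcome_profile", "must be non-negative and sum to 1 (within 1e-9)")
  }
  if (!identical(onset_law$name, "geometric") ||
      is.null(onset_law$p) || onset_law$p <= 0 || onset_law$p > 1) {
    fail("onset_law", "only list(name='geometric', p in (0,1]) is supported")
  }
  dw <- data.table::as.IDate(date_window)
  if (any(is.na(dw)) || dw[1] >= dw[2]) fail("date_window", "start must precede end")
  if (is.null(seed) || is.na(suppressWarnings(as.integer(seed)))) {
    fail("seed", "an integer seed is mandatory")
  }
  structure(list(
    n_reports = n_reports, drugs = drugs, background_drugs = background_drugs,
    background_events = background_events, event_sets = event_sets,
    planted = planted, covid_fraction = covid_fraction,
    duplicate_rate = duplicate_rate, missing_age_rate = missing_age_rate,
    missing_sex_rate = missing_sex_rate,
    missing_country_rate = missing_country_rate,
    missing_occupation_rate = missing_occupation_rate,
    missing_event_date_rate = missing_event_date_rate,
    missing_start_date_rate = missing_start_date_rate,
    partial_date_rate = partial_date_rate,
    outcome_presence_rate = outcome_presence_rate,
    outcome_profile = outcome_profile[codes], onset_law = onset_law,
    date_window = as.character(dw), seed = as.integer(seed)),
    class = "generator_config")
}

planted_for_set <- function(config, set_name) {
  Filter(function(p) identical(p$event_set, set_name), config$planted)
}

# base log-odds of an event set solved so the marginal probability matches
solve_base_logit <- function(config, set_name) {
  s <- config$event_sets[[set_name]]
  if (is.null(s)) stop("unknown event set: ", set_name, call. = FALSE)
  pl <- planted_for_set(config, set_name)
  if (length(pl) == 0) return(stats::qlogis(s$prob))
  probs <- vapply(pl, function(p) config$drugs[[p$drug]]$prob, numeric(1))
  lth <- log(vapply(pl, function(p) p$theta, numeric(1)))
  combos <- as.matrix(expand.grid(rep(list(0:1), length(pl))))
  w <- apply(combos, 1, function(v) prod(ifelse(v == 1, probs, 1 - probs)))
  shift <- as.numeric(combos %*% lth)
  f <- function(b) sum(w * stats::plogis(b + shift)) - s$prob
  stats::uniroot(f, c(-40, 40), tol = 1e-13)$root
}

#' Exact expected 2x2 cells under the generator's law
#'
#' Closed-form expectation of the (a, b, c, d) report counts for a
#' (drug, event set) pair, obtained by enumerating the exposure combinations
#' of all drugs planted on the set.  Cells sum to `n_reports`.
#'
#' @param config a [generator_config()].
#' @param drug canonical drug name in `config$drugs`.
#' @param event_set event-set name in `config$event_sets`.
#' @return named numeric vector `c(a, b, c, d)`.
#' @examples
#' cfg <- generator_config(n_reports = 1000,
#'   drugs = list(x = list(synonyms = "X", prob = 0.1)),
#'   event_sets = list(dili = list(pts = dili_terms(), prob = 0.2)),
#'   planted = list(), seed = 1)
#' expected_contingency(cfg, "x", "dili")  # independence: 20 80 180 720
#' @export
expected_contingency <- function(config, drug, event_set = "dili") {
  stopifnot(inherits(config, "generator_config"))
  if (!drug %in% names(config$drugs)) {
    stop("unknown drug in config: ", drug, call. = FALSE)
  }
  if (!event_set %in% names(config$event_sets)) {
    stop("unknown event set in config: ", event_set, call. = FALSE)
  }
  n <- config$n_reports
  p_d <- config$drugs[[drug]]$prob
  base <- solve_base_logit(config, event_set)
  pl <- planted_for_set(config, event_set)
  pl_drugs <- vapply(pl, `[[`, "", "drug")
  if (drug %in% pl_drugs) {
    probs <- vapply(pl, function(p) config$drugs[[p$drug]]$prob, numeric(1))
    lth <- log(vapply(pl, function(p) p$theta, numeric(1)))
    combos <- as.matrix(expand.grid(rep(list(0:1), length(pl))))
    w <- apply(combos, 1, function(v) prod(ifelse(v == 1, probs, 1 - probs)))
    pe <- stats::plogis(base + as.numeric(combos %*% lth))
    j <- match(drug, pl_drugs)
    a <- n * sum(w[combos[, j] == 1] * pe[combos[, j] == 1])
    c_ <- n * sum(w[combos[, j] == 0] * pe[combos[, j] == 0])
  } else {
    # drug independent of the set: product law
    p_set <- config$event_sets[[event_set]]$prob
    a <- n * p_d * p_set
    c_ <- n * (1 - p_d) * p_set
  }
  b <- n * p_d - a
  d <- n * (1 - p_d) - c_
  c(a = a, b = b, c = c_, d = d)
}

#' Draw a random 2x2 table under the generator's law
#'
#' Multinomial sample of the (a, b, c, d) report counts with cell
#' probabilities given by [expected_contingency()] — the marginal law of the
#' per-report simulation, useful for fast replicate studies (e.g. CI
#' coverage under a null theta = 1).
#'
#' @inheritParams expected_contingency
#' @param n number of reports (defaults to `config$n_reports`).
#' @return a [contingency_table()].
#' @export
sample_contingency <- function(config, drug, event_set = "dili",
                               n = config$n_reports) {
  probs <- expected_contingency(config, drug, event_set) / config$n_reports
  cells <- as.integer(stats::rmultinom(1, n, probs))
  contingency_table(cells[1], cells[2], cells[3], cells[4])
}

# truncate YYYYMMDD strings to month/year precision at `rate`
truncate_dates <- function(d8, rate) {
  n <- length(d8)
  u <- stats::runif(n)
  out <- d8
  out[u < rate / 2] <- substr(d8[u < rate / 2], 1, 6)
  sel <- u >= rate / 2 & u < rate
  out[sel] <- substr(d8[sel], 1, 4)
  out
}

date8 <- function(d) format(d, "%Y%m%d")

#' Generate a synthetic FAERS-like quarter
#'
#' Simulates `n_reports` distinct cases under the configured law (see the
#' module notes above), optionally writes them as dollar-delimited quarterly
#' files, and returns the ground truth needed to test every downstream stage.
#' Identical seeds give byte-identical files.
#'
#' @param config a [generator_config()].
#' @param dir if non-`NULL`, directory where `DEMO.txt`, `DRUG.txt`,
#'   `REAC.txt`, `OUTC.txt`, `THER.txt`, `INDI.txt` and `groundtruth.json`
#'   are written.
#' @return object of class `synthetic_faers`: list with `tables` (named list
#'   of data.tables in file layout), `ground_truth` (distinct case count,
#'   exposure/event flags per case, true onset intervals, expected and
#'   observed cells per planted pair) and `config`.
#' @export
generate <- function(config, dir = NULL) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed)
  n <- config$n_reports
  win <- as.Date(config$date_window)
  span <- as.integer(win[2] - win[1])

  caseid <- sprintf("%08d", 10000000L + seq_len(n))
  primaryid <- paste0(caseid, "1")

  # exposures (n x k)
  target <- names(config$drugs)
  expo <- matrix(FALSE, n, length(target), dimnames = list(NULL, target))
  for (j in target) expo[, j] <- stats::runif(n) < config$drugs[[j]]$prob
  exposed_any <- rowSums(expo) > 0

  # event sets
  events <- matrix(FALSE, n, length(config$event_sets),
                   dimnames = list(NULL, names(config$event_sets)))
  for (s in names(config$event_sets)) {
    base <- solve_base_logit(config, s)
    pl <- planted_for_set(config, s)
    shift <- rep(0, n)
    for (p in pl) shift <- shift + expo[, p$drug] * log(p$theta)
    events[, s] <- stats::runif(n) < stats::plogis(base + shift)
  }

  # dates: FDA receipt uniform over the window (always day precision);
  # suspect start chosen so start + onset stays inside the window
  fda_date <- win[1] + sample.int(span + 1L, n, replace = TRUE) - 1L
  onset <- stats::rgeom(n, config$onset_law$p)
  onset_cl <- pmin(onset, span)
  start_date <- win[1] +
    as.integer(floor(stats::runif(n) * (span - onset_cl + 1)))
  event_date <- data.table::fifelse(
    exposed_any, start_date + onset_cl,
    win[1] + sample.int(span + 1L, n, replace = TRUE) - 1L)
  bg_onset <- pmin(stats::rgeom(n, config$onset_law$p), span)
  bg_start <- pmax(event_date - bg_onset, win[1])

  # demographics
  age_raw <- pmin(pmax(round(stats::rnorm(n, 58, 17)), 18), 94)
  age_unit <- sample(c("YR", "DEC", "MON"), n, replace = TRUE,
                     prob = c(0.9, 0.05, 0.05))
  age_val <- data.table::fcase(age_unit == "YR", as.numeric(age_raw),
                               age_unit == "DEC", floor(age_raw / 10),
                               age_unit == "MON", as.numeric(age_raw) * 12)
  drop_age <- stats::runif(n) < config$missing_age_rate
  age_val[drop_age] <- NA; age_unit[drop_age] <- NA
  sex <- sample(c("M", "F"), n, replace = TRUE, prob = c(0.55, 0.45))
  sex[stats::runif(n) < config$missing_sex_rate] <- NA
  occp <- sample(c("MD", "PH", "CN", "OT"), n, replace = TRUE,
                 prob = c(0.5, 0.25, 0.05, 0.2))
  occp[stats::runif(n) < config$missing_occupation_rate] <- NA
  ctry_pool <- c(US = 0.35, FR = 0.10, DE = 0.08, IT = 0.07, GB = 0.07,
                 ES = 0.05, JP = 0.06, CN = 0.04, IN = 0.04, BR = 0.05,
                 AR = 0.02, ZA = 0.02, AU = 0.03, CA = 0.02)
  country <- sample(names(ctry_pool), n, replace = TRUE, prob = ctry_pool)
  country[stats::runif(n) < config$missing_country_rate] <- NA

  event_dt <- truncate_dates(date8(event_date), config$partial_date_rate)
  event_dt[stats::runif(n) < config$missing_event_date_rate] <- NA

  demo <- data.table::data.table(
    primaryid = primaryid, caseid = caseid, caseversion = "1",
    fda_dt = date8(fda_date), event_dt = event_dt,
    age = ifelse(is.na(age_val), NA_character_,
                 format(age_val, trim = TRUE, scientific = FALSE)),
    age_cod = age_unit, sex = sex, occp_cod = occp,
    reporter_country = country)

  # drug + therapy rows ------------------------------------------------
  # every report: one background drug; exposed reports add their target
  # drug(s) as primary/secondary suspect (background becomes concomitant)
  bg_name <- sample(config$background_drugs, n, replace = TRUE)
  drug_rows <- list(data.table::data.table(
    primaryid = primaryid, drug_seq = "1",
    role_cod = ifelse(exposed_any, "C", "PS"),
    drugname = bg_name, prod_ai = bg_name))
  ther_rows <- list(data.table::data.table(
    primaryid = primaryid, dsg_drug_seq = "1",
    start_dt = date8(bg_start)))
  seq_next <- rep(2L, n)
  for (j in target) {
    idx <- which(expo[, j])
    if (!length(idx)) next
    syns <- toupper(config$drugs[[j]]$synonyms)
    nm <- sample(syns, length(idx), replace = TRUE)
    nm <- ifelse(stats::runif(length(idx)) < 0.2, paste0(nm, " 200MG"), nm)
    ai <- ifelse(stats::runif(length(idx)) < 0.5, toupper(j), NA_character_)
    role <- sample(c("PS", "SS"), length(idx), replace = TRUE,
                   prob = c(0.85, 0.15))
    drug_rows[[j]] <- data.table::data.table(
      primaryid = primaryid[idx], drug_seq = as.character(seq_next[idx]),
      role_cod = role, drugname = nm, prod_ai = ai)
    st <- date8(start_date[idx])
    st <- truncate_dates(st, config$partial_date_rate)
    st[stats::runif(length(idx)) < config$missing_start_date_rate] <- NA
    ther_rows[[j]] <- data.table::data.table(
      primaryid = primaryid[idx], dsg_drug_seq = as.character(seq_next[idx]),
      start_dt = st)
    seq_next[idx] <- seq_next[idx] + 1L
  }
  drug <- data.table::rbindlist(drug_rows)
  ther <- data.table::rbindlist(ther_rows)

  # reactions -----------------------------------------------------------
  bg <- config$background_events
  reac_rows <- list(data.table::data.table(
    primaryid = primaryid,
    pt = sample(bg$pt, n, replace = TRUE, prob = bg$weight)))
  extra <- which(stats::runif(n) < 0.3)
  reac_rows$extra <- data.table::data.table(
    primaryid = primaryid[extra],
    pt = sample(bg$pt, length(extra), replace = TRUE, prob = bg$weight))
  for (s in names(config$event_sets)) {
    idx <- which(events[, s])
    if (!length(idx)) next
    pts <- config$event_sets[[s]]$pts
    reac_rows[[s]] <- data.table::data.table(
      primaryid = primaryid[idx],
      pt = sample(pts, length(idx), replace = TRUE))
  }
  reac <- unique(data.table::rbindlist(reac_rows))

  # outcomes ------------------------------------------------------------
  has_outc <- stats::runif(n) < config$outcome_presence_rate
  prof <- config$outcome_profile
  code1 <- sample(names(prof), n, replace = TRUE, prob = prof)
  code2 <- sample(names(prof), n, replace = TRUE, prob = prof)
  second <- stats::runif(n) < 0.25 & code2 != code1
  outc <- data.table::rbindlist(list(
    data.table::data.table(primaryid = primaryid[has_outc],
                           outc_cod = code1[has_outc]),
    data.table::data.table(primaryid = primaryid[has_outc & second],
                           outc_cod = code2[has_outc & second])))

  # indications ---------------------------------------------------------
  is_covid <- stats::runif(n) < config$covid_fraction
  covid_terms <- covid_keywords()
  other_terms <- c("RHEUMATOID ARTHRITIS", "CYTOKINE RELEASE SYNDROME")
  indi <- data.table::data.table(
    primaryid = primaryid, indi_drug_seq = "1",
    indi_pt = ifelse(is_covid,
                     sample(covid_terms, n, replace = TRUE),
                     sample(other_terms, n, replace = TRUE)))

  # duplicate versions --------------------------------------------------
  dup <- which(stats::runif(n) < config$duplicate_rate)
  if (length(dup)) {
    dup_pid <- paste0(caseid[dup], "2")
    dup_fda <- pmin(fda_date[dup] + sample.int(90L, length(dup), replace = TRUE),
                    win[2])
    demo_dup <- data.table::copy(demo[dup])
    demo_dup[, `:=`(primaryid = dup_pid, caseversion = "2",
                    fda_dt = date8(dup_fda))]
    demo <- data.table::rbindlist(list(demo, demo_dup))
    dup_children <- function(dt) {
      sub <- dt[dt$primaryid %in% paste0(caseid[dup], "1")]
      if (nrow(sub)) {
        sub <- data.table::copy(sub)
        sub[, primaryid := paste0(substr(primaryid, 1, 8), "2")]
      }
      sub
    }
    drug <- data.table::rbindlist(list(drug, dup_children(drug)))
    reac <- data.table::rbindlist(list(reac, dup_children(reac)))
    outc <- data.table::rbindlist(list(outc, dup_children(outc)))
    ther <- data.table::rbindlist(list(ther, dup_children(ther)))
    indi <- data.table::rbindlist(list(indi, dup_children(indi)))
  }

  data.table::setorder(demo, primaryid)
  for (dt in list(drug, reac, outc, ther, indi)) data.table::setorder(dt, primaryid)

  tables <- list(demo = demo, drug = drug, reac = reac, outc = outc,
                 ther = ther, indi = indi)

  pairs <- lapply(config$planted, function(p) {
    exp_cells <- expected_contingency(config, p$drug, p$event_set)
    e <- expo[, p$drug]; ev <- events[, p$event_set]
    obs <- c(a = sum(e & ev), b = sum(e & !ev),
             c = sum(!e & ev), d = sum(!e & !ev))
    list(drug = p$drug, event_set = p$event_set, theta = p$theta,
         expected = exp_cells, observed = obs)
  })
  names(pairs) <- vapply(config$planted,
                         function(p) paste(p$drug, p$event_set, sep = ":"), "")

  ground_truth <- list(
    distinct_case_count = n,
    n_duplicates = length(dup),
    exposure = data.table::data.table(caseid = caseid, expo),
    events = data.table::data.table(caseid = caseid, events),
    onset = data.table::data.table(caseid = caseid, interval_days = onset_cl,
                                   exposed = exposed_any),
    covid = data.table::data.table(caseid = caseid, is_covid = is_covid),
    pairs = pairs)

  out <- structure(list(tables = tables, ground_truth = ground_truth,
                        config = config), class = "synthetic_faers")
  if (!is.null(dir)) {
    write_quarter(tables, dir)
    gt_json <- list(
      distinct_case_count = n,
      n_duplicates = length(dup),
      seed = config$seed,
      pairs = lapply(pairs, function(p) {
        list(drug = p$drug, event_set = p$event_set, theta = p$theta,
             expected = as.list(p$expected), observed = as.list(p$observed))
      }))
    jsonlite::write_json(gt_json, file.path(dir, "groundtruth.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  out
}

#' @export
print.synthetic_faers <- function(x, ...) {
  cat("<synthetic_faers>", x$ground_truth$distinct_case_count,
      "cases (+", x$ground_truth$n_duplicates, "duplicate versions), seed",
      x$config$seed, "\n")
  for (p in x$ground_truth$pairs) {
    cat(sprintf("  planted %s ~ %s: theta = %g\n", p$drug, p$event_set, p$theta))
  }
  invisible(x)
}
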