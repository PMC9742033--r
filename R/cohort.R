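# Case selection: COVID-19 context identification, drug-synonym matching,
# the DILI preferred-term case definition, and descriptive stratification.

#' MedDRA preferred terms defining drug-induced liver injury
#'
#' The 17 preferred terms used as the hepatotoxicity case definition.
#' Matching is exact (case-insensitive) on the whole PT string — no substring
#' matching and no MedDRA hierarchy or SMQ expansion.
#'
#' @return character vector of 17 preferred terms.
#' @export
dili_terms <- function() {
  c("LIVER INJURY",
    "LIVER DAMAGE",
    "HEPATIC DAMAGE",
    "HEPATOTOXICITY",
    "HEPATITIS",
    "NONALCOHOLIC FATTY LIVER DISEASE",
    "LIVER FATTY INFILTRATION",
    "CHOLESTASIS",
    "BILIARY CHOLANGITIS",
    "HEPATIC ENCEPHALOPATHY",
    "HEPATIC FAILURE",
    "PORTAL HYPERTENSION",
    "HEPATIC NECROSIS",
    "DILI",
    "HEPATOCELLULAR INJURY",
    "HEPATIC ENZYME ABNORMAL",
    "BLOOD BILIRUBIN ABNORMAL")
}

#' COVID-19 indication keywords
#'
#' Keywords used to identify coronavirus-infection reports in free-text
#' indication and reaction terms.  Matching is case-insensitive and
#' hyphen/space-insensitive (so "covid 19 pneumonia" matches "COVID-19").
#'
#' @return character vector of keywords.
#' @export
covid_keywords <- function() c("COVID-19", "2019-Ncov", "SARS-Cov-2")

#' Drug synonym dictionary
#'
#' Maps canonical drug names to their trade/synonym names for free-text
#' matching against the verbatim `drugname` and `prod_ai` fields.  Synonym
#' sets must be non-empty and pairwise disjoint across canonical names
#' (case-insensitive).
#'
#' @param x named list: canonical name -> character vector of synonyms.
#' @return validated list of class `drug_dictionary`.
#' @examples
#' default_drug_dictionary()
#' @export
drug_dictionary <- function(x) {
  stopifnot(is.list(x), length(x) > 0, !is.null(names(x)))
  x <- lapply(x, function(s) unique(tolower(trimws(as.character(s)))))
  if (any(!vapply(x, length, 1L))) {
    stop("drug_dictionary: every synonym set must be non-empty", call. = FALSE)
  }
  all_syn <- unlist(x, use.names = FALSE)
  if (anyDuplicated(all_syn)) {
    stop("drug_dictionary: synonym sets must be pairwise disjoint; duplicated: ",
         paste(unique(all_syn[duplicated(all_syn)]), collapse = ", "),
         call. = FALSE)
  }
  structure(x, class = "drug_dictionary")
}

#' @rdname drug_dictionary
#' @details `default_drug_dictionary()` ships the IL-6 receptor antagonist
#'   entries: tocilizumab (actemra, atlizumab, roactemra) and sarilumab
#'   (kevzara).
#' @export
default_drug_dictionary <- function() {
  drug_dictionary(list(
    tocilizumab = c("tocilizumab", "actemra", "atlizumab", "roactemra"),
    sarilumab   = c("sarilumab", "kevzara")
  ))
}

# regex that matches a synonym as a token (word-boundary-tolerant): the
# synonym may be followed by dosage strings etc. but not embedded in a longer
# alphanumeric token
synonym_regex <- function(synonyms) {
  esc <- gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", synonyms)
  paste0("(^|[^[:alnum:]])(", paste(esc, collapse = "|"), ")($|[^[:alnum:]])")
}

#' Match drug entries against a dictionary
#'
#' Returns the canonical names whose synonyms appear (case-insensitive,
#' word-boundary-tolerant, dosage suffixes tolerated) in the verbatim drug
#' name or active-ingredient field of any entry holding one of the requested
#' role codes.  If entries match several canonical drugs, all are returned so
#' each can be counted separately.
#'
#' @param drug_entries `data.table`/data.frame with columns `drugname`,
#'   `prod_ai`, `role_cod` (one report's drug entries).
#' @param dictionary a [drug_dictionary()].
#' @param roles role codes treated as suspect; default `c("PS", "SS")`
#'   (primary/secondary suspect); concomitant (`C`) and interacting (`I`)
#'   entries are ignored by default.
#' @return character vector of matched canonical names (length 0 if none).
#' @export
match_drug <- function(drug_entries, dictionary = default_drug_dictionary(),
                       roles = c("PS", "SS")) {
  stopifnot(inherits(dictionary, "drug_dictionary"))
  de <- data.table::as.data.table(drug_entries)
  if (nrow(de) == 0) return(character(0))
  de <- de[role_cod %in% roles]
  if (nrow(de) == 0) return(character(0))
  text <- tolower(paste(de$drugname %||% "", de$prod_ai %||% ""))
  hits <- vapply(dictionary, function(syn) {
    any(grepl(synonym_regex(syn), text))
  }, logical(1))
  names(dictionary)[hits]
}

# vectorised exposure: long table (primaryid, drug, drug_seq) over all reports
match_drug_table <- function(drug_dt, dictionary, roles = c("PS", "SS")) {
  de <- drug_dt[role_cod %in% roles]
  out <- list()
  if (nrow(de)) {
    text <- tolower(paste(ifelse(is.na(de$drugname), "", de$drugname),
                          ifelse(is.na(de$prod_ai), "", de$prod_ai)))
    for (canon in names(dictionary)) {
      hit <- grepl(synonym_regex(dictionary[[canon]]), text)
      if (any(hit)) {
        out[[canon]] <- data.table::data.table(
          primaryid = de$primaryid[hit], drug = canon,
          drug_seq = de$drug_seq[hit])
      }
    }
  }
  if (length(out)) {
    unique(data.table::rbindlist(out))
  } else {
    data.table::data.table(primaryid = character(0), drug = character(0),
                           drug_seq = integer(0))
  }
}

normalize_covid <- function(x) gsub("[ -]", "", tolower(x))

#' Is a report a COVID-19 case?
#'
#' True iff any indication term or reaction preferred term contains one of
#' the keywords, case-insensitive and hyphen/space-insensitive.  Both fields
#' are searched because spontaneous reports encode COVID-19 variously as an
#' indication or as a coded event.
#'
#' @param report list with elements `indi` (with column `indi_pt`) and `reac`
#'   (with column `pt`) for one report, or character vectors in `indi`/`reac`.
#' @param keywords defaults to [covid_keywords()].
#' @return logical scalar.
#' @export
is_covid_case <- function(report, keywords = covid_keywords()) {
  stopifnot(length(keywords) > 0)
  terms <- c(
    if (!is.null(report$indi)) {
      if (is.character(report$indi)) report$indi else report$indi$indi_pt
    },
    if (!is.null(report$reac)) {
      if (is.character(report$reac)) report$reac else report$reac$pt
    })
  terms <- terms[!is.na(terms)]
  if (length(terms) == 0) return(FALSE)
  pat <- paste(normalize_covid(keywords), collapse = "|")
  any(grepl(pat, normalize_covid(terms)))
}

#' Does a report carry a DILI event?
#'
#' True iff any reaction preferred term equals (case-insensitive, whitespace
#' trimmed) one of the case-definition terms.  Exact match only — substrings
#' such as "Hepatic enzyme increased" do not qualify.
#'
#' @param report list with element `reac` (column `pt`), or a character
#'   vector of PTs.
#' @param definition character vector of PTs; default [dili_terms()].
#' @return logical scalar.
#' @export
has_dili_event <- function(report, definition = dili_terms()) {
  pts <- if (is.character(report)) report else report$reac$pt
  pts <- pts[!is.na(pts)]
  any(toupper(trimws(pts)) %in% toupper(trimws(definition)))
}

#' Convert a FAERS age value and unit code to years
#'
#' @param age_value numeric vector of age values (may be `NA`).
#' @param age_unit unit codes: `DEC` (decades), `YR`, `MON`, `WK`, `DY`,
#'   `HR`.  Unknown units give `NA` with a warning.
#' @return numeric vector of ages in years.
#' @examples
#' age_in_years(c(6, 18), c("DEC", "MON"))  # 60, 1.5
#' @export
age_in_years <- function(age_value, age_unit) {
  factors <- c(DEC = 10, YR = 1, MON = 1 / 12, WK = 1 / 52.1775,
               DY = 1 / 365.25, HR = 1 / 8766)
  age_unit <- toupper(as.character(age_unit))
  f <- factors[age_unit]
  unknown <- !is.na(age_value) & !is.na(age_unit) & is.na(f) & nzchar(age_unit)
  if (any(unknown)) {
    warning(sprintf("age_in_years: %d unknown age unit(s) treated as missing",
                    sum(unknown)), call. = FALSE)
  }
  unname(as.numeric(age_value) * f)
}

default_study_window <- function() c("2020Q2", "2021Q4")

#' Build the study cohort
#'
#' Applies the case-selection chain to deduplicated reports: restrict to the
#' reporting-quarter window, keep COVID-19 context reports, then annotate each
#' report with its suspect-drug exposure (per the dictionary) and whether it
#' carries a DILI event.  Non-exposed COVID-19 reports are retained — they
#' form the comparator universe for disproportionality.
#'
#' @param reports deduplicated `faers_reports` (see [deduplicate()]).
#' @param dictionary a [drug_dictionary()].
#' @param definition DILI preferred terms; default [dili_terms()].
#' @param window inclusive quarter window `c(from, to)` in `"YYYYQn"` form;
#'   default `2020Q2`--`2021Q4`.
#' @param keywords COVID keywords; default [covid_keywords()].
#' @param roles suspect role codes; default `c("PS", "SS")`.
#' @return object of class `study_cohort`: list with `reports` (one row per
#'   report, with `age_years`, `quarter`, `has_dili`), `exposure` (long table
#'   `primaryid`/`drug`/`drug_seq`), the child tables, the configuration used
#'   and `flow` (selection-flow counts).
#' @export
build_cohort <- function(reports,
                         dictionary = default_drug_dictionary(),
                         definition = dili_terms(),
                         window = default_study_window(),
                         keywords = covid_keywords(),
                         roles = c("PS", "SS")) {
  stopifnot(inherits(reports, "faers_reports"),
            inherits(dictionary, "drug_dictionary"),
            length(window) == 2)
  wi <- quarter_index(window)
  if (any(is.na(wi)) || wi[1] > wi[2]) {
    stop("window must be c('YYYYQn','YYYYQn') with start <= end", call. = FALSE)
  }
  demo <- data.table::copy(reports$demo)
  flow <- c(deduplicated_reports = nrow(demo))

  qi <- quarter_index(demo$quarter)
  demo <- demo[!is.na(qi) & qi >= wi[1] & qi <= wi[2]]
  flow["in_window"] <- nrow(demo)

  # COVID context: keyword search over indication terms and reaction PTs
  pat <- paste(normalize_covid(keywords), collapse = "|")
  indi <- reports$indi[primaryid %in% demo$primaryid]
  reac <- reports$reac[primaryid %in% demo$primaryid]
  covid_ids <- union(
    indi$primaryid[grepl(pat, normalize_covid(ifelse(is.na(indi$indi_pt), "", indi$indi_pt)))],
    reac$primaryid[grepl(pat, normalize_covid(ifelse(is.na(reac$pt), "", reac$pt)))])
  demo <- demo[primaryid %in% covid_ids]
  flow["covid_context"] <- nrow(demo)

  keep <- function(dt) dt[primaryid %in% demo$primaryid]
  drug <- keep(reports$drug)
  reac <- keep(reports$reac)
  outc <- keep(reports$outc)
  ther <- keep(reports$ther)
  indi <- keep(reports$indi)

  exposure <- match_drug_table(drug, dictionary, roles)
  def_up <- toupper(trimws(definition))
  dili_ids <- unique(reac$primaryid[toupper(trimws(ifelse(is.na(reac$pt), "", reac$pt))) %in% def_up])
  demo[, has_dili := primaryid %in% dili_ids]
  demo[, age_years := suppressWarnings(age_in_years(age, age_cod))]

  for (canon in names(dictionary)) {
    ids <- unique(exposure[drug == canon, primaryid])
    flow[paste0("exposed_", canon)] <- length(ids)
    flow[paste0("cases_", canon)] <- sum(demo$primaryid %in% ids & demo$has_dili)
  }
  flow["dili_events"] <- sum(demo$has_dili)

  pv_log("cohort: %d reports in window, %d with COVID context",
         flow[["in_window"]], flow[["covid_context"]])

  structure(list(reports = demo, exposure = exposure,
                 drug = drug, reac = reac, outc = outc, ther = ther,
                 indi = indi,
                 dictionary = dictionary, definition = definition,
                 window = window, keywords = keywords, roles = roles,
                 flow = flow),
            class = "study_cohort")
}

#' @export
print.study_cohort <- function(x, ...) {
  cat("<study_cohort>", nrow(x$reports), "COVID-19 reports in",
      paste(x$window, collapse = "-"), "\n")
  for (canon in names(x$dictionary)) {
    cat(sprintf("  %-14s exposed %5d, DILI cases %4d\n", canon,
                x$flow[[paste0("exposed_", canon)]],
                x$flow[[paste0("cases_", canon)]]))
  }
  invisible(x)
}

# reports exposed to `drug` that carry a DILI event (the descriptive-table
# population)
case_ids <- function(cohort, drug_name) {
  ids <- unique(cohort$exposure[drug == drug_name, primaryid])
  cohort$reports[primaryid %in% ids & has_dili == TRUE, primaryid]
}

continent_table <- function() {
  path <- system.file("extdata", "country_continent.csv", package = "pvdili")
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Map ISO 3166-1 alpha-2 country codes to continent labels
#'
#' Uses a static shipped table with the continent labels used in descriptive
#' reporting: Africa, Asian, Europe, North America, South America, Oceania.
#' Unmapped or missing codes give `"Unknown"`.
#'
#' @param iso2 character vector of two-letter country codes.
#' @return character vector of continent labels.
#' @export
country_to_continent <- function(iso2) {
  tab <- continent_table()
  out <- tab$continent[match(toupper(as.character(iso2)), tab$country)]
  out[is.na(out)] <- "Unknown"
  out
}

age_bands <- function() c("<18", "18-44", "45-64", "65-74", "75-84",
                          ">=85", "Unknown")

band_age <- function(age_years) {
  a <- floor(age_years)
  b <- rep("Unknown", length(a))
  b[!is.na(a) & a < 18] <- "<18"
  b[!is.na(a) & a >= 18 & a <= 44] <- "18-44"
  b[!is.na(a) & a >= 45 & a <= 64] <- "45-64"
  b[!is.na(a) & a >= 65 & a <= 74] <- "65-74"
  b[!is.na(a) & a >= 75 & a <= 84] <- "75-84"
  b[!is.na(a) & a >= 85] <- ">=85"
  b
}

outcome_labels <- function() {
  c(CA = "Congenital anomaly",
    DE = "Death",
    DS = "Disability",
    HO = "Hospitalization-initial or prolonged",
    LT = "Life-threatening",
    OT = "Other serious/important medical events",
    RI = "Required intervention to prevent permanent impairment")
}

stratify_dimensions <- function() {
  c("age", "sex", "occupation", "quarter", "region", "outcome")
}

#' Descriptive stratification of the DILI cases of one drug
#'
#' Tabulates the DILI case reports of `drug` by one dimension.  For the
#' partitioning dimensions (age band, sex, reporter occupation, report
#' quarter, region) counts sum to the number of cases and percentages use
#' that count as denominator.  The outcome dimension is *not* a partition
#' (one report may carry several outcome codes); its percentages use the
#' number of case reports carrying at least one outcome code (configurable
#' via `outcome_denominator`).
#'
#' @param cohort a `study_cohort`.
#' @param dimension one of `"age"`, `"sex"`, `"occupation"`, `"quarter"`,
#'   `"region"`, `"outcome"`.
#' @param drug canonical drug name present in the cohort dictionary.
#' @param outcome_denominator `"outcome_reports"` (default: reports with >= 1
#'   outcome code) or `"case_reports"` (all DILI cases of the drug).
#' @return `data.table` with columns `dimension`, `stratum`, `count`,
#'   `percent` (numeric) and `percent_str`; attribute `denominator`.
#' @export
stratify <- function(cohort, dimension, drug,
                     outcome_denominator = c("outcome_reports", "case_reports")) {
  stopifnot(inherits(cohort, "study_cohort"))
  dimension <- match.arg(dimension, stratify_dimensions())
  outcome_denominator <- match.arg(outcome_denominator)
  if (!drug %in% names(cohort$dictionary)) {
    stop("unknown drug: ", drug, call. = FALSE)
  }
  ids <- case_ids(cohort, drug)
  rep_dt <- cohort$reports[primaryid %in% ids]
  n_cases <- nrow(rep_dt)

  if (dimension == "outcome") {
    outc <- unique(cohort$outc[primaryid %in% ids, .(primaryid, outc_cod)])
    denom <- switch(outcome_denominator,
                    outcome_reports = length(unique(outc$primaryid)),
                    case_reports = n_cases)
    labs <- outcome_labels()
    cnt <- vapply(names(labs), function(code) {
      length(unique(outc[outc_cod == code, primaryid]))
    }, integer(1))
    out <- data.table::data.table(
      dimension = dimension, stratum = unname(labs[sort(names(labs))]),
      count = unname(cnt[sort(names(labs))]))
  } else {
    strata <- switch(dimension,
      age = factor(band_age(rep_dt$age_years), levels = age_bands()),
      sex = factor(data.table::fcase(
        !is.na(rep_dt$sex) & rep_dt$sex == "F", "Female",
        !is.na(rep_dt$sex) & rep_dt$sex == "M", "Male",
        default = "Unknown"), levels = c("Female", "Male", "Unknown")),
      occupation = factor(data.table::fcase(
        !is.na(rep_dt$occp_cod) & rep_dt$occp_cod == "CN", "Consumer",
        !is.na(rep_dt$occp_cod) & rep_dt$occp_cod == "PH", "Pharmacist",
        !is.na(rep_dt$occp_cod) & rep_dt$occp_cod == "MD", "Physician",
        !is.na(rep_dt$occp_cod) & rep_dt$occp_cod == "OT", "Other health-professional",
        default = "Unknown"),
        levels = c("Consumer", "Pharmacist", "Physician",
                   "Other health-professional", "Unknown")),
      quarter = factor(rep_dt$quarter),
      region = factor(country_to_continent(rep_dt$reporter_country),
                      levels = c("Africa", "Asian", "Europe", "North America",
                                 "South America", "Oceania", "Unknown")))
    denom <- n_cases
    tab <- table(strata)
    out <- data.table::data.table(
      dimension = rep(dimension, length(tab)),
      stratum = if (length(tab)) names(tab) else character(0),
      count = as.integer(tab))
  }
  out[, percent := if (denom > 0) round_half_up(100 * count / denom, 2) else NA_real_]
  out[, percent_str := format_percent(count, denom)]
  data.table::setattr(out, "denominator", denom)
  data.table::setattr(out, "drug", drug)
  out[]
}

#' All descriptive tables for a set of drugs
#'
#' Convenience wrapper around [stratify()] stacking every dimension and drug
#' into one long table.
#'
#' @inheritParams stratify
#' @param drugs canonical names; defaults to all dictionary entries.
#' @return long `data.table` with a `drug` column.
#' @export
descriptive_tables <- function(cohort, drugs = NULL, ...) {
  drugs <- drugs %||% names(cohort$dictionary)
  out <- list()
  for (d in drugs) {
    for (dim in stratify_dimensions()) {
      tab <- stratify(cohort, dim, d, ...)
      tab[, drug := d]
      out[[paste(d, dim)]] <- tab
    }
  }
  data.table::rbindlist(out)[]
}
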