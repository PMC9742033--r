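test_that("drug dictionary validates and matches synonyms robustly", {
  dict <- default_drug_dictionary()
  expect_setequal(names(dict), c("tocilizumab", "sarilumab"))
  expect_error(drug_dictionary(list(a = "x", b = c("y", "x"))), "disjoint")
  expect_error(drug_dictionary(list(a = character(0))), "non-empty")

  de <- function(name, role = "PS", ai = NA) {
    data.table::data.table(drugname = name, prod_ai = ai, role_cod = role)
  }
  expect_equal(match_drug(de("ACTEMRA")), "tocilizumab")
  expect_equal(match_drug(de("KEVZARA 200MG", "SS")), "sarilumab")
  expect_equal(match_drug(de("aspirin")), character(0))
  # case-insensitive, dosage suffix tolerated, not embedded substrings
  expect_equal(match_drug(de("roActemra 20 MG/ML")), "tocilizumab")
  expect_equal(match_drug(de("XACTEMRAX")), character(0))
  # active ingredient field is searched too
  expect_equal(match_drug(de("UNKNOWN BRAND", ai = "tocilizumab")),
               "tocilizumab")
  # role filtering: concomitant entries are ignored by default
  expect_equal(match_drug(de("ACTEMRA", role = "C")), character(0))
  expect_equal(match_drug(de("ACTEMRA", role = "C"), roles = c("PS", "SS", "C")),
               "tocilizumab")
  # a report with both drugs returns both for separate counting
  both <- data.table::rbindlist(list(de("ACTEMRA"), de("KEVZARA")))
  expect_setequal(match_drug(both), c("tocilizumab", "sarilumab"))
})

test_that("COVID-19 identification is keyword, case and punctuation tolerant", {
  expect_true(is_covid_case(list(indi = "COVID-19")))
  expect_true(is_covid_case(list(indi = "covid 19 pneumonia")))
  expect_true(is_covid_case(list(indi = "SARS-CoV-2 infection")))
  expect_true(is_covid_case(list(indi = "2019-nCoV test positive")))
  expect_false(is_covid_case(list(indi = "influenza")))
  # reaction PTs are searched as well
  expect_true(is_covid_case(list(reac = "COVID-19 pneumonia")))
  expect_false(is_covid_case(list()))
})

test_that("DILI definition is exact-match on 17 PTs", {
  expect_length(dili_terms(), 17)
  expect_true(has_dili_event("Hepatotoxicity"))
  expect_true(has_dili_event(c("Pyrexia", "Cholestasis")))
  expect_true(has_dili_event("  cholestasis "))
  expect_false(has_dili_event("Hepatic enzyme increased"))  # not in the list
  expect_false(has_dili_event("Liver"))
  expect_false(has_dili_event(character(0)))
})

test_that("age conversion covers all unit codes", {
  expect_equal(age_in_years(6, "DEC"), 60)
  expect_equal(age_in_years(18, "MON"), 1.5)
  expect_equal(age_in_years(c(50, 104.355, 730.5, 17532),
                            c("YR", "WK", "DY", "HR")), c(50, 2, 2, 2))
  expect_true(is.na(age_in_years(NA, NA)))
  expect_warning(res <- age_in_years(5, "LIGHTYEARS"), "unknown age unit")
  expect_true(is.na(res))
})

test_that("build_cohort filters on window and COVID context", {
  r <- make_reports(c("W1", "W2", "W3", "W4"),
                    fda_dt = c("20200115", "20200715", "20210715", "20220301"),
                    indi_pt = c("COVID-19", "COVID-19", "influenza",
                                "COVID-19"))
  coh <- build_cohort(r)
  # W1 before 2020Q2, W4 after 2021Q4, W3 not COVID
  expect_equal(coh$reports$primaryid, "W2")
  expect_equal(unname(coh$flow["deduplicated_reports"]), 4)
  expect_equal(unname(coh$flow["in_window"]), 2)
  expect_equal(unname(coh$flow["covid_context"]), 1)
  # flow is monotone non-increasing
  expect_true(all(diff(coh$flow[c("deduplicated_reports", "in_window",
                                  "covid_context")]) <= 0))
})

test_that("non-exposed COVID reports stay in the comparator universe", {
  r <- make_reports(c("X1", "X2", "X3", "X4"),
                    drugname = c("ACTEMRA", "ACTEMRA", "REMDESIVIR",
                                 "REMDESIVIR"),
                    pt = c("Hepatotoxicity", "Pyrexia", "Cholestasis",
                           "Pyrexia"))
  coh <- build_cohort(r)
  expect_equal(nrow(coh$reports), 4)
  expect_setequal(coh$exposure[drug == "tocilizumab", primaryid],
                  c("X1", "X2"))
  expect_equal(coh$reports[has_dili == TRUE, sort(primaryid)],
               c("X1", "X3"))
  t <- build_contingency(coh, "tocilizumab")
  expect_equal(c(t$a, t$b, t$c, t$d), c(1, 1, 1, 1))
})

test_that("cohort recovers planted exposure and events from generated data", {
  syn <- generate(generator_config(n_reports = 1500, seed = 31))
  rep <- deduplicate(assemble_reports(syn$tables))
  coh <- build_cohort(rep)
  gt <- syn$ground_truth
  covid_cases <- gt$covid[is_covid == TRUE, caseid]
  expect_setequal(coh$reports$caseid, covid_cases)
  # exposure flags match ground truth on the covid subset
  for (d in c("tocilizumab", "sarilumab")) {
    want <- gt$exposure[gt$exposure[[d]] & caseid %in% covid_cases, caseid]
    got <- coh$reports[primaryid %in% coh$exposure[drug == d, primaryid],
                       caseid]
    expect_setequal(got, want)
  }
  want_dili <- gt$events[gt$events[["dili"]] & caseid %in% covid_cases, caseid]
  expect_setequal(coh$reports[has_dili == TRUE, caseid], want_dili)
})

test_that("stratify partitions sum to cohort size and formats half-up", {
  coh <- make_descriptive_cohort()
  for (dim in c("age", "sex", "occupation", "quarter", "region")) {
    tab <- stratify(coh, dim, "tocilizumab")
    expect_equal(sum(tab$count), 192, label = dim)
    expect_equal(attr(tab, "denominator"), 192)
  }
  tab <- stratify(coh, "sex", "tocilizumab")
  expect_equal(tab[stratum == "Unknown", percent_str], "40.63%")  # 40.625
  expect_error(stratify(coh, "age", "nosuchdrug"), "unknown drug")
})

test_that("percent formatting matches printed descriptive arithmetic", {
  expect_equal(format_percent(58, 192), "30.21%")
  expect_equal(format_percent(89, 192), "46.35%")
  expect_equal(format_percent(30, 175), "17.14%")
  expect_equal(format_percent(30, 82), "36.59%")
  expect_equal(format_percent(5, 5), "100.00%")
  expect_true(is.na(format_percent(0, 0)))
  expect_equal(round_half_up(c(0.125, -0.125, 2.675), 2),
               c(0.13, -0.13, 2.68))
})
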