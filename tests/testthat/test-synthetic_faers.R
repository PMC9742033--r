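test_that("generator_config validates fields by name", {
  expect_s3_class(generator_config(n_reports = 10, seed = 1),
                  "generator_config")
  expect_error(generator_config(n_reports = 0, seed = 1), "n_reports")
  expect_error(generator_config(covid_fraction = 1.2, seed = 1),
               "covid_fraction")
  expect_error(generator_config(
    planted = list(list(drug = "nope", event_set = "dili", theta = 2)),
    seed = 1), "planted")
  expect_error(generator_config(
    planted = list(list(drug = "sarilumab", event_set = "dili", theta = 0)),
    seed = 1), "theta")
  expect_error(generator_config(
    outcome_profile = c(DE = 0.5, LT = 0.4, HO = 0, DS = 0, CA = 0, RI = 0,
                        OT = 0.2), seed = 1),
    "outcome_profile")
})

test_that("expected_contingency matches the product law under independence", {
  cfg <- generator_config(
    n_reports = 1000,
    drugs = list(x = list(synonyms = "XDRUG", prob = 0.1)),
    event_sets = list(dili = list(pts = dili_terms(), prob = 0.2)),
    planted = list(), seed = 1)
  expect_equal(expected_contingency(cfg, "x", "dili"),
               c(a = 20, b = 80, c = 180, d = 720))
  cfg2 <- generator_config(
    n_reports = 1000,
    drugs = list(x = list(synonyms = "XDRUG", prob = 0.5)),
    event_sets = list(dili = list(pts = dili_terms(), prob = 0.5)),
    planted = list(), seed = 1)
  expect_equal(expected_contingency(cfg2, "x", "dili"),
               c(a = 250, b = 250, c = 250, d = 250))
  expect_error(expected_contingency(cfg, "y", "dili"), "unknown drug")
  expect_error(expected_contingency(cfg, "x", "other"), "unknown event set")
})

test_that("expected_contingency solves the 2x2 margins for planted theta", {
  # independent oracle: root-find the unexposed event probability p0 such
  # that the marginal event probability is met with odds ratio theta
  theta <- 5; p_d <- 0.1; p_e <- 0.2; n <- 1000
  f <- function(p0) {
    p1 <- theta * p0 / (1 - p0 + theta * p0)
    p_d * p1 + (1 - p_d) * p0 - p_e
  }
  p0 <- uniroot(f, c(1e-9, p_e), tol = 1e-14)$root
  p1 <- theta * p0 / (1 - p0 + theta * p0)
  oracle <- c(a = n * p_d * p1, b = n * p_d * (1 - p1),
              c = n * (1 - p_d) * p0, d = n * (1 - p_d) * (1 - p0))

  cfg <- generator_config(
    n_reports = n,
    drugs = list(x = list(synonyms = "XDRUG", prob = p_d)),
    event_sets = list(dili = list(pts = dili_terms(), prob = p_e)),
    planted = list(list(drug = "x", event_set = "dili", theta = theta)),
    seed = 1)
  got <- expected_contingency(cfg, "x", "dili")
  expect_equal(got, oracle, tolerance = 1e-9)
  expect_equal(sum(got), n)
  # implied odds ratio is exactly theta
  expect_equal((got["a"] * got["d"]) / (got["b"] * got["c"]),
               c(a = theta), tolerance = 1e-9)
})

test_that("identical seeds give byte-identical files", {
  cfg <- generator_config(n_reports = 150, seed = 99)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  generate(cfg, dir = d1)
  generate(cfg, dir = d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
})

test_that("duplicate_rate = 0 gives distinct_case_count = n_reports", {
  syn <- generate(generator_config(n_reports = 120, duplicate_rate = 0,
                                   seed = 3))
  expect_equal(syn$ground_truth$distinct_case_count, 120)
  expect_equal(syn$ground_truth$n_duplicates, 0)
  expect_equal(nrow(syn$tables$demo), 120)
})

test_that("planted duplicates are removed exactly by deduplication", {
  syn <- generate(generator_config(n_reports = 200, duplicate_rate = 0.1,
                                   seed = 5), dir = withr::local_tempdir())
  q <- assemble_reports(list(demo = syn$tables$demo, drug = syn$tables$drug,
                             reac = syn$tables$reac, outc = syn$tables$outc,
                             ther = syn$tables$ther, indi = syn$tables$indi))
  d <- deduplicate(q)
  expect_equal(nrow(d$demo), syn$ground_truth$distinct_case_count)
  expect_equal(attr(d, "n_removed"), syn$ground_truth$n_duplicates)
  # the surviving version of each duplicated case is version 2
  dup_cases <- syn$tables$demo[caseversion == "2", caseid]
  expect_true(all(d$demo[caseid %in% dup_cases, caseversion] == 2L))
})

test_that("empirical cell frequencies converge to expected_contingency", {
  cfg <- generator_config(n_reports = 1e5, seed = 17)
  syn <- generate(cfg)
  for (pair in syn$ground_truth$pairs) {
    exp_cells <- pair$expected
    obs <- pair$observed
    p <- exp_cells / cfg$n_reports
    se <- sqrt(cfg$n_reports * p * (1 - p))
    expect_true(all(abs(obs - exp_cells) <= 3 * se),
                label = paste("cells within 3 SE for", pair$drug))
  }
})

test_that("empirical ROR falls inside its own 95% CI in >=93% of replicates", {
  cfg <- generator_config(
    n_reports = 5000,
    drugs = list(x = list(synonyms = "XDRUG", prob = 0.1)),
    event_sets = list(dili = list(pts = dili_terms(), prob = 0.2)),
    planted = list(list(drug = "x", event_set = "dili", theta = 1)),
    seed = 1)
  set.seed(123)
  hits <- vapply(1:200, function(i) {
    t <- sample_contingency(cfg, "x", "dili")
    ci <- ror_with_ci(t)
    ci$ci_low <= 1 && 1 <= ci$ci_high
  }, logical(1))
  expect_gte(mean(hits), 0.93)
})

test_that("generated quarters respect parser invariants end to end", {
  dir <- withr::local_tempdir()
  syn <- generate(generator_config(n_reports = 300, seed = 21), dir = dir)
  q <- parse_quarter(dir)
  expect_true(all(vapply(q$parse_report, function(r) r$rejected == 0, TRUE)))
  expect_equal(nrow(q$tables$demo), nrow(syn$tables$demo))
  # every child row points at an existing report
  rep <- assemble_reports(q)
  for (k in c("drug", "reac", "outc", "ther", "indi")) {
    expect_true(all(rep[[k]]$primaryid %in% rep$demo$primaryid), label = k)
  }
  # COVID indication terms are drawn verbatim from the keyword set
  covid <- q$tables$indi[indi_pt %in% covid_keywords()]
  expect_gt(nrow(covid), 0)
  expect_true(file.exists(file.path(dir, "groundtruth.json")))
})
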