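Package: pvdili
Title: Pharmacovigilance Signal Detection for Drug-Induced Liver Injury in
    Spontaneous Reporting Data
Version: 0.1.0
Authors@R:
    person("FAERS", "Pharmacovigilance Tools", email = "pvdili@example.org",
           role = c("aut", "cre"))
Description: A reusable pipeline for disproportionality analysis of
    spontaneous adverse-event reports in the style of the FDA Adverse Event
    Reporting System (FAERS).  Reads dollar-delimited quarterly ASCII tables
    (DEMO, DRUG, REAC, OUTC, THER, INDI), deduplicates cases by case number
    and version, selects a COVID-19 treatment cohort by indication keywords
    and drug-synonym matching, defines drug-induced liver injury (DILI) by an
    exact MedDRA preferred-term list, and computes reporting odds ratio (ROR),
    proportional reporting ratio (PRR) with chi-squared, information component
    (IC) and empirical Bayes geometric mean (EBGM) with confidence bounds and
    signal criteria.  Includes time-to-onset and outcome/fatality analyses, a
    synthetic FAERS-like data generator with planted reporting odds ratios for
    end-to-end testing, and a one-command study driver.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    data.table (>= 1.14),
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
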