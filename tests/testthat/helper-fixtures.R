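# In-code fixture builders: small FAERS-style tables and cohorts.

demo_header <- c("primaryid", "caseid", "caseversion", "fda_dt", "event_dt",
                 "age", "age_cod", "sex", "occp_cod", "reporter_country")

demo_line <- function(primaryid, caseid = primaryid, caseversion = 1,
                      fda = "20200715", event = "20200710", age = "60",
                      age_cod = "YR", sex = "M", occp = "MD", country = "US") {
  paste(primaryid, caseid, caseversion, fda, event, age, age_cod, sex, occp,
        country, sep = "$")
}

write_demo_file <- function(path, lines) {
  writeLines(c(paste(demo_header, collapse = "$"), lines), path)
}

# build a typed faers_reports object straight from vectors (one row per
# report), with every report carrying a COVID indication, a suspect drug
# entry and one reaction PT
make_reports <- function(primaryid,
                         caseid = primaryid,
                         caseversion = 1L,
                         fda_dt = "20200715",
                         event_dt = "20200710",
                         age = NA_real_, age_cod = NA_character_,
                         sex = NA_character_, occp_cod = NA_character_,
                         country = NA_character_,
                         drugname = "ACTEMRA", role_cod = "PS",
                         pt = "Hepatotoxicity",
                         indi_pt = "COVID-19",
                         start_dt = NA_character_,
                         outc = NULL) {
  n <- length(primaryid)
  rec <- function(x) rep_len(x, n)
  demo <- data.table::data.table(
    primaryid = as.character(primaryid), caseid = as.character(rec(caseid)),
    caseversion = as.integer(rec(caseversion)), fda_dt = rec(fda_dt),
    event_dt = rec(event_dt), age = as.numeric(rec(age)),
    age_cod = rec(age_cod), sex = rec(sex), occp_cod = rec(occp_cod),
    reporter_country = rec(country))
  drug <- data.table::data.table(
    primaryid = as.character(primaryid), drug_seq = 1L,
    role_cod = rec(role_cod), drugname = rec(drugname),
    prod_ai = NA_character_)
  reac <- data.table::data.table(primaryid = as.character(primaryid),
                                 pt = rec(pt))
  ther <- data.table::data.table(primaryid = as.character(primaryid),
                                 dsg_drug_seq = 1L, start_dt = rec(start_dt))
  indi <- data.table::data.table(primaryid = as.character(primaryid),
                                 indi_drug_seq = 1L, indi_pt = rec(indi_pt))
  outc <- if (is.null(outc)) {
    data.table::data.table(primaryid = character(0), outc_cod = character(0))
  } else {
    data.table::as.data.table(outc)
  }
  assemble_reports(list(demo = demo, drug = drug, reac = reac, outc = outc,
                        ther = ther, indi = indi))
}

# Cohort whose tocilizumab DILI case strata equal the published descriptive
# table: 192 cases; age bands 20/58/21/11/2/80, sex 25/89/78,
# occupation 2/52/64/74, quarters 13/29/23/20/53/25/29,
# regions 2/22/102/53/13, outcomes over 175 outcome-bearing reports
# CA 0 / DE 30 / DS 1 / HO 27 / LT 6 / OT 137 / RI 2.
make_descriptive_cohort <- function() {
  n <- 192
  pid <- sprintf("T%05d1", seq_len(n))
  age <- rep(c(30, 50, 70, 80, 90, NA), c(20, 58, 21, 11, 2, 80))
  sex <- rep(c("F", "M", NA), c(25, 89, 78))
  occp <- rep(c("CN", "PH", "MD", NA), c(2, 52, 64, 74))
  fda <- rep(c("20200515", "20200815", "20201115", "20210215", "20210515",
               "20210815", "20211115"), c(13, 29, 23, 20, 53, 25, 29))
  country <- rep(c("ZA", "JP", "FR", "US", "BR"), c(2, 22, 102, 53, 13))
  # 175 outcome-bearing reports; one primary code each, then 28 second codes
  outc <- data.table::data.table(
    primaryid = c(pid[1:137], pid[138:167], pid[168:174], pid[175],
                  pid[1:20], pid[21:25], pid[26], pid[27:28]),
    outc_cod = c(rep("OT", 137), rep("DE", 30), rep("HO", 7), "LT",
                 rep("HO", 20), rep("LT", 5), "DS", rep("RI", 2)))
  reports <- make_reports(pid, age = age,
                          age_cod = ifelse(is.na(age), NA, "YR"),
                          sex = sex, occp_cod = occp, country = country,
                          fda_dt = fda, outc = outc)
  build_cohort(reports)
}
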