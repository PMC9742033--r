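---
title: "Methods: disproportionality screening for drug-induced liver injury"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: disproportionality screening for drug-induced liver injury}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pvdili)
```

## The problem and the data model

Spontaneous reporting systems such as FAERS collect voluntarily submitted
adverse-event reports. They have no exposure denominators, so absolute risks
cannot be estimated; instead, *disproportionality analysis* asks whether a
drug/event pair is reported more often than the background of all other
reports would suggest. `pvdili` implements that screen for drug-induced
liver injury (DILI) under the IL-6 receptor antagonists used in COVID-19,
on the modern (post-2012, PRIMARYID-era) public quarterly dialect: one
dollar-delimited file per table (DEMO, DRUG, REAC, OUTC, THER, INDI), header
row, UTF-8 with undecodable bytes replaced. Malformed rows are rejected and
*counted* — never silently dropped — so selection-flow reports always add
up. Legacy ISR-era column aliases are out of scope.

### Deduplication

Cases are resubmitted as new versions. Exactly one report per case number
survives: highest `caseversion`, ties broken by latest FDA receipt date,
then by lexicographically largest `primaryid`. The rule is idempotent and
the output size always equals the number of distinct case identifiers; both
properties are enforced by fuzz tests.

### Case selection

* **Window**: reporting quarters 2020Q2–2021Q4 inclusive (configurable),
  derived from the FDA receipt date.
* **COVID-19 context**: a report qualifies if any indication term *or*
  reaction PT contains one of the keywords `COVID-19`, `2019-Ncov`,
  `SARS-Cov-2`, matched case-insensitively after stripping hyphens and
  spaces. Both fields are searched because COVID-19 is encoded variously as
  indication or coded event.
* **Exposure**: a report is exposed to a drug when any entry with a suspect
  role code (default `PS`/`SS`; concomitant and interacting entries are
  ignored) contains a dictionary synonym in `drugname` or `prod_ai`.
  Matching is case-insensitive and word-boundary-tolerant, so
  `"KEVZARA 200MG"` matches `kevzara` but `"XACTEMRAX"` does not match
  `actemra`. The shipped dictionary maps tocilizumab ↦ {tocilizumab,
  actemra, atlizumab, roactemra} and sarilumab ↦ {sarilumab, kevzara}.
* **Event definition**: DILI is an exact (case-insensitive) match of a
  reaction PT against a fixed 17-term MedDRA preferred-term list
  (`dili_terms()`). No substring matching, no MedDRA hierarchy or SMQ
  expansion — "Hepatic enzyme increased" does *not* qualify while "Hepatic
  enzyme abnormal" does, by design of the exact-list definition.

Non-exposed COVID-19 reports are retained: they are the comparator
universe. The published analysis never states its comparator explicitly and
its absolute cell counts cannot be reconstructed at desk scale, so the
package makes the universe explicit (the COVID-19 cohort itself, the
default) and validates the statistics by other means (below).

## The statistics and their numerical choices

With cells a, b, c, d, N = a+b+c+d and s = √(1/a+1/b+1/c+1/d):

ROR = ad/bc with 95% CI exp(ln ROR ∓ 1.96·s); PRR = (a/(a+b))/(c/(c+d))
with Pearson χ² (no Yates correction by default — a flag adds it); IC =
log₂(aN/((a+b)(a+c))); EBGM = aN/((a+b)(a+c)). IC and EBGM share one core
expression, so IC = log₂(EBGM) holds identically — a property test asserts
it on random tables.

Three choices deserve emphasis:

* **Bound form.** The implemented IC025 and EBGM05 are the multiplicative
  bounds exp(ln X − z·s) applied to the *point estimate* (z = 1.96 and
  1.64). This is not the conventional BCPNN credible interval or MGPS
  percentile; it is the formula this pipeline is validated against, and
  back-deriving s from a printed ROR/CI pair reproduces the reference
  IC025/EBGM05 values to the printed precision (the acceptance suite does
  exactly that). The multiplicative IC bound requires IC > 0; otherwise it
  is reported as `NA` with a warning. The conventional additive bound
  IC − 1.96·s/ln 2 (delta method on the log₂ scale) is available via
  `method = "additive"`.
* **No shrinkage.** EBGM here is the raw observed/expected reporting ratio.
  MGPS-style gamma-mixture shrinkage is deliberately not fitted; the
  documentation says so wherever EBGM appears, to avoid confusion with the
  shrunk estimator of the same name.
* **Constants and zero cells.** The literal constants 1.96/1.64 are used
  (not qnorm quantiles), matching the published formulas to machine
  precision. Zero cells are an error under the default `strict` policy;
  `haldane` adds 0.5 to every cell. The table-level report
  (`signal_table()`) degrades degenerate rows to `NA` statistics instead of
  aborting, so an empty cohort still yields an explicit, well-formed bundle.

Signal criteria: ROR CI lower bound > 1 & a ≥ 2; PRR ≥ 2 & χ² ≥ 4 & a ≥ 3;
IC025 > 0; EBGM05 > 2 & a > 0. No multiplicity correction is applied across
pairs (none is applied in the analysis this mirrors).

## Descriptive tables, onset and outcomes

Percentages are rounded half-up to two decimals (`round_half_up`), because
banker's rounding visibly disagrees on exact halves (78/192 = 40.625% must
print 40.63%). Age uses the FAERS unit codes (DEC×10, YR, MON/12,
WK/52.1775, DY/365.25, HR/8766) and the bands <18, 18–44, 45–64, 65–74,
75–84, ≥85, Unknown; regions come from a shipped ISO-3166 → continent
table. Outcome codes are *not* a partition — one report may carry several —
so outcome percentages use the number of case reports with at least one
outcome code as denominator (the rule that reproduces the reference
descriptive table exactly; configurable to all-case denominators). One
reference cell (6/175) prints as 3.42% in the source material but is
arithmetically 3.43%; the package reports 3.43%.

Time-to-onset is event date minus the earliest day-precision therapy start
date of the matched suspect-drug entries. A report is excluded — with the
reason counted — when either date is absent, either has only month/year
precision (partial dates are anchored but never imputed), or the interval
is negative (an erroneous entry). Included plus excluded always equals the
candidate count. Onset summaries report median (midpoint convention for
even n), the true IQR *and* the min–max range, all labelled: reference
phrasing like "1 (IQR 0–46)" is read as a min–max range, since an IQR
spanning the full support with median 1 is implausible.

Between-group comparisons: two-tailed two-sample t-test (pooled variance by
default, Welch behind a flag), Kruskal–Wallis with tie correction for ≥ 3
groups, and for proportions an uncorrected Pearson χ² with Yates and Fisher
variants, all labelled — the reference analysis does not state which
variant produced its mortality p-value, so all three are reported.

## The synthetic generator: what it emulates and what it does not

The generator writes parseable quarterly files with: per-report
demographics with missing-completely-at-random gaps, one-to-many drug
entries with role codes and synonym/dosage-string name variation,
one-to-many reaction PTs, outcome codes, COVID-19 indications drawn
verbatim from the keyword list, duplicate case versions (same case number,
version 2, later receipt date), partial and missing dates, and planted
drug–event associations.

The planted association law works on the logit scale:
odds(event | exposures x) = odds_base · ∏ⱼ θⱼ^xⱼ, with odds_base solved by
root-finding so the configured marginal event probability is met. For a
single planted drug this makes the exposed/unexposed odds ratio *exactly*
θ. `expected_contingency()` computes expected cells by enumerating the
planted drugs' exposure combinations, so it is exact under the simulation
law and empirical-vs-expected tests need no approximation slack (checked at
n = 10⁵ within 3 standard errors). With two or more drugs planted on one
event set, each θ is the odds ratio conditional on non-exposure to the
others; at the default exposure probabilities the marginal attenuation is
negligible, and tests that assert exact θ recovery use single-drug configs.

Defaults state the emulated world: 20,000 reports in 2020Q2–2021Q4; target
exposure probabilities 0.12 (tocilizumab) and 0.015 (sarilumab) against a
3% DILI-set marginal, chosen so the expected co-occurrence counts land near
the reference study's scale (~90 cases each at the planted θ of 1.33 and
12.94); 90% COVID indications; 10% duplicates; ~40% missing age/sex
(matching the large "Unknown" strata such data show); 10% partial dates;
outcome profile proportional to the reference outcome counts; geometric
onset law with p = 0.3 (median 1 day, matching the reference median for
tocilizumab; geometric because its median, IQR and CDF have closed forms
for oracle tests). Outcome codes per report: one draw from the profile plus
a second distinct draw with probability 0.25, giving multi-outcome reports.

What the generator does **not** emulate: realistic marginal frequencies of
the thousands of real drugs and PTs, reporting heterogeneity over time,
correlated missingness, free-text noise beyond dosage suffixes, or
region-specific reporting cultures. A green end-to-end test therefore
establishes that the pipeline's logic is correct under the stated law — not
that the reference study's absolute counts are reproduced, which would
require the full external database.

Two scales are used deliberately in the test suite: replicate studies (CI
coverage over 500 null cohorts) draw the 2×2 cells directly from the
generator's exact marginal law (`sample_contingency`), while the per-report
path is validated once at n = 10⁵; this keeps the default suite around half
a minute without weakening what is established.

## Reproducibility

Every random quantity flows from the single integer seed in the
configuration; identical seeds give byte-identical files and bundles (an
asserted property). The study driver writes a provenance record (package
version, seed, window, roles, policies, dictionary) with every bundle, and
failure in any stage removes the partial bundle and names the stage.

## Known limitations

* Exact-PT event definition only; no MedDRA hierarchy, so terms coded at
  other levels are invisible.
* The comparator universe is the analysed cohort; whole-database
  comparators require parsing all quarters, which the IO layer supports but
  the driver does not orchestrate.
* Disproportionality is hypothesis-generating: no causality assessment
  (e.g. RUCAM), no confounding control, and reporting biases pass through
  untouched.
* The onset analysis uses therapy-record start dates only; the supported
  dialect's DRUG table has no start-date column to fall back on.
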