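---
title: "Methods: thromboembolic-event signal detection in FAERS-style report data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: thromboembolic-event signal detection in FAERS-style report data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(faerstee)
```

# The analysis in one paragraph

Spontaneous adverse-event reports for three antiangiogenic monoclonal
antibodies (bevacizumab, ramucirumab, aflibercept) are read from quarterly
`$`-delimited archives, collapsed to one report per case, filtered to
primary-suspect, intravenous-route, health-professional-reported cases,
and classified into thromboembolic event (TEE) categories by Preferred
Term (PT) lists. Each drug × event pair is then assessed for
disproportionate reporting against the full report background with the
reporting odds ratio (ROR) and the Bayesian information component (IC);
time to onset is summarised and compared nonparametrically; and fatal
outcome is modelled by multivariable logistic regression on TEE exposure.
Everything is exercisable end to end on a synthetic archive generator
with planted, closed-form ground truth.

# Data model and ingestion

FAERS quarterly archives are six `$`-delimited tables (DEMO, DRUG, REAC,
OUTC, THER, INDI) keyed by PRIMARYID (post-2012Q3) or ISR (legacy).
Both dialects are parsed; legacy key columns (ISR, CASE, GNDR_COD,
OCC_COD) are renamed onto the modern schema at assembly so downstream
code sees one shape. Data lines whose field count disagrees with the
header, child rows with no matching DEMO row, and reports with an empty
case id are written to a structured rejects log rather than dropped —
every count in the outputs can be audited against that log.

Dates arrive as digit strings of length 8, 6 or 4 and are modelled as
*partial dates* (year/month/day plus a precision level). Parsing is
total: malformed or impossible tokens (month 13, Feb 30) map to
`precision = "none"` rather than erroring, because such inputs are
ordinary in this data.

**Deduplication.** FAERS distributes successive versions of a case across
quarters. Following the FDA-recommended rule the key is CASEID alone:
the version with the latest FDA_DT survives, ties broken by the
numerically largest PRIMARYID. We deliberately do not attempt
multi-field clinical-duplicate heuristics (same patient reported by two
manufacturers, etc.); they are heuristic, irreproducible across
implementations, and not what the selection rule here claims to do.

**Age conversion.** AGE_COD units are converted to years with
DEC×10, YR×1, MON÷12, WK÷52.14, DY÷365.25, HR÷8766 — the 365.25-day-year
conventions, kept in one named constant. Ages ≥150 years are treated as
input errors and set missing.

# Event dictionary

TEE categories are three disjoint top-level PT sets — VTE, ATE, and
unspecified/mixed — mirroring the embolic and thrombotic events SMQ,
with subtypes PE ⊆ VTE and MI, cerebral-ATE ⊆ ATE, and overall TEE
derived as the union. MedDRA is licensed, so PT membership is user
configuration (YAML); the bundled dictionary
(`inst/extdata/tee_dictionary_synthetic.yaml`) is a small hand-written
stand-in for tests and examples, not an SMQ export. Matching is exact
string equality on upper-cased PTs — REAC rows are already PT-coded, so
fuzzy matching would only add false positives. A report with both VTE
and ATE PTs counts once in each category and once in overall TEE;
within a label a report counts once no matter how many of its PTs match.

# Cohort construction

A report enters a drug cohort iff (i) some drug entry matches the drug's
synonym table (case-insensitive containment on verbatim name or active
ingredient; defaults cover ingredient + brand for the three mAbs) with
role code PS, (ii) that entry's route class is admitted — by default only
routes whose normalised form starts with INTRAVENOUS; INTRAVITREAL /
OPHTHALMIC / INTRAOCULAR map to an intraocular class and blank routes to
"unspecified", both excluded unless asked for (this is what keeps
intraocular bevacizumab/aflibercept use out), (iii) the reporter is a
health professional — default {physician, pharmacist, other health
professional}; RN-coded reporters are not included in the default because
their mapping across quarters is inconsistent, and the filter is
configurable, and (iv) the event date, when available, falls in the
study window. The study window itself is configuration: the source
analyses state both "to 2024Q2" and "to 2024Q3" in different places, and
the package takes no side.

Treatment strategy is classified from co-reported drugs (roles SS/C/I):
any match in a configured chemotherapy ingredient list gives
"plus_chemotherapy", otherwise a match in a non-chemo antineoplastic
list gives "other_combined", otherwise "monotherapy". Indication groups
are a configured pattern map over INDI PTs (colorectal, NSCLC,
gastroesophageal, ovarian, glioblastoma, other, unknown).

In the descriptive summary, percentages use the full cohort as
denominator, except the onset block, which is computed over reports
with an evaluable onset and reports that "available n" alongside — the
convention of clinical characteristics tables. Percentages are rounded
half-up to one decimal; half-up (not banker's) so that printed cells
match hand arithmetic.

# Disproportionality statistics

For the 2×2 table (a, b, c, d) with N = a+b+c+d:

* ROR = ad/bc with 95% CI exp(ln ROR ± 1.96·√(1/a+1/b+1/c+1/d)).
  **Zero-cell policy:** the Haldane–Anscombe correction (+0.5 to all four
  cells) is applied only when some cell is zero, and only for the ROR —
  so point estimates on non-degenerate tables are exactly ad/bc, and the
  IC (which carries its own +0.5 shrinkage) is never double-corrected.
  With the correction disabled, a degenerate table is flagged
  non-evaluable instead of propagating NaN.
* IC = log₂((a+0.5)/(E+0.5)), E = (a+b)(a+c)/N. The default 95% interval
  is the closed-form shrinkage approximation
  (lower = IC − 3.3(a+0.5)^−1/2 − 2(a+0.5)^−3/2,
  upper = IC + 2.4(a+0.5)^−1/2 − 0.5(a+0.5)^−3/2), isolated behind one
  function; `method = "gamma"` swaps in 2.5/97.5% quantiles of
  log₂ Gamma(a+0.5, E+0.5). The shared +0.5 offset makes IC > 0 ⇔ a > E
  exactly, which the tests assert as an invariant.
* Evaluation requires a ≥ 3 reports; a *signal* additionally requires
  ROR CI lower bound > 1 and IC interval lower bound > 0. No multiple
  testing adjustment is applied across categories or PTs, matching
  standard pharmacovigilance practice for these thresholds; PT-level
  scans must therefore be read as hypothesis-generating.

**The comparison universe** for full-database analyses is every
deduplicated report in the ingested window restricted to the same
reporter qualifications as the drug cohorts — mirroring the cohorts'
provenance, since whether the original background included consumer
reports is not stated; the restriction is a parameter of
`label_universe()`. A report eligible for two study cohorts would be
ambiguous and is excluded with a log entry. Head-to-head comparisons
restrict the table to the two cohorts (a/b from A, c/d from B) with the
same estimators and thresholds.

# Time to onset

Onset = EVENT_DT − therapy START_DT of the primary-suspect drug entry
(earliest start when several episodes exist), in whole days, computed
only when both dates have full day precision and the interval is
non-negative; otherwise the report is excluded with reason
missing / partial_precision / negative_interval. Exclusion, not
imputation, is the default (an optional first-of-month imputation mode
exists but is off): truncated dates are indistinguishable from input
errors here, and the bins are coarse enough that the loss of power is the
lesser evil.

Bins are the closed integer ranges 0–30, 31–60, 61–90, 91–180, 181–365,
>365 days. Median uses the midpoint-of-middle-two convention; quartiles
default to the standard linear-interpolation sample quantile (type 7),
with Tukey inclusive hinges as a config switch — the source tables do not
state a convention, so it is exposed rather than guessed.

The Mann-Whitney U statistic counts pairs (x, y) with x > y (ties ½),
i.e. U = R_x − n_x(n_x+1)/2 from midranks. For both groups ≤ 8 the
two-sided p comes from exact enumeration of all rank assignments
(conditional on observed ties); above that, a normal approximation with
tie-corrected variance and continuity correction. The switch at 8 is
deterministic and documented rather than adaptive. Kruskal-Wallis uses
midranks with the tie-correction divisor 1 − Σ(t³−t)/(N³−N) and a
χ²(k−1) tail; with everything tied the statistic is defined as 0 and
p = 1. Both implementations are cross-checked in the tests against
`wilcox.test` and `kruskal.test` as independent oracles.

Cumulative-incidence curves are per-group empirical CDFs of observed
events — every curve ends at 100%. There is no censoring model and no
Kaplan–Meier machinery: spontaneous reports carry no time-at-risk, so a
survival estimate would claim more than the data support.

# Mortality model

Fatal outcome (outcome code DE) is regressed on TEE exposure (any
overall-TEE label) with covariates sex, age group and drug by logistic
regression, fitted with iteratively reweighted least squares:
convergence when the maximum absolute score < 10⁻⁸ or the relative
log-likelihood change < 10⁻¹⁰, cap 100 iterations, with step-halving so
the log-likelihood is monotone (asserted by a test). Wald standard
errors come from the inverse observed information; intervals are
symmetric on the log scale, reported as adjusted odds ratios. Complete
separation (fitted probability within 10⁻⁸ of 0/1 with a diverging
coefficient) flags the fit non-converged and suppresses odds ratios
rather than reporting garbage.

Unknown sex and age are retained as explicit factor levels by default:
dropping them would shrink the cohorts materially and bias toward
well-documented reports; a complete-case switch exists. Reference
levels are exposure = FALSE, sex = M, age = 18–64, drug = bevacizumab.
The choice affects per-level odds ratios only; the invariance of the
exposure aOR to reference choice is tested. Per-drug strata and
indication subgroups adjust for sex and age only (drug fixed); strata
without outcome variation are emitted flagged "not estimable" rather
than dropped. As with the signal scan, no multiplicity adjustment is
applied across subgroups.

# The synthetic archive generator

`generate_faers()` emits modern-dialect quarterly files with per-report
sampling in a fixed causal order: drug assignment → per-PT event
sampling → fatal outcome → onset → then duplication, date truncation and
missingness applied last, so the pre-corruption truth is recorded
exactly. Identical (config, seed) pairs produce byte-identical archives.

Planted effects are *odds multipliers on event probability given drug*,
so the implied true ROR of any planted signal is computable in closed
form from the config (`planted_truth()`); recovery tests compare
estimates to those expected cells, never to the nominal multiplier —
which keeps them exact rather than circular. Duplicates are emitted as
later-quarter versions with advanced FDA_DT so the dedup rule is
genuinely exercised. Legacy-dialect parsing is covered by small static
fixtures instead; the generator writes the modern dialect only.

Defaults encode the study conditions: drug report-volume weights
proportional to 92,055 : 2,814 : 2,455 (the published cohort sizes)
against an 80% background; onset log-normals with medians 60.5 / 26.5 /
31.5 days and dispersions σ = 1.47 / 1.27 / 1.91 back-computed from the
published IQRs via σ = ln(Q3/Q1)/(2·0.6745); baseline fatal probability
0.253 with exposure fatal-odds multiplier 1.19; sex/age margins and
indication mixes from the published characteristics table; reporter mix
with ~82% health professionals; and planted category multipliers in the
range of the published drug-level RORs (2.2–2.5 for VTE, 1.35–2.2 for
ATE). Values the source does not state (background PT frequencies, route
mix, reporting delay 3–60 days) were chosen once as field-plausible and
are not tuned.

What the generator does **not** emulate: real MedDRA term frequencies,
drug co-reporting structure beyond a single optional chemotherapy
co-drug, reporting-volume trends over time, or correlated missingness.
Passing tests therefore demonstrate correctness of the machinery and
calibration of the estimators under the stated statistical structure —
not performance on real FAERS idiosyncrasies.

# Verification design and problem sizes

The test suite checks, among others: ROR against the closed-form odds
ratio over all 810,000 tables with cells 1–30; interval calibration
under multinomial independence (2,000 replicates at N = 10⁵: 95% ROR CI
covers 1 in ≥93%, dual-threshold false-signal rate ≤5% plus Monte-Carlo
margin); and end-to-end parameter recovery from generated archives of
10⁵ reports.

The recovery studies deliberately set study-drug routes to 100%
intravenous and all reporters to health professionals. With the default
route/reporter mixes, study-drug reports excluded by the cohort filters
fall into the comparator arm of the 2×2 table still carrying their
boosted event odds, attenuating the measured ROR below the planted
multiplier — a property of the design, not an estimator error. Making
cohort membership coincide with drug assignment isolates what the
recovery test is meant to measure. The fatal-odds recovery additionally
triples background TEE reporting probabilities so the exposed count
supports a [1.1, 1.3] band around a planted odds multiplier of 1.2.

Routine tests run on archives of 1,000–20,000 reports; the two
10⁵-report recovery archives are the largest objects built, and the
whole suite completes in about a minute on one CPU. The same quantities
are recomputed from scratch by `scripts/acceptance.R`.

# Known limitations

Disproportionality measures are reporting associations, not risks;
deduplication by case id cannot merge true clinical duplicates filed
under different cases; exact-date onset analysis discards a substantial
fraction of reports and may not be missing at random; the fatal flag is
all-cause within the report, not cause-specific death; and the bundled
dictionary is illustrative — real analyses require licensed
MedDRA-derived PT lists and the real archives.
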