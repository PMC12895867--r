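# faerstee

Pharmacovigilance analysis of thromboembolic events (TEEs) under
antiangiogenic monoclonal antibodies — bevacizumab, ramucirumab and
aflibercept — in spontaneous adverse-event report data distributed in the
FAERS quarterly ASCII dialect. The package is aimed at drug-safety
analysts who want the whole chain — ingestion, deduplication, event
classification, disproportionality statistics, time-to-onset analysis and
a mortality model — as tested, reusable functions rather than ad-hoc SQL,
plus a synthetic archive generator so every step can be validated against
known ground truth without downloading FAERS.

## What it computes

Each drug–event pair is summarised by the 2×2 report table (a = drug ∧
event, b = drug ∧ other events, c = other drugs ∧ event, d = neither) and
assessed with two disproportionality measures:

* **Reporting odds ratio** — ROR = ad/bc, with the 95% CI
  exp(ln ROR ± 1.96·√(1/a + 1/b + 1/c + 1/d)); the Haldane–Anscombe
  correction (+0.5 to all cells) is applied only when a cell is zero.
* **Information component** — IC = log₂((a + 0.5)/(E + 0.5)) with
  E = (a+b)(a+c)/N, with a closed-form shrinkage credibility interval
  (a gamma-posterior quantile interval is available as an option).

A *signal of disproportionate reporting* requires at least 3 reports, ROR
CI lower bound > 1 **and** IC interval lower bound > 0. No
multiple-testing adjustment is applied across events or PTs — deliberate,
and worth keeping in mind when reading PT-level scans.

Around the estimators sit: FDA-rule deduplication (latest FDA_DT per
CASEID, ties to the largest PRIMARYID), PT classification into VTE / ATE /
unspecified-mixed categories with PE / MI / cerebral-ATE subtypes from a
user-supplied dictionary (MedDRA is licensed; a synthetic fixture ships
for tests), cohort filters (primary suspect, intravenous route,
health-professional reporters), time-to-onset statistics with
Mann-Whitney / Kruskal-Wallis comparisons, and an IRLS logistic model of
fatal outcome on TEE exposure adjusted for sex, age group and drug,
reported as adjusted odds ratios.

## Worked example

Simulate a 20,000-report archive with planted disproportionality, run the
full pipeline, and look at the drug-level signal table:

```r
library(faerstee)
res <- run_pipeline(run_config("results/demo", seed = 42,
                               simulate = list(n_reports = 20000L,
                                               duplicate_rate = 0.1)))
res$signals[signal == TRUE, .(drug, event, n_obs, ror, ror_lower, ic_lower)]
```

```
          drug             event n_obs      ror ror_lower   ic_lower
1: bevacizumab               VTE    85 1.751665  1.361161 0.25167775
2: bevacizumab unspecified_mixed    36 1.703256  1.160622 0.02859609
3: bevacizumab       overall_TEE   172 1.526511  1.279344 0.20575861
```

n_obs is the deduplicated report count in the a-cell; a row is flagged
only when both interval bounds clear their thresholds. At this scale only
the largest cohort (bevacizumab, ~2,900 eligible reports) has the counts
to flag its planted VTE multiplier of 2.5; the theoretical RORs implied
by the generator config are available in closed form via
`planted_truth()`. The same run writes Table-1-style descriptive
summaries, PT-level scans, head-to-head comparisons, onset tests and the
mortality forest table under `results/demo/`.

The `analysis/` directory holds the same workflow as six numbered
narrative scripts (`01_simulate.R` … `06_outcomes.R`), each a thin driver
over the package that prints what it found and writes its tables under
`results/`.

## Limitations

Spontaneous-report data support signal detection, not incidence or
causal inference; the bundled dictionary is an illustrative stand-in, and
real analyses need MedDRA-derived PT lists and real FAERS archives. See
the methods vignette (`vignettes/faers-tee-methods.Rmd`) for the model
assumptions, parameter choices and design decisions.
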