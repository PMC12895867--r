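#!/usr/bin/env Rscript
# Stage 4 — disproportionality analysis.
#
# Builds the labelled comparison universe (all deduplicated
# health-professional reports), computes ROR and IC with 95% intervals
# for every drug x event category against the full database, scans
# individual PTs per drug, and runs the pairwise head-to-head
# comparisons. A signal requires >= 3 reports, ROR CI lower bound > 1 and
# IC interval lower bound > 0.

suppressMessages(library(faerstee))
suppressMessages(library(data.table))

tabs <- read_faers_archive("results/archive")
reports <- deduplicate(assemble_reports(tabs))
dict <- load_event_dictionary(example_dictionary_path())
drugs <- c("bevacizumab", "ramucirumab", "aflibercept")
cohorts <- lapply(setNames(nm = drugs),
                  function(dg) select_cohort(reports, cohort_spec(dg), dict))
universe <- label_universe(reports, dict, cohorts)
print(universe)

sig <- signal_table(universe)
fwrite(sig, "results/table2_signals.tsv", sep = "\t")
cat(sprintf("Wrote results/table2_signals.tsv; %d of %d pairs flagged:\n",
            sum(sig$signal), nrow(sig)))
print(sig[signal == TRUE,
          .(drug, event, n_obs, ror = round(ror, 2),
            ror_ci = sprintf("%.2f-%.2f", ror_lower, ror_upper),
            ic = round(ic, 2), ic025 = round(ic_lower, 2))])

scans <- rbindlist(lapply(drugs, function(dg) {
  sc <- pt_level_scan(universe, dg)
  if (nrow(sc)) sc[, drug := dg] else sc
}), fill = TRUE)
fwrite(scans, "results/fig2_pt_scan.tsv", sep = "\t")
cat(sprintf("PT-level scan: %s significant PTs\n",
            paste(sprintf("%s=%d", drugs, vapply(drugs, function(d)
              sum(scans[drug == d, signal]), 0L)), collapse = " ")))

hh <- rbindlist(lapply(utils::combn(drugs, 2, simplify = FALSE), function(p) {
  cbind(data.table(drugA = p[1], drugB = p[2]),
        head_to_head(cohorts[[p[1]]], cohorts[[p[2]]], "overall_TEE"))
}))
fwrite(hh, "results/head_to_head.tsv", sep = "\t")
cat("Head-to-head (overall TEE):\n")
print(hh[, .(drugA, drugB, ror = round(ror, 2),
             ci = sprintf("%.2f-%.2f", ror_lower, ror_upper), signal)])
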