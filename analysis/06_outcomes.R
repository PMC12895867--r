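#!/usr/bin/env Rscript
# Stage 6 — mortality model.
#
# Multivariable logistic regression of fatal outcome on thromboembolic
# exposure (any TEE label) adjusted for sex, age group and drug, with
# per-drug strata and bevacizumab indication subgroups adjusted for sex
# and age. Emits the forest-plot-ready table.

suppressMessages(library(faerstee))
suppressMessages(library(data.table))

tabs <- read_faers_archive("results/archive")
reports <- deduplicate(assemble_reports(tabs))
dict <- load_event_dictionary(example_dictionary_path())
drugs <- c("bevacizumab", "ramucirumab", "aflibercept")
rows <- rbindlist(lapply(drugs, function(dg)
  select_cohort(reports, cohort_spec(dg), dict)))

ft <- mortality_association(
  rows, subgroups = list(bevacizumab = c("colorectal", "nsclc", "ovarian",
                                         "glioblastoma")))
fwrite(ft, "results/fig3_forest.tsv", sep = "\t")
cat("Wrote results/fig3_forest.tsv\n")
print(ft[, .(stratum, n, fatal_pct_exposed, fatal_pct_unexposed,
             aOR = round(aOR, 2),
             ci = ifelse(estimable, sprintf("%.2f-%.2f", aOR_lower,
                                            aOR_upper), "-"),
             p = signif(p_value, 3), estimable)])

ov <- ft[stratum == "overall"]
if (ov$estimable) {
  cat(sprintf(paste0("Overall: fatal %.1f%% with TEE vs %.1f%% without; ",
                     "aOR %.2f (%.2f-%.2f), p = %.3g\n"),
              ov$fatal_pct_exposed, ov$fatal_pct_unexposed, ov$aOR,
              ov$aOR_lower, ov$aOR_upper, ov$p_value))
}
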