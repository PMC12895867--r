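#!/usr/bin/env Rscript
# Stage 3 — select the drug cohorts and produce the descriptive summary.
#
# Applies the report-selection filters (primary suspect, intravenous
# route, health-professional reporter) for each study drug, classifies
# thromboembolic events with the bundled dictionary, and writes the
# characteristics table (sex, age, outcome, indication, treatment
# strategy, onset bins, median/IQR) to results/table1_summary.tsv.

suppressMessages(library(faerstee))
suppressMessages(library(data.table))

tabs <- read_faers_archive("results/archive")
reports <- deduplicate(assemble_reports(tabs))
dict <- load_event_dictionary(example_dictionary_path())

drugs <- c("bevacizumab", "ramucirumab", "aflibercept")
cohorts <- lapply(setNames(nm = drugs),
                  function(dg) select_cohort(reports, cohort_spec(dg), dict))
rows <- rbindlist(cohorts)
cat(sprintf("Cohort sizes: %s\n",
            paste(sprintf("%s=%d", drugs, vapply(cohorts, nrow, 0L)),
                  collapse = " ")))
tee <- rows[overall_TEE == TRUE]
cat(sprintf("Thromboembolic-event reports: %d (%s)\n", nrow(tee),
            paste(sprintf("%s=%d", drugs,
                          vapply(drugs, function(d) nrow(tee[drug == d]), 0L)),
                  collapse = " ")))

s <- descriptive_summary(rows)
fwrite(s, "results/table1_summary.tsv", sep = "\t")
cat("Wrote results/table1_summary.tsv\n")
for (dg in drugs) {
  m <- s[drug == dg & block == "onset_stats"]
  cat(sprintf("  %s: fatal %.1f%%; onset median %g days (IQR %g-%g)\n", dg,
              s[drug == dg & block == "outcome" & level == "fatal", pct],
              m[level == "median", n], m[level == "q1", n],
              m[level == "q3", n]))
}
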