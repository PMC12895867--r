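#!/usr/bin/env Rscript
# Stage 1 — generate the synthetic FAERS-style study archive.
#
# Emits quarterly $-delimited DEMO/DRUG/REAC/OUTC/THER/INDI files under
# results/archive/ with known ground truth. The configuration mirrors the
# study conditions: three antiangiogenic mAbs against a dominant background,
# planted disproportionality on the thromboembolic categories, fatal-odds
# multiplier 1.19 on TEE exposure, per-drug onset medians 60.5/26.5/31.5
# days, 10% duplicated cases and 10% truncated dates.

suppressMessages(library(faerstee))

seed <- 42L
out <- "results/archive"
unlink(out, recursive = TRUE)

cfg <- default_sim_config(seed = seed, n_reports = 20000L)
cfg$duplicate_rate <- 0.10
cfg$partial_date_rate <- 0.10

gen <- generate_faers(cfg, out)
cat(sprintf("Wrote archive for %d cases (%d emitted report versions) to %s\n",
            nrow(gen$cases), nrow(gen$cases) + sum(gen$cases$n_versions == 2L),
            out))
elig <- table(gen$cases[eligible == TRUE, drug])
cat(sprintf("Truly eligible (IV route, health-professional, PS): %s\n",
            paste(sprintf("%s=%d", names(elig), as.integer(elig)),
                  collapse = " ")))
cat("Planted theoretical RORs (vs all other drugs):\n")
print(gen$truth[drug != "background" & label %in%
                  c("VTE", "ATE", "overall_TEE"),
                .(drug, label, p_event = round(p_event, 4),
                  true_ror = round(true_ror, 2))])
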