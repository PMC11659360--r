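#!/usr/bin/env Rscript
# Step 1 — generate the paired synthetic studies used by the workflow.
#
# Two studies are written under results/:
#   study_default/   the atlas-like conditions: 50 clusters, a rare gene A
#                    (~0.4% of cells) vs a ~100x more prevalent gene B,
#                    co-expression enrichment (odds 4), 20 structures with
#                    partial coverage on four of them, noisy literature
#                    references;
#   study_recovery/  the validation conditions: explicit moderate rates,
#                    exactly 200 deep cells in each of 50 clusters, full
#                    coverage, noise-free references — every error source
#                    is known, so downstream steps can be checked against
#                    ground truth.

library(coexatlas)

cfg_default <- sim_config(seed = 1)
study_default <- simulate_paired(cfg_default)
write_study(study_default, "results/study_default")

cfg_recovery <- recovery_config(seed = 1)
study_recovery <- simulate_paired(cfg_recovery)
write_study(study_recovery, "results/study_recovery")

for (nm in c("default", "recovery")) {
  st <- get(paste0("study_", nm))
  message(sprintf(
    "[%s] deep: %d cells / %d clusters; spatial: %d cells / %d structures",
    nm, ncol(st$deep$dataset$counts), nrow(st$taxonomy),
    nrow(st$spatial$cells), nrow(st$spatial$structures)))
}
message("studies written to results/study_default and results/study_recovery")
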