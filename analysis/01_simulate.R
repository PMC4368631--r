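#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study — 3 histone marks + input,
# 2 patients vs 4 controls, promoter-localized signal with implanted
# silenced/active archetypes — and write it under results/data/.

source("analysis/00_config.R")

cfg <- analysis_sim_config()
ds <- simulate_dataset(cfg, "results/data")

truth <- ds$truth
cat("Simulated", nrow(ds$genome$genes), "genes on",
    length(ds$genome$chrom_sizes), "chromosomes;",
    length(ds$files), "BED libraries written to results/data/\n")
print(table(truth$archetype))
cat("Implanted |log2 effect| = 2 archetypes; ground truth in",
    "results/data/truth.tsv\n")
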