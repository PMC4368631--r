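# Shared configuration for the numbered analysis stages: one simulated
# study (3 marks + input, 2 patients vs 4 controls) analyzed end-to-end.
# Sourced, not run.

suppressPackageStartupMessages(library(promdiff))

analysis_sim_config <- function() {
  simulation_config(n_chroms = 2, chrom_length = 4e5, n_genes = 300,
                    library_size = 4e4,
                    archetype_fractions = c(silenced = 0.05, active = 0.05),
                    seed = 42)
}
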