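#!/usr/bin/env Rscript
# Stage 3: count deduplicated reads whose 5' base falls in each TSS +/- 1 kb
# promoter window; one genes x samples matrix per mark.

source("analysis/00_config.R")

cfg <- analysis_sim_config()
sizes <- read_chrom_sizes("results/data/chrom.sizes")
genes <- read_annotation("results/data/annotation.tsv")
windows <- promoter_windows(genes, chrom_sizes = sizes)
groups <- sample_groups(cfg)
dir.create("results/counts", recursive = TRUE, showWarnings = FALSE)

for (mk in cfg$marks) {
  vecs <- lapply(stats::setNames(sample_ids(cfg), sample_ids(cfg)),
                 function(sid) {
    rd <- deduplicate_reads(read_bed_reads(
      sprintf("results/data/%s_%s.bed", sid, mk)))
    count_reads_in_windows(rd, windows, mode = "read_5prime")
  })
  pcm <- assemble_count_matrix(vecs, mk, groups)
  write_count_matrix(pcm, sprintf("results/counts/counts_%s.tsv", mk))
  cat(sprintf("%s: %d x %d count matrix; in-window read fraction %.2f\n",
              mk, nrow(pcm$counts), ncol(pcm$counts),
              sum(pcm$counts) / sum(vapply(sample_ids(cfg), function(sid)
                nrow(read_bed_reads(sprintf("results/data/%s_%s.bed",
                                            sid, mk))), 1))))
}
cat("Count matrices written to results/counts/\n")
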