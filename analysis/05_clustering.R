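#!/usr/bin/env Rscript
# Stage 5: complete-linkage hierarchical clustering of the selected genes
# on their 3-mark log2 fold-change vectors, phenotype labels per cluster,
# and the z-scaled heatmap matrix.

source("analysis/00_config.R")

cfg <- analysis_sim_config()
dir.create("results/clusters", recursive = TRUE, showWarnings = FALSE)

tables <- lapply(stats::setNames(cfg$marks, cfg$marks), function(mk) {
  utils::read.table(sprintf("results/diff/diff_%s.tsv", mk), header = TRUE,
                    sep = "\t", stringsAsFactors = FALSE)
})
sel <- utils::read.table("results/diff/significance.tsv", header = TRUE,
                         sep = "\t", stringsAsFactors = FALSE)

fc <- fold_change_matrix(tables, sel)
dend <- hier_cluster(fc)           # Euclidean distance, complete linkage
asg <- cut_clusters(dend, k = 4)
sm <- cluster_summary(asg, fc)
asg$phenotype <- sm$phenotype[match(asg$cluster, sm$cluster)]
utils::write.table(asg, "results/clusters/assignment.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
utils::write.table(sm, "results/clusters/summary.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)

# z-scaled, group-averaged counts for the heatmap rows
heat <- list(gene_id = rownames(fc))
for (mk in cfg$marks) {
  pcm <- read_count_matrix(sprintf("results/counts/counts_%s.tsv", mk), mk)
  gz <- group_average_z(zscale_counts(pcm)[rownames(fc), , drop = FALSE],
                        pcm$groups)
  heat[[paste0(mk, "_patient")]] <- gz[, "patient"]
  heat[[paste0(mk, "_control")]] <- gz[, "control"]
}
utils::write.table(as.data.frame(heat), "results/clusters/heatmap.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)

cat(sprintf("Clustered %d selected genes into %d clusters:\n", nrow(fc),
            nrow(sm)))
print(sm, digits = 3)

truth <- utils::read.table("results/data/truth.tsv", header = TRUE,
                           sep = "\t", stringsAsFactors = FALSE)
for (ph in c("silenced", "active")) {
  implanted <- truth$gene_id[truth$archetype == ph]
  called <- asg$gene_id[asg$phenotype == ph]
  cat(sprintf("%s: %d/%d implanted genes recovered, %d false members\n",
              ph, length(intersect(called, implanted)), length(implanted),
              length(setdiff(called, implanted))))
}
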