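# Hierarchical clustering of significant promoters on their per-mark log2
# fold changes, z-scaled heatmap matrices, and chromatin-state phenotype
# labels for the resulting clusters.

#' Build the genes x marks log2 fold-change matrix for selected genes
#'
#' @param tables named list of per-mark differential tables.
#' @param selection data.frame from [select_significant()].
#' @return numeric matrix, rows = selected genes, columns = marks.
#' @export
fold_change_matrix <- function(tables, selection) {
  genes <- selection$gene_id[selection$selected]
  mat <- vapply(tables, function(tb) {
    tb$log2FC[match(genes, tb$gene_id)]
  }, numeric(length(genes)))
  mat <- matrix(mat, nrow = length(genes),
                dimnames = list(genes, names(tables)))
  if (any(!is.finite(mat))) stop("fold_change_matrix: non-finite log2FC")
  mat
}

#' Z-scale a count matrix by row
#'
#' Counts are size-factor normalized, then each row is centered and scaled
#' to unit standard deviation (n - 1 denominator); rows with zero standard
#' deviation become all-zero rather than NaN.
#'
#' @param pcm a `promoter_count_matrix` (or plain matrix).
#' @param sf size factors; computed with [size_factors()] when missing.
#' @return numeric matrix of z-scores with the input's dimnames.
#' @export
zscale_counts <- function(pcm, sf = NULL) {
  counts <- if (inherits(pcm, "promoter_count_matrix")) pcm$counts else pcm
  stopifnot(ncol(counts) >= 2L)
  if (is.null(sf)) sf <- size_factors(counts)
  norm <- sweep(counts, 2L, sf, "/")
  mu <- rowMeans(norm)
  sd <- apply(norm, 1L, stats::sd)
  z <- (norm - mu) / ifelse(sd > 0, sd, 1)
  z[sd == 0, ] <- 0
  z
}

#' Average z-scores within patient and control groups
#'
#' Display helper for the heatmap export: per gene, the mean z-score over
#' the patient samples and over the control samples.
#'
#' @param z matrix from [zscale_counts()].
#' @param groups group label per column.
#' @return matrix with columns `patient`, `control`.
#' @export
group_average_z <- function(z, groups) {
  cbind(patient = rowMeans(z[, groups == "patient", drop = FALSE]),
        control = rowMeans(z[, groups == "control", drop = FALSE]))
}

#' Hierarchical clustering of a fold-change matrix
#'
#' Agglomerative clustering on the Euclidean distance matrix with complete
#' linkage (`D(A, B)` = maximum pairwise distance), via [stats::hclust()].
#'
#' @param mat numeric matrix, rows = genes.
#' @param distance distance metric (passed to [stats::dist()]).
#' @param linkage agglomeration method (passed to [stats::hclust()]).
#' @return an `hclust` object.
#' @export
hier_cluster <- function(mat, distance = "euclidean", linkage = "complete") {
  if (nrow(mat) < 2L) stop("hier_cluster: need at least 2 rows")
  if (any(!is.finite(mat))) stop("hier_cluster: non-finite values")
  stats::hclust(stats::dist(mat, method = distance), method = linkage)
}

#' Cut a dendrogram into k clusters
#'
#' Cluster ids are relabeled 1..k in leaf order (the order genes appear
#' along the dendrogram), so cluster 1 is always the leftmost.
#'
#' @param dend an `hclust` object from [hier_cluster()].
#' @param k number of clusters, `1 <= k <= n`.
#' @return data.frame with `gene_id` and `cluster`.
#' @export
cut_clusters <- function(dend, k) {
  n <- length(dend$order)
  if (k < 1L || k > n) stop("cut_clusters: k out of range [1, ", n, "]")
  raw <- stats::cutree(dend, k = k)
  leaf_first <- raw[dend$order]
  relabel <- stats::setNames(seq_len(k), unique(leaf_first))
  data.frame(gene_id = names(raw),
             cluster = unname(relabel[as.character(raw)]),
             stringsAsFactors = FALSE)
}

#' Label a cluster's chromatin-state phenotype
#'
#' With threshold t on per-mark mean log2 fold changes (patients vs
#' controls): `silenced` = active marks all <= -t and repressive marks all
#' >= +t; `active` = the mirror image; `poised_up` / `poised_down` = all
#' marks concordantly >= +t / <= -t; anything else is `mixed`.
#'
#' @param mean_lfc named numeric vector of per-mark mean log2FC.
#' @param active_marks,repressive_marks partition of the marks into roles.
#' @param magnitude_threshold t, in log2 units.
#' @return one of `"silenced"`, `"active"`, `"poised_up"`, `"poised_down"`,
#'   `"mixed"`.
#' @export
classify_cluster_phenotype <- function(mean_lfc,
                                       active_marks = c("H3K4me3", "H3K9ac"),
                                       repressive_marks = "H3K27me3",
                                       magnitude_threshold = 0.5) {
  marks <- names(mean_lfc)
  if (!setequal(marks, c(active_marks, repressive_marks)) ||
      length(intersect(active_marks, repressive_marks)))
    stop("classify_cluster_phenotype: every mark needs exactly one role")
  t <- magnitude_threshold
  act <- mean_lfc[active_marks]; rep_ <- mean_lfc[repressive_marks]
  if (all(act <= -t) && all(rep_ >= t)) return("silenced")
  if (all(act >= t) && all(rep_ <= -t)) return("active")
  if (all(mean_lfc >= t)) return("poised_up")
  if (all(mean_lfc <= -t)) return("poised_down")
  "mixed"
}

#' Summarize clusters: sizes, per-mark mean log2FC, phenotype labels
#'
#' @param assignment data.frame from [cut_clusters()].
#' @param fc_mat fold-change matrix (genes x marks) used for clustering.
#' @param active_marks,repressive_marks,magnitude_threshold passed to
#'   [classify_cluster_phenotype()].
#' @return data.frame with `cluster`, `size`, one `mean_lfc_<mark>` column
#'   per mark, and `phenotype`.
#' @export
cluster_summary <- function(assignment, fc_mat,
                            active_marks = c("H3K4me3", "H3K9ac"),
                            repressive_marks = "H3K27me3",
                            magnitude_threshold = 0.5) {
  ks <- sort(unique(assignment$cluster))
  rows <- lapply(ks, function(k) {
    genes <- assignment$gene_id[assignment$cluster == k]
    m <- colMeans(fc_mat[genes, , drop = FALSE])
    lab <- classify_cluster_phenotype(m, active_marks, repressive_marks,
                                      magnitude_threshold)
    out <- data.frame(cluster = k, size = length(genes))
    out[paste0("mean_lfc_", names(m))] <- as.list(unname(m))
    out$phenotype <- lab
    out
  })
  do.call(rbind, rows)
}

#' Per-cluster TSS meta-profiles, averaged within groups
#'
#' Restricts [meta_profile()] to the cluster's TSSs and averages the
#' per-sample profiles within the patient and control groups.
#'
#' @param cluster_genes character vector of gene ids in the cluster.
#' @param tracks named list of per-sample `coverage_track`s for one mark.
#' @param windows promoter windows (provides `gene_id`, `chrom`, `tss`,
#'   `strand`).
#' @param groups named character vector mapping sample id to group.
#' @param flank_bp,bin_bp passed to [meta_profile()].
#' @return data.frame with `bin_center`, `patient`, `control`.
#' @export
cluster_meta_profiles <- function(cluster_genes, tracks, windows, groups,
                                  flank_bp = 1000, bin_bp = 50) {
  if (length(cluster_genes) == 0L) stop("cluster_meta_profiles: empty cluster")
  tss <- windows[windows$gene_id %in% cluster_genes, , drop = FALSE]
  prof <- meta_profile(tracks, tss, flank_bp = flank_bp, bin_bp = bin_bp)
  sample_ids <- setdiff(names(prof), "bin_center")
  g <- groups[sample_ids]
  data.frame(bin_center = prof$bin_center,
             patient = rowMeans(prof[, sample_ids[g == "patient"], drop = FALSE]),
             control = rowMeans(prof[, sample_ids[g == "control"], drop = FALSE]))
}
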