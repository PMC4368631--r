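# Gene-set over-representation (hypergeometric, in place of an external
# annotation service) and distributional comparison of fold changes
# between a gene group and the background.

#' Hypergeometric over-representation of gene sets in a cluster
#'
#' For each set, with universe size N, set size K (after intersecting the
#' set with the universe), cluster size n and overlap x, the upper-tail
#' p-value is `P(X >= x)` for `X ~ Hypergeom(N, K, n)`. The cluster must be
#' a subset of the universe.
#'
#' @param cluster_genes character vector of cluster gene ids.
#' @param gene_sets named list from [read_gmt()] (or a named list of
#'   character vectors).
#' @param universe_genes character vector: all genes that could have been
#'   selected (here, all genes with a quantified promoter).
#' @param adjust also report Benjamini-Hochberg adjusted p-values.
#' @return data.frame sorted by p with columns `set`, `overlap`,
#'   `cluster_size`, `set_size`, `universe_size`, `pval`, `neglog10_p`
#'   (and `padj` when `adjust`).
#' @export
hypergeom_enrichment <- function(cluster_genes, gene_sets, universe_genes,
                                 adjust = TRUE) {
  universe_genes <- unique(universe_genes)
  cluster_genes <- unique(cluster_genes)
  if (length(universe_genes) == 0L) stop("hypergeom_enrichment: empty universe")
  if (length(cluster_genes) == 0L) stop("hypergeom_enrichment: empty cluster")
  if (!all(cluster_genes %in% universe_genes))
    stop("hypergeom_enrichment: cluster not a subset of the universe")
  N <- length(universe_genes); n <- length(cluster_genes)
  rows <- lapply(names(gene_sets), function(nm) {
    gs <- gene_sets[[nm]]
    genes <- if (is.list(gs)) gs$genes else gs
    genes <- intersect(unique(genes), universe_genes)
    K <- length(genes)
    x <- length(intersect(genes, cluster_genes))
    p <- stats::phyper(x - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(set = nm, overlap = x, cluster_size = n, set_size = K,
               universe_size = N, pval = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (adjust) out$padj <- bh_adjust(out$pval)
  out$neglog10_p <- -log10(out$pval)
  out[order(out$pval, out$set), , drop = FALSE]
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment with monotonicity enforcement
#' (via [stats::p.adjust()]), after validating the inputs are in [0, 1].
#'
#' @param pvalues numeric vector of raw p-values.
#' @return adjusted p-values, order-preserving.
#' @export
bh_adjust <- function(pvalues) {
  if (any(!is.finite(pvalues)) || any(pvalues < 0) || any(pvalues > 1))
    stop("bh_adjust: p-values must lie in [0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}

#' Mann-Whitney U comparison of a gene group against the background
#'
#' Two-sided two-sample Mann-Whitney U with mid-rank ties: exact p by
#' enumeration when `n1 * n2 <= 400` and the data are tie-free, otherwise
#' the normal approximation with tie and continuity correction (the
#' behavior of [stats::wilcox.test()]). Used to compare log2 fold changes
#' of a gene group (e.g. MHC genes) with all genes as background.
#'
#' @param group_values numeric vector (the gene group).
#' @param background_values numeric vector (the comparison population).
#' @return list with `test`, `U`, `pval`, `n1`, `n2`, `median1`, `median2`,
#'   `exact`.
#' @export
mannwhitney_compare <- function(group_values, background_values) {
  if (length(group_values) == 0L || length(background_values) == 0L)
    stop("mannwhitney_compare: empty sample")
  n1 <- length(group_values); n2 <- length(background_values)
  ties <- anyDuplicated(c(group_values, background_values)) > 0L
  exact <- (n1 * n2 <= 400) && !ties
  wt <- stats::wilcox.test(group_values, background_values,
                           alternative = "two.sided", exact = exact,
                           correct = TRUE)
  list(test = "Mann-Whitney U", U = unname(wt$statistic),
       pval = wt$p.value, n1 = n1, n2 = n2,
       median1 = stats::median(group_values),
       median2 = stats::median(background_values), exact = exact)
}

#' Paired t-test comparison (for paired designs)
#'
#' @param x,y paired numeric vectors of equal length.
#' @return list with `test`, `t`, `df`, `pval`, `mean_diff`.
#' @export
paired_t_compare <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2L)
  tt <- stats::t.test(x, y, paired = TRUE)
  list(test = "paired t", t = unname(tt$statistic),
       df = unname(tt$parameter), pval = tt$p.value,
       mean_diff = unname(tt$estimate))
}
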