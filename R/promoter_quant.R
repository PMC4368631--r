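# Strand-aware promoter windows around TSSs and gene x sample count
# matrices, one per histone mark.

#' Derive promoter windows around TSSs
#'
#' The TSS of a plus-strand gene is its txStart; for a minus-strand gene it
#' is `end - 1`, the 5'-most transcribed base under the half-open
#' convention. The default window spans 1 kb either side of the TSS:
#' a plus-strand TSS t gives `[t - upstream, t + downstream)` and a
#' minus-strand TSS t the mirror image `[t - downstream + 1, t + upstream + 1)`.
#' Windows are clipped to chromosome bounds.
#'
#' @param genes annotation data.frame from [read_annotation()].
#' @param upstream_bp,downstream_bp window extent in bp (not both 0).
#' @param chrom_sizes named vector of chromosome lengths.
#' @return data.frame with `gene_id`, `chrom`, `start`, `end`, `strand`,
#'   `tss`.
#' @export
promoter_windows <- function(genes, upstream_bp = 1000, downstream_bp = 1000,
                             chrom_sizes) {
  stopifnot(upstream_bp >= 0, downstream_bp >= 0,
            upstream_bp + downstream_bp > 0)
  unknown <- setdiff(unique(genes$chrom), names(chrom_sizes))
  if (length(unknown))
    stop("gene on unknown chromosome: ", paste(unknown, collapse = ", "))
  minus <- genes$strand == "-"
  tss <- ifelse(minus, genes$end - 1L, genes$start)
  start <- ifelse(minus, tss - downstream_bp + 1L, tss - upstream_bp)
  end <- ifelse(minus, tss + upstream_bp + 1L, tss + downstream_bp)
  start <- pmax(start, 0)
  end <- pmin(end, unname(chrom_sizes[genes$chrom]))
  data.frame(gene_id = genes$gene_id, chrom = genes$chrom,
             start = as.integer(start), end = as.integer(end),
             strand = genes$strand, tss = as.integer(tss),
             stringsAsFactors = FALSE)
}

#' Count reads (or fragments) in promoter windows
#'
#' In the default `read_5prime` mode a read is counted for a window iff its
#' 5' base lies in the half-open window — an unambiguous, strand-symmetric
#' rule. In `fragment_overlap` mode an interval is counted iff it overlaps
#' the window by at least 1 bp. Each read is counted at most once per
#' window; with overlapping windows a read may contribute to several genes.
#'
#' @param reads read data.frame (mode `read_5prime`, needs `strand`) or
#'   fragment intervals (mode `fragment_overlap`).
#' @param windows data.frame from [promoter_windows()].
#' @param mode `"read_5prime"` or `"fragment_overlap"`.
#' @return integer vector of counts, one per window row, named by gene_id.
#' @export
count_reads_in_windows <- function(reads, windows,
                                   mode = c("read_5prime", "fragment_overlap")) {
  mode <- match.arg(mode)
  counts <- integer(nrow(windows))
  for (chrom in unique(windows$chrom)) {
    wi <- which(windows$chrom == chrom)
    sub <- reads[reads$chrom == chrom, , drop = FALSE]
    if (nrow(sub) == 0L) next
    ws <- windows$start[wi]; we <- windows$end[wi]
    if (mode == "read_5prime") {
      pos <- sort(.read_5prime(sub))
      counts[wi] <- findInterval(we - 1L, pos) - findInterval(ws - 1L, pos)
    } else {
      a <- sort(sub$start); b <- sort(sub$end)
      counts[wi] <- findInterval(we - 1L, a) - findInterval(ws, b)
    }
  }
  stats::setNames(counts, windows$gene_id)
}

#' Assemble a promoter count matrix for one mark
#'
#' @param count_vectors named list of per-sample count vectors with
#'   identical gene ordering (as from [count_reads_in_windows()]).
#' @param mark histone mark name.
#' @param groups named character vector mapping sample id to group
#'   (`"patient"` or `"control"`).
#' @return object of class `promoter_count_matrix`: list with `mark`,
#'   integer matrix `counts` (genes x samples), and `groups`.
#' @export
assemble_count_matrix <- function(count_vectors, mark, groups) {
  stopifnot(length(count_vectors) >= 1L, !is.null(names(count_vectors)))
  genes <- names(count_vectors[[1L]])
  for (v in count_vectors)
    if (!identical(names(v), genes))
      stop("assemble_count_matrix: inconsistent gene lists across samples")
  samples <- names(count_vectors)
  if (!all(samples %in% names(groups)))
    stop("assemble_count_matrix: missing group label for some sample")
  groups <- groups[samples]
  if (!all(groups %in% c("patient", "control")))
    stop("assemble_count_matrix: groups must be 'patient' or 'control'")
  counts <- matrix(as.integer(unlist(count_vectors, use.names = FALSE)),
                   nrow = length(genes), ncol = length(samples),
                   dimnames = list(genes, samples))
  structure(list(mark = mark, counts = counts, groups = groups),
            class = "promoter_count_matrix")
}

#' @export
print.promoter_count_matrix <- function(x, ...) {
  cat("promoter_count_matrix:", x$mark, "-", nrow(x$counts), "genes x",
      ncol(x$counts), "samples (",
      sum(x$groups == "patient"), "patient /",
      sum(x$groups == "control"), "control )\n")
  invisible(x)
}

#' Write a promoter count matrix as TSV (plus a group sidecar)
#'
#' The main TSV has a header row of sample ids and a first `gene_id`
#' column; `<path>.groups.tsv` maps sample to group.
#'
#' @param pcm a `promoter_count_matrix`.
#' @param path output TSV path.
#' @export
write_count_matrix <- function(pcm, path) {
  df <- data.frame(gene_id = rownames(pcm$counts), pcm$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  gdf <- data.frame(sample = names(pcm$groups), group = unname(pcm$groups))
  utils::write.table(gdf, paste0(path, ".groups.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a promoter count matrix written by [write_count_matrix()]
#' @param path TSV path.
#' @param mark mark name to record.
#' @return a `promoter_count_matrix`.
#' @export
read_count_matrix <- function(path, mark) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  gdf <- utils::read.table(paste0(path, ".groups.tsv"), sep = "\t",
                           header = TRUE, stringsAsFactors = FALSE)
  counts <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(counts) <- "integer"
  rownames(counts) <- df$gene_id
  structure(list(mark = mark, counts = counts,
                 groups = stats::setNames(gdf$group, gdf$sample)[colnames(counts)]),
            class = "promoter_count_matrix")
}
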