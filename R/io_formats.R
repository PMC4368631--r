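# Readers and writers for the plain-text formats the pipeline touches.
# All internal coordinates are 0-based, half-open [start, end); BED and
# refFlat are native to that convention, so no shifting happens anywhere.

.STRANDS <- c("+", "-", ".")

#' Validate a set of genomic intervals
#'
#' Checks the universal interval invariants: non-empty chromosome names,
#' integer-like `0 <= start < end`, strand in `+`, `-`, `.`, and (when
#' `chrom_sizes` is supplied) `end <= chromosome length`.
#'
#' @param df data.frame with at least `chrom`, `start`, `end` columns and
#'   optionally `strand`.
#' @param chrom_sizes optional named vector of chromosome lengths.
#' @param what label used in error messages.
#' @return `df`, invisibly, if valid; otherwise an error is thrown.
#' @export
validate_intervals <- function(df, chrom_sizes = NULL, what = "interval") {
  stopifnot(is.data.frame(df))
  if (nrow(df) == 0L) return(invisible(df))
  if (any(is.na(df$chrom)) || any(!nzchar(df$chrom)))
    stop(what, ": empty chromosome name")
  if (any(!is.finite(df$start)) || any(!is.finite(df$end)))
    stop(what, ": non-finite coordinates")
  if (any(df$start < 0L)) stop(what, ": negative start coordinate")
  if (any(df$start >= df$end))
    stop(what, ": start >= end at row ", which(df$start >= df$end)[1L])
  if (!is.null(df$strand) && any(!df$strand %in% .STRANDS))
    stop(what, ": strand must be one of '+', '-', '.'")
  if (!is.null(chrom_sizes)) {
    unknown <- setdiff(unique(df$chrom), names(chrom_sizes))
    if (length(unknown))
      stop(what, ": unknown chromosome(s): ", paste(unknown, collapse = ", "))
    if (any(df$end > chrom_sizes[df$chrom]))
      stop(what, ": interval extends beyond chromosome end")
  }
  invisible(df)
}

#' Read aligned reads from a BED6 file
#'
#' Each line must have at least six tab-separated columns
#' (chrom, start, end, name, score, strand). Coordinates are 0-based
#' half-open. Line order is preserved.
#'
#' @param path path to a BED file.
#' @return data.frame with columns `chrom`, `start`, `end`, `name`,
#'   `score`, `strand`.
#' @export
read_bed_reads <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  nf <- utils::count.fields(path, sep = "\t", quote = "", comment.char = "")
  if (length(nf) == 0L) {
    return(data.frame(chrom = character(), start = integer(), end = integer(),
                      name = character(), score = integer(), strand = character(),
                      stringsAsFactors = FALSE))
  }
  bad <- which(nf < 6L)
  if (length(bad))
    stop("malformed BED line ", bad[1L], " in ", path, ": fewer than 6 columns")
  df <- utils::read.table(path, sep = "\t", quote = "", comment.char = "",
                          stringsAsFactors = FALSE,
                          col.names = paste0("V", seq_len(max(nf))),
                          fill = TRUE)[, 1:6]
  names(df) <- c("chrom", "start", "end", "name", "score", "strand")
  df$chrom <- as.character(df$chrom)
  df$name <- as.character(df$name)
  if (any(is.na(df$start)) || any(is.na(df$end)))
    stop("malformed BED line in ", path, ": non-numeric coordinates")
  validate_intervals(df, what = "BED read")
  df
}

#' Write aligned reads as BED6
#'
#' Inverse of [read_bed_reads()]: canonical files round-trip byte-identically.
#'
#' @param reads data.frame as returned by [read_bed_reads()].
#' @param path output path.
#' @export
write_bed_reads <- function(reads, path) {
  validate_intervals(reads, what = "BED read")
  lines <- sprintf("%s\t%d\t%d\t%s\t%s\t%s", reads$chrom,
                   as.integer(reads$start), as.integer(reads$end),
                   reads$name, format(reads$score, trim = TRUE, scientific = FALSE),
                   reads$strand)
  writeLines(lines, path)
  invisible(path)
}

#' Read a gene annotation (refFlat-style TSV)
#'
#' Columns: geneName, name, chrom, strand, txStart, txEnd, with `txStart`
#' 0-based and `txEnd` exclusive. Duplicate transcript ids are rejected;
#' strand must be `+` or `-`.
#'
#' @param path path to the annotation TSV (no header).
#' @return data.frame with columns `gene_id`, `gene_name`, `chrom`,
#'   `strand`, `start`, `end`.
#' @export
read_annotation <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.table(path, sep = "\t", quote = "", comment.char = "",
                          stringsAsFactors = FALSE,
                          colClasses = c("character", "character", "character",
                                         "character", "integer", "integer"))
  names(df) <- c("gene_name", "gene_id", "chrom", "strand", "start", "end")
  df <- df[, c("gene_id", "gene_name", "chrom", "strand", "start", "end")]
  if (anyDuplicated(df$gene_id))
    stop("duplicate gene_id in annotation: ",
         df$gene_id[duplicated(df$gene_id)][1L])
  if (any(!df$strand %in% c("+", "-")))
    stop("annotation strand must be '+' or '-'")
  validate_intervals(df, what = "transcript")
  df
}

#' Write a gene annotation as refFlat-style TSV
#' @param genes data.frame as returned by [read_annotation()].
#' @param path output path.
#' @export
write_annotation <- function(genes, path) {
  lines <- sprintf("%s\t%s\t%s\t%s\t%d\t%d", genes$gene_name, genes$gene_id,
                   genes$chrom, genes$strand, as.integer(genes$start),
                   as.integer(genes$end))
  writeLines(lines, path)
  invisible(path)
}

#' Read chromosome sizes from a two-column TSV
#' @param path path to a `<chrom>\t<length>` file.
#' @return named numeric vector of chromosome lengths.
#' @export
read_chrom_sizes <- function(path) {
  df <- utils::read.table(path, sep = "\t", quote = "", comment.char = "",
                          stringsAsFactors = FALSE,
                          colClasses = c("character", "numeric"))
  if (anyDuplicated(df[[1L]])) stop("duplicate chromosome in sizes file")
  if (any(df[[2L]] <= 0)) stop("chromosome lengths must be positive")
  stats::setNames(df[[2L]], df[[1L]])
}

#' Write chromosome sizes
#' @param sizes named vector of chromosome lengths.
#' @param path output path.
#' @export
write_chrom_sizes <- function(sizes, path) {
  writeLines(sprintf("%s\t%d", names(sizes), as.integer(sizes)), path)
  invisible(path)
}

#' Read gene sets from a GMT file
#'
#' Each line is `setName TAB description TAB gene1 TAB gene2 ...`.
#' Duplicate genes within a line are collapsed.
#'
#' @param path path to a GMT file.
#' @return named list; each element is `list(description =, genes =)`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 3L)
      stop("malformed GMT line ", i, ": fewer than 3 fields")
    genes <- unique(f[-(1:2)])
    genes <- genes[nzchar(genes)]
    if (length(genes) == 0L) stop("empty gene set at GMT line ", i)
    out[[f[1L]]] <- list(description = f[2L], genes = genes)
  }
  out
}

#' Write gene sets to a GMT file
#' @param sets named list as returned by [read_gmt()].
#' @param path output path.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, sets[[nm]]$description, sets[[nm]]$genes), collapse = "\t")
  }, character(1L))
  writeLines(lines, path)
  invisible(path)
}

#' Export a coverage track as bedGraph
#'
#' Writes a run-length-merged 4-column bedGraph (chrom, start, end, value);
#' zero-valued runs are omitted and lines are sorted by chromosome name then
#' start. Values must be finite.
#'
#' @param track a [coverage_track()].
#' @param path output path.
#' @export
write_bedgraph <- function(track, path) {
  stopifnot(inherits(track, "coverage_track"))
  con <- file(path, "w")
  on.exit(close(con))
  for (chrom in sort(names(track$values))) {
    v <- track$values[[chrom]]
    if (any(!is.finite(v))) stop("non-finite coverage value on ", chrom)
    r <- rle(v)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    keep <- r$values != 0
    if (!any(keep)) next
    writeLines(sprintf("%s\t%d\t%d\t%s", chrom, starts[keep], ends[keep],
                       format(r$values[keep], trim = TRUE, scientific = FALSE,
                              digits = 15)),
               con)
  }
  invisible(path)
}

#' Read a bedGraph file back into per-chromosome vectors
#'
#' Inverse of [write_bedgraph()] given the chromosome lengths (bases not
#' covered by any line are zero).
#'
#' @param path bedGraph path.
#' @param chrom_sizes named vector of chromosome lengths.
#' @param library_size library size to record on the returned track.
#' @param state state label to record on the returned track.
#' @return a [coverage_track()].
#' @export
read_bedgraph <- function(path, chrom_sizes, library_size = NA_real_,
                          state = "raw") {
  vals <- lapply(chrom_sizes, function(L) numeric(L))
  nf <- utils::count.fields(path, sep = "\t", quote = "")
  if (length(nf)) {
    df <- utils::read.table(path, sep = "\t", quote = "",
                            stringsAsFactors = FALSE,
                            colClasses = c("character", "integer", "integer",
                                           "numeric"))
    for (chrom in unique(df[[1L]])) {
      if (!chrom %in% names(chrom_sizes))
        stop("bedGraph chromosome not in sizes: ", chrom)
      sub <- df[df[[1L]] == chrom, ]
      for (k in seq_len(nrow(sub)))
        vals[[chrom]][(sub[k, 2L] + 1L):sub[k, 3L]] <- sub[k, 4L]
    }
  }
  coverage_track(vals, library_size = library_size, state = state)
}

#' Parse a genome-browser region string
#'
#' Interprets browser-style printed coordinates such as
#' `"chr2:102,282,711-102,874,166"` (with comma thousands separators and a
#' hyphen or en-dash) as `start = first`, `end = second`, so that the region
#' length is `end - start`.
#'
#' @param region a region string, `"chrom:start-end"`.
#' @return list with `chrom`, `start`, `end`, `length`.
#' @export
parse_browser_region <- function(region) {
  region <- gsub(",", "", region, fixed = TRUE)
  region <- gsub("–", "-", region)  # en-dash
  m <- regmatches(region, regexec("^([^:]+):([0-9]+)-([0-9]+)$", region))[[1L]]
  if (length(m) != 4L) stop("cannot parse region: ", region)
  start <- as.numeric(m[3L]); end <- as.numeric(m[4L])
  if (start >= end) stop("region start >= end")
  list(chrom = m[2L], start = start, end = end, length = end - start)
}

#' Report chromosome-name consistency between reads and annotation
#'
#' Returns the chromosome names present in only one of the two inputs;
#' disjoint naming (e.g. a missing "chr" prefix) is the classic silent
#' failure this check surfaces.
#'
#' @param reads read data.frame.
#' @param genes annotation data.frame.
#' @return list with `reads_only` and `annotation_only` character vectors.
#' @export
check_chrom_names <- function(reads, genes) {
  r <- unique(reads$chrom); g <- unique(genes$chrom)
  list(reads_only = setdiff(r, g), annotation_only = setdiff(g, r))
}
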