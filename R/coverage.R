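# Per-base coverage tracks and their normalization chain:
# raw -> per_million -> smoothed -> quantile_normalized.

.TRACK_STATES <- c("raw", "per_million", "smoothed", "quantile_normalized")

#' Construct a coverage track
#'
#' A coverage track holds one non-negative per-base signal vector per
#' chromosome, the library size it was built from, and a normalization
#' state. States only move forward through
#' raw, per_million, smoothed, quantile_normalized.
#'
#' @param values named list of numeric vectors, one per chromosome.
#' @param library_size total retained read count of the originating library.
#' @param state normalization state.
#' @return object of class `coverage_track`.
#' @export
coverage_track <- function(values, library_size = NA_real_, state = "raw") {
  stopifnot(is.list(values), !is.null(names(values)))
  state <- match.arg(state, .TRACK_STATES)
  structure(list(values = values, library_size = library_size, state = state),
            class = "coverage_track")
}

#' @export
print.coverage_track <- function(x, ...) {
  cat("coverage_track:", length(x$values), "chromosome(s),",
      format(sum(vapply(x$values, length, 1)), big.mark = ","), "bp, state =",
      x$state, ", library_size =", x$library_size, "\n")
  invisible(x)
}

.check_state <- function(track, allowed, op) {
  if (!track$state %in% allowed)
    stop(op, ": track in state '", track$state, "', needs one of: ",
         paste(allowed, collapse = ", "))
}

.read_5prime <- function(reads) {
  ifelse(reads$strand == "-", reads$end - 1L, reads$start)
}

#' Remove duplicate reads
#'
#' Keeps at most one read per (chromosome, 5' position, strand) key — the
#' "unique reads" filter applied before profile generation. The first
#' occurrence is kept and the output is sorted by chromosome, start, end,
#' strand for determinism.
#'
#' @param reads read data.frame (BED6 columns).
#' @return deduplicated, sorted read data.frame.
#' @export
deduplicate_reads <- function(reads) {
  if (nrow(reads) == 0L) return(reads)
  key <- paste(reads$chrom, .read_5prime(reads), reads$strand, sep = "\r")
  out <- reads[!duplicated(key), , drop = FALSE]
  out <- out[order(out$chrom, out$start, out$end, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Extend reads to fragment length
#'
#' Each read is extended from its 5' end to `fragment_length`, modeling the
#' sequenced fragment: a plus-strand read starting at s becomes
#' [s, s + fragment_length), a minus-strand read ending at e becomes
#' [e - fragment_length, e). A fragment never ends up shorter than the read
#' itself, and fragments are clipped to chromosome bounds.
#'
#' @param reads read data.frame.
#' @param fragment_length target fragment length in bp (>= 1).
#' @param chrom_sizes named vector of chromosome lengths.
#' @return data.frame with `chrom`, `start`, `end`.
#' @export
extend_reads <- function(reads, fragment_length = 200, chrom_sizes) {
  stopifnot(fragment_length >= 1)
  validate_intervals(reads, chrom_sizes, what = "read")
  minus <- reads$strand == "-"
  start <- ifelse(minus, pmin(reads$end - fragment_length, reads$start),
                  reads$start)
  end <- ifelse(minus, reads$end,
                pmax(reads$start + fragment_length, reads$end))
  start <- pmax(start, 0)
  end <- pmin(end, unname(chrom_sizes[reads$chrom]))
  data.frame(chrom = reads$chrom, start = as.integer(start),
             end = as.integer(end), stringsAsFactors = FALSE)
}

#' Build a raw coverage track from fragments
#'
#' The value at base b is the number of fragments overlapping b, so the
#' genome-wide total equals the summed fragment lengths.
#'
#' @param fragments data.frame with `chrom`, `start`, `end` (clipped to
#'   chromosome bounds).
#' @param chrom_sizes named vector of chromosome lengths.
#' @param library_size library size to record; defaults to `nrow(fragments)`.
#' @return a `coverage_track` in state `raw`.
#' @export
build_coverage <- function(fragments, chrom_sizes,
                           library_size = nrow(fragments)) {
  validate_intervals(fragments, chrom_sizes, what = "fragment")
  vals <- lapply(names(chrom_sizes), function(chrom) {
    L <- as.integer(chrom_sizes[[chrom]])
    sub <- fragments[fragments$chrom == chrom, , drop = FALSE]
    if (nrow(sub) == 0L) return(numeric(L))
    d <- tabulate(sub$start + 1L, nbins = L + 1L) -
      tabulate(sub$end + 1L, nbins = L + 1L)
    cumsum(d)[seq_len(L)]
  })
  names(vals) <- names(chrom_sizes)
  coverage_track(vals, library_size = library_size, state = "raw")
}

#' Scale a track to per-million-reads units
#'
#' Multiplies every value by 1e6 / library_size to account for differential
#' sequencing depth.
#'
#' @param track a raw `coverage_track`.
#' @return track in state `per_million`.
#' @export
normalize_per_million <- function(track) {
  .check_state(track, "raw", "normalize_per_million")
  if (is.na(track$library_size) || track$library_size <= 0)
    stop("normalize_per_million: library_size must be positive")
  track$values <- lapply(track$values, function(v) v * 1e6 / track$library_size)
  track$state <- "per_million"
  track
}

#' Smooth a track with a centered moving average
#'
#' An even window is widened by one base so it can be centered (the 1000 bp
#' default becomes 1001). Near chromosome ends the window truncates to the
#' available bases; no signal is invented outside the chromosome.
#'
#' @param track a `coverage_track` in state raw or per_million.
#' @param window_bp smoothing window in bp.
#' @return track in state `smoothed`.
#' @export
smooth_track <- function(track, window_bp = 1000) {
  .check_state(track, c("raw", "per_million"), "smooth_track")
  stopifnot(window_bp >= 1)
  w <- as.integer(window_bp)
  if (w %% 2L == 0L) w <- w + 1L
  half <- (w - 1L) %/% 2L
  track$values <- lapply(track$values, function(v) {
    L <- length(v)
    cs <- c(0, cumsum(v))
    i <- seq_len(L)
    lo <- pmax(i - half, 1L)
    hi <- pmin(i + half, L)
    (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  })
  track$state <- "smoothed"
  track
}

.track_concat <- function(track) {
  unlist(track$values, use.names = FALSE)
}

.track_unconcat <- function(template, x) {
  lens <- vapply(template$values, length, 1L)
  split_at <- rep(names(template$values), lens)
  out <- split(x, factor(split_at, levels = names(template$values)))
  lapply(out, unname)
}

# One sample's values mapped onto the cross-sample mean quantiles.
# Tied values receive the mean of the quantile values their ranks span.
.qn_one <- function(x, mean_quant) {
  o <- order(x)
  xs <- x[o]
  grp <- cumsum(c(TRUE, diff(xs) != 0))
  new_sorted <- stats::ave(mean_quant, grp)
  out <- numeric(length(x))
  out[o] <- new_sorted
  out
}

#' Quantile-normalize a set of coverage tracks
#'
#' Classic rank-based quantile normalization across samples over the
#' concatenated per-base values: the value at rank r in each sample is
#' replaced by the mean of the rank-r values across samples; ties within a
#' sample receive the mean of the quantile values their ranks span, so
#' within-sample rank order is preserved.
#'
#' @param tracks list of `coverage_track`s sharing chromosomes, lengths and
#'   state.
#' @return list of tracks in state `quantile_normalized`.
#' @export
quantile_normalize <- function(tracks) {
  stopifnot(is.list(tracks), length(tracks) >= 1L)
  ref <- tracks[[1L]]
  for (tr in tracks) {
    stopifnot(inherits(tr, "coverage_track"))
    if (!identical(names(tr$values), names(ref$values)) ||
        !identical(vapply(tr$values, length, 1L),
                   vapply(ref$values, length, 1L)))
      stop("quantile_normalize: tracks have mismatched genomes")
    if (!identical(tr$state, ref$state))
      stop("quantile_normalize: tracks in different states")
  }
  mat <- vapply(tracks, .track_concat, numeric(sum(vapply(ref$values, length, 1L))))
  sorted <- apply(mat, 2L, sort, method = "radix")
  mean_quant <- rowMeans(sorted)
  lapply(seq_along(tracks), function(j) {
    tr <- tracks[[j]]
    tr$values <- .track_unconcat(ref, .qn_one(mat[, j], mean_quant))
    tr$state <- "quantile_normalized"
    tr
  })
}

# Per-base signal in the oriented +/- flank window around one TSS.
# Plus strand: bases [tss - flank, tss + flank); minus strand: bases
# tss + flank down to tss - flank + 1, i.e. the exact mirror image, so
# reflecting the genome leaves profiles unchanged.
.tss_window_signal <- function(values, tss, strand, flank) {
  if (strand == "-") {
    values[seq.int(tss + flank + 1L, tss - flank + 2L)]
  } else {
    values[seq.int(tss - flank + 1L, tss + flank)]
  }
}

#' Aggregate signal around TSSs into a binned meta-profile
#'
#' For each gene the +/- `flank_bp` window around its TSS is oriented
#' 5' to 3' (minus-strand windows mirrored), partitioned into `bin_bp`
#' bins, and bin-averaged; the profile is the per-bin mean over genes.
#' TSSs closer than `flank_bp` to a chromosome end are skipped with a
#' warning.
#'
#' @param tracks named list of `coverage_track`s (one per sample), or a
#'   single track.
#' @param tss data.frame with columns `chrom`, `tss`, `strand` (e.g. from
#'   [promoter_windows()]).
#' @param flank_bp half-window size in bp; must be a multiple of `bin_bp`.
#' @param bin_bp bin width in bp.
#' @return data.frame with `bin_center` (offset from the TSS of each bin
#'   midpoint) and one mean-signal column per track.
#' @export
meta_profile <- function(tracks, tss, flank_bp = 1000, bin_bp = 50) {
  if (inherits(tracks, "coverage_track")) tracks <- list(signal = tracks)
  stopifnot(length(tracks) >= 1L, flank_bp %% bin_bp == 0)
  if (nrow(tss) == 0L) stop("meta_profile: empty TSS set")
  sizes <- vapply(tracks[[1L]]$values, length, 1L)
  ok <- tss$chrom %in% names(sizes)
  ok[ok] <- tss$tss[ok] - flank_bp >= 0 &
    tss$tss[ok] + flank_bp <= sizes[tss$chrom[ok]]
  if (any(!ok))
    warning("meta_profile: skipping ", sum(!ok),
            " TSS(s) within flank_bp of a chromosome end")
  tss <- tss[ok, , drop = FALSE]
  if (nrow(tss) == 0L) stop("meta_profile: no usable TSS")
  n_bins <- as.integer(2 * flank_bp / bin_bp)
  prof <- vapply(tracks, function(tr) {
    acc <- numeric(n_bins)
    for (i in seq_len(nrow(tss))) {
      sig <- .tss_window_signal(tr$values[[tss$chrom[i]]], tss$tss[i],
                                tss$strand[i], flank_bp)
      acc <- acc + colMeans(matrix(sig, nrow = bin_bp))
    }
    acc / nrow(tss)
  }, numeric(n_bins))
  centers <- -flank_bp + (seq_len(n_bins) - 0.5) * bin_bp
  out <- data.frame(bin_center = centers)
  nms <- names(tracks)
  if (is.null(nms)) nms <- paste0("sample", seq_along(tracks))
  out[nms] <- as.data.frame(prof)
  out
}
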