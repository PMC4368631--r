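# Negative-binomial differential promoter occupancy: median-of-ratios size
# factors, method-of-moments dispersion with an optional trend floor, the
# exact conditional test on group-summed counts, and threshold-based
# significance calls.

#' Median-of-ratios size factors
#'
#' For sample j, `s_j = median_i k_ij / (prod_v k_iv)^(1/m)`, the median
#' taken over genes whose counts are positive in every sample (only those
#' contribute a finite geometric-mean reference).
#'
#' @param counts integer matrix (genes x samples) or a
#'   `promoter_count_matrix`.
#' @return named numeric vector of size factors, with the geometric mean
#'   attached as attribute `geo_mean`.
#' @export
size_factors <- function(counts) {
  if (inherits(counts, "promoter_count_matrix")) counts <- counts$counts
  stopifnot(is.matrix(counts), ncol(counts) >= 1L)
  pos <- rowSums(counts > 0) == ncol(counts)
  if (!any(pos))
    stop("size_factors: no gene with all-positive counts; ",
         "cannot form the geometric-mean reference (counts too sparse)")
  lk <- log(counts[pos, , drop = FALSE])
  ref <- rowMeans(lk)
  s <- exp(apply(lk - ref, 2L, stats::median))
  attr(s, "geo_mean") <- exp(mean(log(s)))
  s
}

#' Method-of-moments dispersion estimates
#'
#' Per gene, with normalized counts `k_ij / s_j`: `q_i` the overall mean,
#' `v_i` the pooled within-group sample variance (denominator n − G, so
#' true between-group differences do not inflate the estimate), and
#' `xi = mean(1/s_j)` the shot-noise scale, the raw estimate is
#' `alpha_i = (v_i − q_i * xi) / q_i^2`, floored at `floor`. With
#' `shrink = TRUE` (default) a log-log linear trend of the raw estimates on
#' `q` is fitted and each gene receives `max(raw, trend)` — conservative
#' against dispersion under-estimation at few replicates.
#'
#' @param counts count matrix (genes x samples) or `promoter_count_matrix`.
#' @param sf size factors from [size_factors()].
#' @param groups character vector of group labels per sample.
#' @param shrink apply the trend floor.
#' @param floor minimum dispersion.
#' @return numeric vector of per-gene dispersions.
#' @export
estimate_dispersion <- function(counts, sf, groups, shrink = TRUE,
                                floor = 1e-8) {
  if (inherits(counts, "promoter_count_matrix")) {
    if (missing(groups)) groups <- counts$groups
    counts <- counts$counts
  }
  stopifnot(ncol(counts) >= 2L, length(sf) == ncol(counts),
            length(groups) == ncol(counts))
  norm <- sweep(counts, 2L, sf, "/")
  q <- rowMeans(norm)
  gl <- unique(groups)
  df_within <- 0L
  ss <- numeric(nrow(counts))
  for (g in gl) {
    cols <- which(groups == g)
    if (length(cols) < 2L) next
    sub <- norm[, cols, drop = FALSE]
    ss <- ss + rowSums((sub - rowMeans(sub))^2)
    df_within <- df_within + length(cols) - 1L
  }
  if (df_within == 0L)
    stop("estimate_dispersion: no group with >= 2 samples")
  v <- ss / df_within
  xi <- mean(1 / sf)
  alpha <- (v - q * xi) / q^2
  alpha[!is.finite(alpha)] <- floor
  alpha <- pmax(alpha, floor)
  if (shrink) {
    use <- alpha > floor & q > 0
    if (sum(use) >= 10L) {
      fit <- stats::lm(log(alpha[use]) ~ log(q[use]))
      trend <- exp(stats::coef(fit)[1L] + stats::coef(fit)[2L] * log(pmax(q, .Machine$double.eps)))
      trend[!is.finite(trend)] <- floor
      alpha <- pmax(alpha, trend)
    }
  }
  unname(alpha)
}

.log_nb <- function(x, mu, alpha) {
  if (alpha <= 0) stats::dpois(x, lambda = mu, log = TRUE)
  else stats::dnbinom(x, mu = mu, size = 1 / alpha, log = TRUE)
}

.logsumexp <- function(x) {
  x <- x[is.finite(x) | x == -Inf]
  m <- max(x)
  if (!is.finite(m)) return(-Inf)
  m + log(sum(exp(x - m)))
}

#' Exact conditional negative-binomial test for two group-summed counts
#'
#' Conditions on the total `K_S = K_A + K_B` and sums, over all splits
#' `a + b = K_S` whose probability does not exceed that of the observed
#' split, the product `P(a) P(b)` of negative-binomial masses, normalized
#' by the sum over all splits. Group means are the summed size factors
#' times the common concentration `q0 = K_S / (s_A + s_B)`; group-sum
#' variances are the sums of per-sample NB variances,
#' `mu_G + alpha * q0^2 * sum_j s_j^2`, so the effective group size
#' parameter is `s_G^2 / (alpha * sum_j s_j^2)`. Dispersion 0 is evaluated
#' as the Poisson limit. Computed in log space; stable for totals up to
#' about 1e6.
#'
#' @param kA,kB observed summed counts in groups A and B.
#' @param sfA,sfB size factors of the samples in each group.
#' @param alpha NB dispersion (>= 0).
#' @return two-sided p-value in (0, 1].
#' @export
nb_exact_test <- function(kA, kB, sfA, sfB, alpha) {
  stopifnot(kA >= 0, kB >= 0, alpha >= 0)
  kS <- kA + kB
  if (kS == 0) return(1)
  sA <- sum(sfA); sB <- sum(sfB)
  q0 <- kS / (sA + sB)
  muA <- sA * q0; muB <- sB * q0
  alphaA <- if (alpha > 0) alpha * sum(sfA^2) / sA^2 else 0
  alphaB <- if (alpha > 0) alpha * sum(sfB^2) / sB^2 else 0
  a <- 0:kS
  lp <- .log_nb(a, muA, alphaA) + .log_nb(kS - a, muB, alphaB)
  lobs <- lp[kA + 1L]
  keep <- lp <= lobs + 1e-7
  p <- exp(.logsumexp(lp[keep]) - .logsumexp(lp))
  min(max(p, .Machine$double.xmin), 1)
}

#' Log2 fold change of normalized group means
#'
#' `log2((mean normalized patient count + c) / (mean normalized control
#' count + c))`; the pseudocount c keeps the estimate finite at zero
#' counts. Direction is patients versus controls throughout (a silenced
#' promoter has negative log2FC on the active marks).
#'
#' @param counts count matrix or `promoter_count_matrix`.
#' @param sf size factors.
#' @param groups group labels per sample (`patient` / `control`).
#' @param pseudocount positive stabilizing constant.
#' @return numeric vector of per-gene log2 fold changes.
#' @export
log2_fold_change <- function(counts, sf, groups, pseudocount = 1) {
  if (inherits(counts, "promoter_count_matrix")) {
    if (missing(groups)) groups <- counts$groups
    counts <- counts$counts
  }
  stopifnot(pseudocount > 0)
  norm <- sweep(counts, 2L, sf, "/")
  mp <- rowMeans(norm[, groups == "patient", drop = FALSE])
  mc <- rowMeans(norm[, groups == "control", drop = FALSE])
  log2((mp + pseudocount) / (mc + pseudocount))
}

#' Differential occupancy table for one mark
#'
#' Runs the full per-mark chain: size factors, dispersion estimation, the
#' exact conditional test of patients versus controls on group-summed
#' counts, and pseudocount-protected log2 fold changes.
#'
#' @param pcm a `promoter_count_matrix`.
#' @param shrink passed to [estimate_dispersion()].
#' @param pseudocount passed to [log2_fold_change()].
#' @param sf optional externally supplied size factors.
#' @return data.frame with `gene_id`, `baseMean_control`,
#'   `baseMean_patient`, `log2FC`, `pval`, `dispersion`.
#' @export
differential_table <- function(pcm, shrink = TRUE, pseudocount = 1, sf = NULL) {
  stopifnot(inherits(pcm, "promoter_count_matrix"))
  counts <- pcm$counts
  groups <- pcm$groups
  if (is.null(sf)) sf <- size_factors(counts)
  alpha <- estimate_dispersion(counts, sf, groups, shrink = shrink)
  norm <- sweep(counts, 2L, sf, "/")
  pat <- groups == "patient"
  mp <- rowMeans(norm[, pat, drop = FALSE])
  mc <- rowMeans(norm[, !pat, drop = FALSE])
  kA <- rowSums(counts[, pat, drop = FALSE])
  kB <- rowSums(counts[, !pat, drop = FALSE])
  pv <- vapply(seq_len(nrow(counts)), function(i) {
    nb_exact_test(kA[i], kB[i], sf[pat], sf[!pat], alpha[i])
  }, numeric(1L))
  data.frame(gene_id = rownames(counts),
             baseMean_control = unname(mc), baseMean_patient = unname(mp),
             log2FC = unname(log2_fold_change(counts, sf, groups,
                                              pseudocount = pseudocount)),
             pval = pv, dispersion = alpha,
             stringsAsFactors = FALSE)
}

#' Select genes with significantly changed occupancy in any mark
#'
#' A gene is flagged in a mark when `|log2FC| >= lfc_threshold` and
#' `p <= p_threshold` (defaults: two-fold change, p 0.05), and selected
#' when flagged in at least one mark.
#'
#' @param tables named list of per-mark data.frames from
#'   [differential_table()], sharing the gene universe.
#' @param lfc_threshold minimum absolute log2 fold change.
#' @param p_threshold maximum p-value.
#' @return data.frame with `gene_id`, one logical column per mark, and
#'   `selected`.
#' @export
select_significant <- function(tables, lfc_threshold = 1, p_threshold = 0.05) {
  stopifnot(length(tables) >= 1L, !is.null(names(tables)))
  genes <- tables[[1L]]$gene_id
  for (tb in tables)
    if (!identical(tb$gene_id, genes))
      stop("select_significant: mark tables have mismatched gene universes")
  out <- data.frame(gene_id = genes, stringsAsFactors = FALSE)
  for (mk in names(tables)) {
    tb <- tables[[mk]]
    out[[mk]] <- abs(tb$log2FC) >= lfc_threshold & tb$pval <= p_threshold
  }
  out$selected <- Reduce(`|`, out[names(tables)])
  out
}
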