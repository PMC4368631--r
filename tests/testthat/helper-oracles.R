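# Independent reference implementations used to check the package's
# optimized paths: naive enumeration / brute-force versions that share no
# code with R/.

# Direct evaluation of the conditional NB test: probabilities in natural
# scale, explicit sum over qualifying splits.
oracle_nb_exact_p <- function(kA, kB, sfA, sfB, alpha) {
  kS <- kA + kB
  if (kS == 0) return(1)
  sA <- sum(sfA); sB <- sum(sfB)
  q0 <- kS / (sA + sB)
  muA <- sA * q0; muB <- sB * q0
  pmf <- function(x, mu, sf_group) {
    if (alpha <= 0) return(dpois(x, mu))
    a_g <- alpha * sum(sf_group^2) / sum(sf_group)^2
    dnbinom(x, mu = mu, size = 1 / a_g)
  }
  pa <- pmf(0:kS, muA, sfA)
  pb <- pmf(kS:0, muB, sfB)
  joint <- pa * pb
  obs <- joint[kA + 1]
  sum(joint[joint <= obs * (1 + 1e-7)]) / sum(joint)
}

# O(n^3) complete-linkage agglomeration from the raw distance matrix.
# Returns the sequence of merge heights (non-decreasing).
oracle_complete_linkage_heights <- function(mat) {
  d <- as.matrix(dist(mat))
  clusters <- as.list(seq_len(nrow(mat)))
  heights <- numeric(0)
  while (length(clusters) > 1) {
    best <- Inf; bi <- bj <- NA
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (j <= i) next
        h <- max(d[clusters[[i]], clusters[[j]]])
        if (h < best) { best <- h; bi <- i; bj <- j }
      }
    }
    heights <- c(heights, best)
    clusters[[bi]] <- c(clusters[[bi]], clusters[[bj]])
    clusters[[bj]] <- NULL
  }
  heights
}

# Double loop over reads x windows.
oracle_count_5prime <- function(reads, windows) {
  p5 <- ifelse(reads$strand == "-", reads$end - 1L, reads$start)
  vapply(seq_len(nrow(windows)), function(w) {
    sum(reads$chrom == windows$chrom[w] &
          p5 >= windows$start[w] & p5 < windows$end[w])
  }, numeric(1))
}

oracle_count_overlap <- function(frags, windows) {
  vapply(seq_len(nrow(windows)), function(w) {
    sum(frags$chrom == windows$chrom[w] &
          frags$start < windows$end[w] & frags$end > windows$start[w])
  }, numeric(1))
}

# Exhaustive hypergeometric upper tail: enumerate every size-n draw from
# the universe and count draws with overlap >= observed.
oracle_hypergeom_p <- function(N, K, n, x_obs) {
  draws <- combn(N, n)
  overlaps <- colSums(draws <= K)  # first K elements are the set
  mean(overlaps >= x_obs)
}

# Exact two-sided Mann-Whitney p by full enumeration of group labelings.
oracle_mw_p <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  u_of <- function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2
  u_obs <- u_of(seq_len(n1))
  dev_obs <- abs(u_obs - n1 * n2 / 2)
  sets <- combn(n1 + n2, n1)
  us <- apply(sets, 2, u_of)
  mean(abs(us - n1 * n2 / 2) >= dev_obs - 1e-9)
}

# Per-base coverage by looping over every fragment and base.
oracle_coverage <- function(frags, L) {
  v <- numeric(L)
  for (i in seq_len(nrow(frags))) {
    if (frags$end[i] > frags$start[i])
      for (b in (frags$start[i] + 1):frags$end[i]) v[b] <- v[b] + 1
  }
  v
}

# Small deterministic annotation for I/O and window tests.
make_genes <- function(n = 6, chrom = "chr1", spacing = 10000, start0 = 5000) {
  tss_plus <- start0 + (seq_len(n) - 1) * spacing
  strand <- rep_len(c("+", "-"), n)
  start <- ifelse(strand == "+", tss_plus, tss_plus - 1500)
  end <- ifelse(strand == "+", tss_plus + 1500, tss_plus + 1)
  data.frame(gene_id = sprintf("NM_%03d", seq_len(n)),
             gene_name = sprintf("G%d", seq_len(n)),
             chrom = chrom, strand = strand,
             start = as.integer(start), end = as.integer(end),
             stringsAsFactors = FALSE)
}
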