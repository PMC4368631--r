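make_reads <- function(chrom, start, end, strand) {
  data.frame(chrom = chrom, start = as.integer(start), end = as.integer(end),
             name = sprintf("r%d", seq_along(start)), score = 0L,
             strand = strand, stringsAsFactors = FALSE)
}

test_that("deduplication keys on (chrom, 5' position, strand)", {
  rd <- make_reads("chr1", c(100, 100), c(150, 150), c("+", "+"))
  expect_equal(nrow(deduplicate_reads(rd)), 1L)

  # same position, opposite strands: both kept
  rd <- make_reads("chr1", c(100, 51), c(150, 101), c("+", "-"))
  expect_equal(nrow(deduplicate_reads(rd)), 2L)

  # minus-strand key is the 5' (right) end: same span -> duplicate
  rd <- make_reads("chr1", c(100, 100), c(150, 150), c("-", "-"))
  expect_equal(nrow(deduplicate_reads(rd)), 1L)

  expect_equal(nrow(deduplicate_reads(rd[0, ])), 0L)
})

test_that("read extension is 5'-anchored, clamped to the read span, and clipped", {
  sizes <- c(chr1 = 1000)
  plus <- make_reads("chr1", 100, 150, "+")
  expect_equal(extend_reads(plus, 200, sizes)[, c("start", "end")],
               data.frame(start = 100L, end = 300L))
  minus <- make_reads("chr1", 250, 300, "-")
  expect_equal(extend_reads(minus, 200, sizes)[, c("start", "end")],
               data.frame(start = 100L, end = 300L))
  # fragment shorter than the read: keep at least the read span
  expect_equal(extend_reads(plus, 50, sizes)[, c("start", "end")],
               data.frame(start = 100L, end = 150L))
  # clipping at both chromosome ends
  expect_equal(extend_reads(make_reads("chr1", 950, 990, "+"), 200,
                            sizes)$end, 1000L)
  expect_equal(extend_reads(make_reads("chr1", 10, 60, "-"), 200,
                            sizes)$start, 0L)
  expect_error(extend_reads(make_reads("chr1", 990, 1050, "+"), 200, sizes),
               "beyond chromosome")
})

test_that("coverage equals the per-base loop oracle and conserves mass", {
  sizes <- c(chr1 = 8)
  fr <- data.frame(chrom = "chr1", start = 2L, end = 5L)
  expect_equal(build_coverage(fr, sizes)$values$chr1,
               c(0, 0, 1, 1, 1, 0, 0, 0))
  expect_equal(build_coverage(rbind(fr, fr), sizes)$values$chr1,
               2 * c(0, 0, 1, 1, 1, 0, 0, 0))

  set.seed(11)
  L <- 10000
  n <- 1000
  s <- sample.int(L - 300, n)
  fr <- data.frame(chrom = "chr1", start = s,
                   end = s + sample(50:300, n, TRUE))
  cov <- build_coverage(fr, c(chr1 = L))$values$chr1
  expect_equal(sum(cov), sum(fr$end - fr$start))
  expect_equal(cov, oracle_coverage(fr, L))
})

test_that("per-million scaling is the exact linear map and needs a library size", {
  v <- c(0, 3, 5, 1)
  tr <- coverage_track(list(chr1 = v), library_size = 1e6)
  expect_equal(normalize_per_million(tr)$values$chr1, v)
  tr$library_size <- 2e6
  expect_equal(normalize_per_million(tr)$values$chr1, v / 2)
  tr$library_size <- 1234
  expect_equal(sum(normalize_per_million(tr)$values$chr1),
               sum(v) * 1e6 / 1234)
  tr$library_size <- 0
  expect_error(normalize_per_million(tr), "positive")
})

test_that("smoothing is a truncated centered moving average", {
  tr <- coverage_track(list(chr1 = rep(4, 50)), library_size = 1)
  expect_equal(smooth_track(tr, 11)$values$chr1, rep(4, 50))

  # interior unit impulse spreads to value 1/w across w bases
  v <- numeric(101); v[51] <- 1
  sm <- smooth_track(coverage_track(list(chr1 = v)), 11)$values$chr1
  expect_equal(sm[46:56], rep(1 / 11, 11))
  expect_equal(sum(sm > 0), 11)

  # mass preserved when the signal sits w zeros away from both ends
  set.seed(5)
  inner <- runif(200)
  v <- c(numeric(21), inner, numeric(21))
  sm <- smooth_track(coverage_track(list(chr1 = v)), 21)$values$chr1
  expect_equal(sum(sm), sum(v), tolerance = 1e-12)

  # an even window is widened to remain centered: 1000 behaves as 1001
  v <- numeric(3000); v[1500] <- 1
  expect_equal(sum(smooth_track(coverage_track(list(chr1 = v)),
                                1000)$values$chr1 > 0), 1001)
})

test_that("the track state machine only moves forward", {
  tr <- coverage_track(list(chr1 = rep(1, 10)), library_size = 10)
  sm <- smooth_track(tr)
  expect_error(normalize_per_million(sm), "state")
  qn <- quantile_normalize(list(sm, sm))[[1]]
  expect_error(smooth_track(qn), "state")
  expect_error(quantile_normalize(list(sm, qn)), "different states")
})

test_that("quantile normalization equalizes distributions with rank means", {
  tr1 <- coverage_track(list(chr1 = c(1, 2, 3)), state = "raw")
  tr2 <- coverage_track(list(chr1 = c(4, 5, 6)), state = "raw")
  out <- quantile_normalize(list(tr1, tr2))
  expect_equal(out[[1]]$values$chr1, c(2.5, 3.5, 4.5))
  expect_equal(out[[2]]$values$chr1, c(2.5, 3.5, 4.5))

  # identical tracks are a fixed point
  out <- quantile_normalize(list(tr1, tr1))
  expect_equal(out[[1]]$values$chr1, c(1, 2, 3))

  # ties share the mean of the quantile values their ranks span
  out <- quantile_normalize(list(coverage_track(list(chr1 = c(1, 1, 2))),
                                 coverage_track(list(chr1 = c(1, 2, 3)))))
  expect_equal(out[[1]]$values$chr1, c(1.25, 1.25, 2.5))
  expect_equal(out[[2]]$values$chr1, c(1, 1.5, 2.5))

  # rank order within a sample is preserved
  set.seed(9)
  trs <- lapply(1:3, function(i) coverage_track(list(chr1 = runif(500))))
  out <- quantile_normalize(trs)
  for (i in 1:3)
    expect_equal(order(out[[i]]$values$chr1), order(trs[[i]]$values$chr1))

  expect_error(quantile_normalize(list(tr1,
    coverage_track(list(chr1 = c(1, 2, 3, 4))))), "mismatched")
})

test_that("meta-profiles bin oriented TSS windows and mirror under strand flip", {
  L <- 10000
  tr <- coverage_track(list(chr1 = rep(2.5, L)), state = "smoothed")
  tss <- data.frame(chrom = "chr1", tss = c(3000L, 7000L),
                    strand = c("+", "-"))
  prof <- meta_profile(tr, tss, flank_bp = 1000, bin_bp = 50)
  expect_equal(nrow(prof), 40)
  expect_equal(prof$signal, rep(2.5, 40))
  expect_equal(prof$bin_center, seq(-975, 975, by = 50))

  # asymmetric signal: a minus-strand profile on the reflected genome
  # equals the plus-strand profile on the original
  set.seed(21)
  v <- runif(L)
  t_plus <- 4000L
  p_plus <- meta_profile(coverage_track(list(chr1 = v)),
                         data.frame(chrom = "chr1", tss = t_plus, strand = "+"),
                         1000, 50)
  p_minus <- meta_profile(coverage_track(list(chr1 = rev(v))),
                          data.frame(chrom = "chr1", tss = L - 1L - t_plus,
                                     strand = "-"),
                          1000, 50)
  expect_equal(p_minus$signal, p_plus$signal)

  # TSS too close to an end is skipped with a warning
  expect_warning(
    meta_profile(tr, data.frame(chrom = "chr1", tss = c(500L, 5000L),
                                strand = c("+", "+")), 1000, 50),
    "skipping")
  expect_error(meta_profile(tr, tss[0, ], 1000, 50), "empty TSS")
})
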