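test_that("median-of-ratios size factors match hand evaluation", {
  m <- matrix(c(10, 30, 20, 60), nrow = 2,
              dimnames = list(c("g1", "g2"), c("s1", "s2")))
  sf <- size_factors(m)
  expect_equal(unname(sf), c(1 / sqrt(2), sqrt(2)), tolerance = 1e-4,
               ignore_attr = TRUE)
  expect_equal(attr(sf, "geo_mean"), 1, tolerance = 1e-12)

  m2 <- matrix(rep(c(5, 9, 40), 3), ncol = 3)
  expect_equal(unname(size_factors(m2)), c(1, 1, 1), ignore_attr = TRUE)

  expect_error(size_factors(matrix(c(0, 1, 2, 0), 2)), "all-positive")
})

test_that("size factors are scale-equivariant", {
  set.seed(31)
  for (rep in 1:5) {
    m <- matrix(rnbinom(400 * 4, mu = 50, size = 5) + 1, ncol = 4)
    sf <- size_factors(m)
    m2 <- m
    m2[, 2] <- m2[, 2] * 3
    sf2 <- size_factors(m2)
    # scaling sample 2 by c multiplies its factor by c relative to every
    # other sample (the shared geometric-mean reference rescales too)
    expect_equal((sf2[2] / sf2[-2]) / (sf[2] / sf[-2]), rep(3, 3),
                 tolerance = 1e-9, ignore_attr = TRUE)
    expect_equal(sf2[-2] / sf2[1], sf[-2] / sf[1], tolerance = 1e-9)
  }
})

test_that("dispersion estimation hits the floor for constant counts and
           recovers simulated truth", {
  groups <- rep(c("patient", "control"), c(2, 4))
  m <- matrix(100L, nrow = 5, ncol = 6)
  a <- estimate_dispersion(m, rep(1, 6), groups, shrink = FALSE)
  expect_true(all(a == 1e-8))

  # Poisson counts: excess dispersion near zero
  set.seed(41)
  m <- matrix(rpois(2000 * 6, 100), ncol = 6)
  a <- estimate_dispersion(m, rep(1, 6), groups, shrink = FALSE)
  expect_lte(median(a), 0.01)

  # NB alpha = 0.2 recovered within a factor
  m <- matrix(rnbinom(2000 * 6, mu = 100, size = 5), ncol = 6)
  a <- estimate_dispersion(m, rep(1, 6), groups, shrink = FALSE)
  expect_gte(median(a), 0.1)
  expect_lte(median(a), 0.3)

  # between-group differences do not inflate the pooled estimate
  m <- matrix(rpois(2000 * 6, rep(c(400, 400, 100, 100, 100, 100),
                                  each = 2000)), ncol = 6)
  a <- estimate_dispersion(m, rep(1, 6), groups, shrink = FALSE)
  expect_lte(median(a), 0.01)
})

test_that("the exact conditional NB test matches its defining properties", {
  # equal summed size factors and equal counts: the observed split is the
  # mode, every split qualifies
  expect_equal(nb_exact_test(30, 30, c(1, 1), c(1, 1), 0.1), 1)
  # group swap symmetry
  p1 <- nb_exact_test(40, 10, c(1, 0.5), c(2, 1, 1, 0.5), 0.05)
  p2 <- nb_exact_test(10, 40, c(2, 1, 1, 0.5), c(1, 0.5), 0.05)
  expect_equal(p1, p2, tolerance = 1e-12)
  # zero total
  expect_equal(nb_exact_test(0, 0, 1, 1, 0.1), 1)
  # p in (0, 1]
  expect_gt(nb_exact_test(1000, 10, c(1, 1), c(1, 1, 1, 1), 0.01), 0)
})

test_that("nb_exact_test equals brute-force enumeration over all splits", {
  configs <- list(
    list(sfA = c(1, 1), sfB = c(1, 1, 1, 1), alpha = 0.1),
    list(sfA = c(0.5, 2), sfB = c(1, 1.5), alpha = 0.05),
    list(sfA = 1, sfB = 3, alpha = 0.5)
  )
  for (cf in configs) {
    for (kS in c(1, 2, 7, 20, 50)) {
      for (kA in 0:kS) {
        expect_equal(nb_exact_test(kA, kS - kA, cf$sfA, cf$sfB, cf$alpha),
                     oracle_nb_exact_p(kA, kS - kA, cf$sfA, cf$sfB, cf$alpha),
                     tolerance = 1e-12)
      }
    }
  }
})

test_that("dispersion zero reduces to the probability-ordered binomial test", {
  # With equal per-sample factors and alpha = 0, conditioning on the total
  # makes the split binomial with prob sA / (sA + sB).
  sfA <- c(1, 1); sfB <- c(1, 1, 1, 1)
  pr <- sum(sfA) / (sum(sfA) + sum(sfB))
  for (kS in c(10, 100, 200)) {
    for (kA in c(0, kS %/% 3, kS %/% 2, kS)) {
      b <- dbinom(0:kS, kS, pr)
      p_bin <- sum(b[b <= b[kA + 1] * (1 + 1e-7)])
      expect_equal(nb_exact_test(kA, kS - kA, sfA, sfB, 0), p_bin,
                   tolerance = 1e-10)
    }
  }
})

test_that("log2 fold change is pseudocount-protected and scale-invariant", {
  groups <- c("patient", "patient", "control", "control")
  m <- matrix(c(40, 40, 10, 10, 40, 40, 10, 10), nrow = 2, byrow = TRUE)
  lfc <- log2_fold_change(m, rep(1, 4), groups)
  expect_equal(unname(lfc), rep(log2(41 / 11), 2))

  m0 <- matrix(0, 2, 4)
  expect_equal(unname(log2_fold_change(m0, rep(1, 4), groups)), c(0, 0))

  m1 <- matrix(c(12, 10, 9, 14), 1)
  expect_equal(unname(log2_fold_change(m1, rep(1, 4), groups)),
               unname(log2_fold_change(2 * m1, rep(2, 4), groups)))
})

test_that("significance selection applies the any-mark fold/p rule", {
  mk_tab <- function(lfc, p) data.frame(gene_id = "g", log2FC = lfc, pval = p)
  tabs <- list(H3K4me3 = mk_tab(1.5, 0.01), H3K27me3 = mk_tab(0.1, 0.5),
               H3K9ac = mk_tab(0.2, 0.9))
  expect_true(select_significant(tabs)$selected)

  tabs <- list(H3K4me3 = mk_tab(0.5, 1e-9), H3K27me3 = mk_tab(0.5, 1e-9),
               H3K9ac = mk_tab(0.5, 1e-9))
  expect_false(select_significant(tabs)$selected)

  # sign-agnostic, any-mark
  tabs <- list(H3K4me3 = mk_tab(0.1, 0.9), H3K27me3 = mk_tab(-2, 0.04),
               H3K9ac = mk_tab(0, 1))
  sel <- select_significant(tabs)
  expect_true(sel$selected)
  expect_true(sel$H3K27me3)
  expect_false(sel$H3K4me3)

  bad <- list(a = mk_tab(1, 1), b = data.frame(gene_id = "h", log2FC = 1,
                                               pval = 1))
  expect_error(select_significant(bad), "mismatched")
})

test_that("null NB counts at 2 vs 4 give calibrated or conservative p-values", {
  cfg <- simulation_config(n_genes = 2000, archetype_fractions = numeric(0),
                           seed = 303)
  truth <- data.frame(gene_id = sprintf("g%04d", 1:2000),
                      archetype = "unchanged",
                      baseline = rep(105, 2000))
  for (mk in cfg$marks) truth[[paste0("effect_", mk)]] <- 0
  tb <- differential_table(simulate_count_matrix(truth, "H3K4me3", cfg))
  expect_lte(mean(tb$pval <= 0.05), 0.08)
  expect_true(all(tb$pval > 0 & tb$pval <= 1))
})
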