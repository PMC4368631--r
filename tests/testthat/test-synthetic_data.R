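# Small config used across the generator tests.
tiny_cfg <- function(...) {
  args <- utils::modifyList(list(n_chroms = 2, chrom_length = 3e5,
                                 n_genes = 200, library_size = 3e4,
                                 seed = 101),
                            list(...))
  do.call(simulation_config, args)
}

test_that("the simulated genome is deterministic, disjoint, and complete", {
  cfg <- tiny_cfg()
  g1 <- simulate_genome(cfg)
  g2 <- simulate_genome(cfg)
  expect_identical(g1, g2)

  expect_equal(nrow(g1$genes), cfg$n_genes)

  w <- promoter_windows(g1$genes, chrom_sizes = g1$chrom_sizes)
  for (chrom in names(g1$chrom_sizes)) {
    ws <- w[w$chrom == chrom, ]
    ws <- ws[order(ws$start), ]
    expect_true(all(ws$start[-1] >= ws$end[-nrow(ws)]))
  }
  # TSSs at least 2 kb from chromosome ends
  expect_true(all(w$tss >= 2000 & w$tss <= cfg$chrom_length - 2000))

  expect_error(simulate_genome(tiny_cfg(n_genes = 10000)), "too large")
})

test_that("archetype assignment implants the configured effects", {
  cfg <- simulation_config(n_chroms = 4, chrom_length = 1.2e6,
                           n_genes = 2000, seed = 5)
  g <- simulate_genome(cfg)
  truth <- assign_archetypes(g$genes, cfg)
  expect_equal(sum(truth$archetype == "silenced"), 100)
  expect_equal(sum(truth$archetype == "active"), 100)
  expect_equal(sum(truth$archetype == "unchanged"), 1800)

  sil <- truth$archetype == "silenced"
  expect_true(all(truth$effect_H3K4me3[sil] == -2))
  expect_true(all(truth$effect_H3K27me3[sil] == 2))
  expect_true(all(truth$effect_H3K9ac[sil] == -2))
  act <- truth$archetype == "active"
  expect_true(all(truth$effect_H3K4me3[act] == 2))
  unc <- truth$archetype == "unchanged"
  for (mk in cfg$marks)
    expect_true(all(truth[[paste0("effect_", mk)]][unc] == 0))

  # empty fractions: everything unchanged
  cfg0 <- tiny_cfg(archetype_fractions = numeric(0))
  t0 <- assign_archetypes(simulate_genome(cfg0)$genes, cfg0)
  expect_true(all(t0$archetype == "unchanged"))
  expect_true(all(t0$effect_H3K4me3 == 0))

  expect_error(tiny_cfg(archetype_fractions = c(nosuch = 0.1)),
               "effect-table")
})

test_that("read simulation is deterministic per (seed, mark, group, sample)", {
  cfg <- tiny_cfg()
  g <- simulate_genome(cfg)
  truth <- assign_archetypes(g$genes, cfg)
  r1 <- simulate_sample_reads(g, truth, "H3K4me3", "patient", 1, cfg)
  r2 <- simulate_sample_reads(g, truth, "H3K4me3", "patient", 1, cfg)
  expect_identical(r1, r2)
  r3 <- simulate_sample_reads(g, truth, "H3K4me3", "patient", 2, cfg)
  expect_false(identical(r1, r3))
  expect_error(simulate_sample_reads(g, truth, "H3K36me3", "patient", 1, cfg),
               "unknown mark")
})

test_that("with no background, every fragment midpoint lies within 1 kb of a TSS", {
  cfg <- tiny_cfg(background_fraction = 0)
  g <- simulate_genome(cfg)
  truth <- assign_archetypes(g$genes, cfg)
  rd <- simulate_sample_reads(g, truth, "H3K9ac", "control", 2, cfg)
  frag_start <- ifelse(rd$strand == "+", rd$start,
                       rd$end - cfg$fragment_length)
  mid <- frag_start + cfg$fragment_length / 2
  tss_by_chrom <- split(promoter_windows(g$genes,
                                         chrom_sizes = g$chrom_sizes)$tss,
                        promoter_windows(g$genes,
                                         chrom_sizes = g$chrom_sizes)$chrom)
  mindist <- vapply(seq_len(nrow(rd)), function(i) {
    min(abs(mid[i] - tss_by_chrom[[rd$chrom[i]]]))
  }, numeric(1))
  expect_true(all(mindist <= 1001))
})

test_that("library totals scale with the per-sample depth multipliers", {
  # implant-free so every library's expected total is library_size x factor
  cfg <- tiny_cfg(archetype_fractions = numeric(0))
  g <- simulate_genome(cfg)
  truth <- assign_archetypes(g$genes, cfg)
  sf <- true_size_factors(cfg)
  expect_equal(unname(sf), c(0.5, 1, 2, 0.5, 1, 2))
  for (sid in c("P2", "C3")) {
    grp <- if (startsWith(sid, "P")) "patient" else "control"
    idx <- as.integer(substring(sid, 2))
    rd <- simulate_sample_reads(g, truth, "H3K27me3", grp, idx, cfg)
    expected <- cfg$library_size * sf[[sid]]
    expect_lt(abs(nrow(rd) - expected) / expected, 0.05)
  }
})

test_that("promoter counts approach the Poisson limit at dispersion zero", {
  # 200 replicate draws of one promoter with mean 100: the empirical mean
  # stays within 3 standard errors of 100
  cfg <- simulation_config(n_chroms = 1, chrom_length = 2e4, n_genes = 1,
                           library_size = 100, background_fraction = 0,
                           dispersion = 0, size_factor_cycle = 1,
                           archetype_fractions = numeric(0), seed = 1)
  g <- simulate_genome(cfg)
  counts <- vapply(1:200, function(i) {
    cfg_i <- cfg; cfg_i$seed <- i
    truth <- assign_archetypes(g$genes, cfg_i)
    nrow(simulate_sample_reads(g, truth, "H3K4me3", "control", 1, cfg_i))
  }, numeric(1))
  se <- sqrt(100 / 200)
  expect_lt(abs(mean(counts) - 100), 3 * se)
})

test_that("a written dataset is byte-identical under regeneration", {
  cfg <- tiny_cfg(n_genes = 50, library_size = 5000)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  simulate_dataset(cfg, d1)
  simulate_dataset(cfg, d2)
  files <- list.files(d1)
  expect_true(length(files) >= 4 + 4 * 6)  # metadata + 4 libraries x 6 samples
  for (f in files)
    expect_identical(readLines(file.path(d2, f)), readLines(file.path(d1, f)),
                     label = f)
  # input libraries are pure background (no promoter concentration needed,
  # just existence and size here)
  inp <- read_bed_reads(file.path(d1, "P1_input.bed"))
  expect_gt(nrow(inp), 0)
})
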