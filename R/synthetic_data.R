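# Seeded generator for aligned-read datasets with the statistical
# structure the analysis assumes: three histone marks plus an input
# library, two patients versus four controls, promoter-localized signal
# with implanted differential chromatin-state archetypes, and a ground
# truth table for every downstream stage.

.DEFAULT_ARCHETYPES <- list(
  silenced = c(H3K4me3 = -2, H3K27me3 = 2, H3K9ac = -2),
  active   = c(H3K4me3 = 2, H3K27me3 = -2, H3K9ac = 2)
)

#' Build a simulation configuration
#'
#' The defaults mirror the study design the pipeline targets: three marks
#' (H3K4me3, H3K27me3, H3K9ac) plus an input library of pure background,
#' 2 patients versus 4 controls, 200 bp fragments, 50 bp reads, and
#' silenced/active archetypes implanted at |log2 effect| = 2 in 5% of
#' genes each. Sample sequencing depths are modulated by size-factor
#' multipliers cycling 0.5, 1, 2 so depth-normalization is exercised.
#'
#' @param n_chroms number of chromosomes.
#' @param chrom_length length of each chromosome (bp).
#' @param n_genes number of genes, placed with disjoint +/- 1 kb promoter
#'   windows.
#' @param marks histone mark names.
#' @param group_sizes `c(patients, controls)`.
#' @param library_size expected reads per sample at size factor 1.
#' @param fragment_length,read_length fragment and read length (bp).
#' @param background_fraction fraction of each library placed uniformly.
#' @param dispersion NB dispersion of promoter counts.
#' @param archetype_table named list: per archetype, named vector of
#'   per-mark log2 effects (patients vs controls).
#' @param archetype_fractions named numeric: fraction of genes per
#'   archetype; the remainder is unchanged.
#' @param size_factor_cycle per-sample depth multipliers, recycled over
#'   samples (patients first, then controls).
#' @param seed master seed; every random stream is derived from it.
#' @return list of class `sim_config`.
#' @export
simulation_config <- function(n_chroms = 4, chrom_length = 1.2e6,
                              n_genes = 2000,
                              marks = c("H3K4me3", "H3K27me3", "H3K9ac"),
                              group_sizes = c(2, 4),
                              library_size = 3e5,
                              fragment_length = 200, read_length = 50,
                              background_fraction = 0.3,
                              dispersion = 0.05,
                              archetype_table = .DEFAULT_ARCHETYPES,
                              archetype_fractions = c(silenced = 0.05,
                                                      active = 0.05),
                              size_factor_cycle = c(0.5, 1, 2),
                              seed = 1) {
  cfg <- list(n_chroms = n_chroms, chrom_length = chrom_length,
              n_genes = n_genes, marks = marks, group_sizes = group_sizes,
              library_size = library_size, fragment_length = fragment_length,
              read_length = read_length,
              background_fraction = background_fraction,
              dispersion = dispersion, archetype_table = archetype_table,
              archetype_fractions = archetype_fractions,
              size_factor_cycle = size_factor_cycle, seed = as.integer(seed))
  stopifnot(cfg$n_chroms >= 1, cfg$chrom_length > 8000, cfg$n_genes >= 1,
            all(cfg$group_sizes >= 1), cfg$library_size > 0,
            cfg$fragment_length >= 1, cfg$read_length >= 1,
            cfg$background_fraction >= 0, cfg$background_fraction <= 1,
            cfg$dispersion >= 0)
  if (length(cfg$archetype_fractions)) {
    stopifnot(all(cfg$archetype_fractions >= 0),
              sum(cfg$archetype_fractions) <= 1)
    unknown <- setdiff(names(cfg$archetype_fractions),
                       names(cfg$archetype_table))
    if (length(unknown))
      stop("archetype without an effect-table row: ",
           paste(unknown, collapse = ", "))
    for (a in names(cfg$archetype_table)) {
      miss <- setdiff(cfg$marks, names(cfg$archetype_table[[a]]))
      if (length(miss))
        stop("archetype '", a, "' missing effect for mark: ",
             paste(miss, collapse = ", "))
    }
  }
  class(cfg) <- "sim_config"
  cfg
}

# Independent stream per (purpose, mark, group, sample): a documented
# arithmetic key on the master seed, kept below 2^31.
.sim_seed <- function(cfg, purpose, mark_index = 0L, group_code = 0L,
                      sample_index = 0L) {
  p <- switch(purpose, genome = 1, truth = 2, reads = 3, counts = 4,
              stop("unknown stream purpose"))
  as.integer((as.numeric(cfg$seed) * 48271 + p * 1299709 +
                mark_index * 104729 + group_code * 7919 + sample_index * 101) %%
               2147483629)
}

#' Per-sample depth multipliers
#'
#' Recycles `size_factor_cycle` over samples (patients first, then
#' controls). These are the true size factors the median-of-ratios
#' estimator should recover.
#'
#' @param cfg a `sim_config`.
#' @return named numeric vector, one entry per sample (P1.., C1..).
#' @export
true_size_factors <- function(cfg) {
  n <- sum(cfg$group_sizes)
  sf <- rep_len(cfg$size_factor_cycle, n)
  stats::setNames(sf, sample_ids(cfg))
}

#' Sample ids in canonical order (patients then controls)
#' @param cfg a `sim_config`.
#' @return character vector, e.g. `c("P1","P2","C1","C2","C3","C4")`.
#' @export
sample_ids <- function(cfg) {
  c(paste0("P", seq_len(cfg$group_sizes[1L])),
    paste0("C", seq_len(cfg$group_sizes[2L])))
}

#' Group labels per sample
#' @param cfg a `sim_config`.
#' @return named character vector (`patient` / `control`).
#' @export
sample_groups <- function(cfg) {
  stats::setNames(rep(c("patient", "control"), cfg$group_sizes),
                  sample_ids(cfg))
}

#' Simulate a genome: chromosome sizes and a gene annotation
#'
#' Genes are spread evenly over the chromosomes on alternating strands,
#' with uniformly jittered TSS positions constrained so that all +/- 1 kb
#' promoter windows are pairwise disjoint and every TSS is at least 2 kb
#' from a chromosome end. Deterministic given the config seed.
#'
#' @param cfg a `sim_config`.
#' @return list with `chrom_sizes` (named vector) and `genes`
#'   (annotation data.frame as from [read_annotation()]).
#' @export
simulate_genome <- function(cfg) {
  set.seed(.sim_seed(cfg, "genome"))
  chroms <- paste0("chr", seq_len(cfg$n_chroms))
  sizes <- stats::setNames(rep(as.integer(cfg$chrom_length), cfg$n_chroms),
                           chroms)
  per_chrom <- diff(round(seq(0, cfg$n_genes, length.out = cfg$n_chroms + 1)))
  usable <- cfg$chrom_length - 4000
  if (max(per_chrom) * 2100 > usable)
    stop("simulate_genome: n_genes too large for the requested genome")
  rows <- list()
  gi <- 0L
  for (ci in seq_len(cfg$n_chroms)) {
    n <- per_chrom[ci]
    if (n == 0L) next
    spacing <- usable / n
    jitter <- floor(stats::runif(n, 0, spacing - 2050))
    tss <- as.integer(2000 + (seq_len(n) - 1L) * spacing + jitter)
    strand <- rep_len(c("+", "-"), n)
    body_len <- 1500L
    start <- ifelse(strand == "+", tss,
                    pmax(tss + 1L - body_len, 0L))
    end <- ifelse(strand == "+",
                  pmin(tss + body_len, as.integer(cfg$chrom_length)),
                  tss + 1L)
    ids <- gi + seq_len(n)
    rows[[ci]] <- data.frame(
      gene_id = sprintf("NM_%05d", ids),
      gene_name = sprintf("GENE%d", ids),
      chrom = chroms[ci], strand = strand,
      start = as.integer(start), end = as.integer(end),
      stringsAsFactors = FALSE)
    gi <- gi + n
  }
  genes <- do.call(rbind, rows)
  rownames(genes) <- NULL
  list(chrom_sizes = sizes, genes = genes)
}

#' Assign differential archetypes and baselines: the ground-truth table
#'
#' `round(fraction x n_genes)` genes per archetype receive that
#' archetype's per-mark log2 effects (patients vs controls); the rest are
#' unchanged with all effects 0. Baseline mean promoter counts are drawn
#' from a Gamma(5) distribution scaled so the expected promoter reads per
#' sample (at size factor 1) total `(1 - background_fraction) x
#' library_size`. Deterministic given the config seed.
#'
#' @param genes annotation data.frame from [simulate_genome()].
#' @param cfg a `sim_config`.
#' @return data.frame with `gene_id`, `archetype`, `baseline`, and one
#'   `effect_<mark>` column per mark.
#' @export
assign_archetypes <- function(genes, cfg) {
  set.seed(.sim_seed(cfg, "truth"))
  n <- nrow(genes)
  archetype <- rep("unchanged", n)
  if (length(cfg$archetype_fractions)) {
    counts <- round(cfg$archetype_fractions * n)
    if (sum(counts) > n) stop("archetype fractions exceed the gene count")
    pool <- sample.int(n, sum(counts))
    offset <- 0L
    for (a in names(counts)) {
      if (counts[[a]] > 0)
        archetype[pool[offset + seq_len(counts[[a]])]] <- a
      offset <- offset + counts[[a]]
    }
  }
  signal_total <- (1 - cfg$background_fraction) * cfg$library_size
  baseline <- stats::rgamma(n, shape = 5, rate = 1)
  baseline <- baseline * signal_total / sum(baseline)
  truth <- data.frame(gene_id = genes$gene_id, archetype = archetype,
                      baseline = baseline, stringsAsFactors = FALSE)
  for (mk in cfg$marks) {
    eff <- numeric(n)
    for (a in names(cfg$archetype_table)) {
      eff[archetype == a] <- cfg$archetype_table[[a]][[mk]]
    }
    truth[[paste0("effect_", mk)]] <- eff
  }
  truth
}

.nb_draw <- function(n, mu, dispersion) {
  if (dispersion <= 0) stats::rpois(n, lambda = mu)
  else stats::rnbinom(n, mu = mu, size = 1 / dispersion)
}

#' Simulate a promoter count matrix directly (no reads)
#'
#' Draws the per-gene, per-sample promoter counts of one mark from the
#' same NB model the read-level simulator uses — mean `baseline x
#' 2^(effect if patient) x size factor`, dispersion from the config —
#' without placing reads. Useful for count-level calibration studies.
#'
#' @param truth ground-truth table from [assign_archetypes()].
#' @param mark mark name.
#' @param cfg a `sim_config`.
#' @return a `promoter_count_matrix`.
#' @export
simulate_count_matrix <- function(truth, mark, cfg) {
  if (!mark %in% cfg$marks) stop("unknown mark: ", mark)
  mi <- match(mark, cfg$marks)
  sf <- true_size_factors(cfg)
  groups <- sample_groups(cfg)
  eff <- truth[[paste0("effect_", mark)]]
  set.seed(.sim_seed(cfg, "counts", mark_index = mi))
  counts <- vapply(seq_along(sf), function(j) {
    mu <- truth$baseline * sf[j] *
      (if (groups[j] == "patient") 2^eff else 1)
    .nb_draw(nrow(truth), mu, cfg$dispersion)
  }, numeric(nrow(truth)))
  counts <- matrix(as.integer(counts), nrow = nrow(truth),
                   dimnames = list(truth$gene_id, names(sf)))
  structure(list(mark = mark, counts = counts, groups = groups),
            class = "promoter_count_matrix")
}

# Triangular(-w, 0, +w) midpoint offsets as the sum of two uniforms.
.rtri <- function(n, w) {
  (stats::runif(n) + stats::runif(n) - 1) * w
}

#' Simulate one sample's aligned reads for one mark
#'
#' Per-gene promoter read counts are drawn from
#' `NB(mean = baseline x 2^(effect if patient) x size factor,
#' dispersion)`; each promoter read's fragment midpoint follows a
#' symmetric triangular distribution centered on the TSS spanning
#' +/- 1 kb (the peaked promoter shape the meta-profiles detect), and
#' `background_fraction x library_size x size factor` reads are placed
#' uniformly over the genome. Read strands are random; reads are clipped
#' to chromosome bounds. `mark = "input"` yields pure background.
#' Deterministic given (seed, mark, group, sample index).
#'
#' @param genome list from [simulate_genome()].
#' @param truth ground-truth table from [assign_archetypes()].
#' @param mark one of the config marks, or `"input"`.
#' @param group `"patient"` or `"control"`.
#' @param sample_index index of the sample within its group.
#' @param cfg a `sim_config`.
#' @return read data.frame (BED6 columns).
#' @export
simulate_sample_reads <- function(genome, truth, mark, group, sample_index,
                                  cfg) {
  group <- match.arg(group, c("patient", "control"))
  is_input <- identical(mark, "input")
  if (!is_input && !mark %in% cfg$marks) stop("unknown mark: ", mark)
  mi <- if (is_input) 0L else match(mark, cfg$marks)
  gc <- if (group == "patient") 1L else 2L
  sf_all <- true_size_factors(cfg)
  sample_id <- paste0(if (group == "patient") "P" else "C", sample_index)
  sf <- sf_all[[sample_id]]
  set.seed(.sim_seed(cfg, "reads", mark_index = mi, group_code = gc,
                     sample_index = sample_index))
  sizes <- genome$chrom_sizes
  windows <- promoter_windows(genome$genes, chrom_sizes = sizes)
  mids <- numeric(0); chroms <- character(0)
  if (!is_input) {
    eff <- truth[[paste0("effect_", mark)]]
    mu <- truth$baseline * sf * (if (group == "patient") 2^eff else 1)
    k <- .nb_draw(nrow(truth), mu, cfg$dispersion)
    tss_rep <- rep(windows$tss, k)
    chrom_rep <- rep(windows$chrom, k)
    mids <- round(tss_rep + .rtri(length(tss_rep), 1000))
    chroms <- chrom_rep
  }
  bg_frac <- if (is_input) 1 else cfg$background_fraction
  n_bg <- round(bg_frac * cfg$library_size * sf)
  if (n_bg > 0) {
    bg_chrom <- sample(names(sizes), n_bg, replace = TRUE)
    bg_mid <- floor(stats::runif(n_bg, 0, sizes[bg_chrom]))
    mids <- c(mids, bg_mid)
    chroms <- c(chroms, bg_chrom)
  }
  n <- length(mids)
  if (n == 0L)
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), name = character(), score = integer(),
                      strand = character(), stringsAsFactors = FALSE))
  strand <- sample(c("+", "-"), n, replace = TRUE)
  half <- cfg$fragment_length / 2
  frag_start <- round(mids - half)
  # the read is the 5' read_length of the fragment
  start <- ifelse(strand == "+", frag_start,
                  frag_start + cfg$fragment_length - cfg$read_length)
  start <- pmax(pmin(start, sizes[chroms] - cfg$read_length), 0)
  df <- data.frame(chrom = chroms, start = as.integer(start),
                   end = as.integer(start + cfg$read_length),
                   name = sprintf("%s_%s_r%d", sample_id,
                                  if (is_input) "input" else mark, seq_len(n)),
                   score = 0L, strand = strand, stringsAsFactors = FALSE)
  df <- df[order(df$chrom, df$start, df$end, df$strand), , drop = FALSE]
  df$name <- sprintf("%s_%s_r%d", sample_id,
                     if (is_input) "input" else mark, seq_len(n))
  rownames(df) <- NULL
  df
}

#' Simulate and write a complete dataset
#'
#' Writes per-sample BED files for every mark (plus the input libraries),
#' the annotation TSV, the chromosome sizes, the ground-truth table and a
#' sample sheet into `out_dir`. Regeneration under the same config is
#' byte-identical.
#'
#' @param cfg a `sim_config`.
#' @param out_dir output directory (created if needed).
#' @param input_library also write per-sample input (pure background) BEDs.
#' @return list with `genome`, `truth`, and `files` (named paths).
#' @export
simulate_dataset <- function(cfg, out_dir, input_library = TRUE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  genome <- simulate_genome(cfg)
  truth <- assign_archetypes(genome$genes, cfg)
  files <- list()
  write_annotation(genome$genes, file.path(out_dir, "annotation.tsv"))
  write_chrom_sizes(genome$chrom_sizes, file.path(out_dir, "chrom.sizes"))
  utils::write.table(truth, file.path(out_dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  groups <- sample_groups(cfg)
  sheet <- data.frame(sample = names(groups), group = unname(groups))
  utils::write.table(sheet, file.path(out_dir, "samples.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  marks <- cfg$marks
  if (input_library) marks <- c(marks, "input")
  for (mk in marks) {
    for (g in c("patient", "control")) {
      ng <- cfg$group_sizes[if (g == "patient") 1L else 2L]
      for (i in seq_len(ng)) {
        sid <- paste0(if (g == "patient") "P" else "C", i)
        reads <- simulate_sample_reads(genome, truth, mk, g, i, cfg)
        path <- file.path(out_dir, sprintf("%s_%s.bed", sid, mk))
        write_bed_reads(reads, path)
        files[[sprintf("%s_%s", sid, mk)]] <- path
      }
    }
  }
  list(genome = genome, truth = truth, files = files)
}
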