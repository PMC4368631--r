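---
title: "Differential promoter histone-modification occupancy: models and methods"
author: "promdiff"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Differential promoter histone-modification occupancy: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(promdiff)
```

## The problem

ChIP-seq of promoter-associated histone modifications — H3K4me3 and H3K9ac
(active/poised promoters) and H3K27me3 (repressed promoters) — lets one ask
whether a disease state rewires promoter chromatin. The design this package
targets is the hard, common one: very small groups (here two patients versus
four controls), three marks measured per sample, and the question of which
promoters change, in which direction, and in which combinations across marks
(silenced, activated, or "poised" with active and repressive marks moving
together).

`promdiff` implements the complete chain from aligned reads to labeled
chromatin-state clusters, plus a generator of synthetic datasets with known
ground truth so every stage is testable without any external download.

## Coordinates and formats

All internal coordinates are 0-based, half-open `[start, end)`. BED and
refFlat files are native to this convention and are parsed without shifting.
Genome-browser-style printed ranges such as `chr2:102,282,711-102,874,166`
are imported as `start = first, end = second`, so the region length is
`end - start` (591,455 bp for that example). The TSS of a minus-strand
transcript is `end - 1`, the 5'-most transcribed base.

Promoter windows span 1 kb on each side of the TSS. For a plus-strand TSS
`t` the window is `[t - 1000, t + 1000)`; for a minus-strand TSS it is the
exact mirror image `[t - 999, t + 1001)`. This makes every windowed
computation invariant under reflection of the genome, a property the test
suite checks explicitly.

## Coverage tracks and meta-profiles

Tracks move through a one-way normalization chain,
`raw -> per_million -> smoothed -> quantile_normalized`, and operations
refuse tracks in the wrong state:

1. **Deduplication.** At most one read per (chromosome, 5' position,
   strand); PCR duplicates collapse, opposite-strand reads at the same
   position do not.
2. **Fragment extension.** Each read extends from its 5' end to the
   configured fragment length (default 200 bp, the conventional midpoint of
   typical 150-600 bp sonication distributions; adjust to your library).
   A fragment is never shorter than its read.
3. **Per-million scaling** by `1e6 / library_size`.
4. **Smoothing**: centered moving average in a 1000 bp window (widened to
   1001 bp so it can be centered); at chromosome ends the window truncates
   rather than inventing signal.
5. **Quantile normalization** across the samples of one mark, on the
   concatenated per-base values: rank r in every sample receives the mean
   of the rank-r values across samples. Ties within a sample receive the
   mean of the quantile values their ranks span, which preserves
   within-sample rank order. With tie-free values the operation is exactly
   idempotent and leaves all samples with identical sorted vectors; with
   heavy ties (e.g. long zero runs that differ between samples) those
   identities hold only approximately — the property tests therefore use
   continuous-valued tracks.

Normalization is per-mark by default: different antibodies have genuinely
different signal distributions, and forcing all marks onto one distribution
would be a modeling claim the data do not support.

TSS meta-profiles average the oriented (5'→3', minus-strand windows
mirrored) +/-1 kb windows in 50 bp bins, giving 40 bins per gene and the
peaked average promoter profile that distinguishes promoter-localized marks
from background.

## The count model and the differential test

Promoter counts (default: deduplicated reads whose 5' base falls in the
window; an overlap-based mode exists for sensitivity analysis) are modeled
as negative binomial with variance `mu + alpha * mu^2`.

**Size factors** are median-of-ratios: `s_j = median_i k_ij / g_i` with
`g_i` the geometric mean of gene i across samples, using only genes with
all-positive counts. This estimator is robust to the minority of genuinely
changed promoters and recovers simulated depth factors of 0.5/1/2 to within
a few percent at 2,000 genes.

**Dispersion** is method-of-moments per gene:
`alpha_i = max(floor, (v_i - q_i * xi) / q_i^2)` with `q_i` the mean
normalized count, `xi = mean(1/s_j)`, and `v_i` the *pooled within-group*
variance (denominator n - G). Pooling within groups matters: a variance
taken across both groups would absorb true patient-control differences into
the dispersion and destroy power exactly at the implanted genes one wants to
detect. Because a per-gene estimate at 2 + 4 samples is noisy, the default
adds a conservative trend floor: a log-log linear regression of the raw
estimates on `q` is fitted and each gene receives
`max(raw, trend(q_i))` — under-dispersed flukes are pulled up, genuinely
over-dispersed genes keep their own estimate. The floor is `1e-8`.

**The exact conditional test** compares group-summed counts `K_A`
(patients) and `K_B` (controls) given their total `K_S`. Under the null the
common concentration is `q0 = K_S / (s_A + s_B)` with `s_G` the summed size
factors; group sums are NB with mean `s_G * q0` and variance
`s_G * q0 + alpha * q0^2 * sum_{j in G} s_j^2` (the sum of per-sample NB
variances). The two-sided p-value sums `P(a)P(b)` over all splits
`a + b = K_S` whose probability does not exceed the observed split's,
normalized by the total; dispersion 0 is evaluated as the Poisson limit,
where the test reduces to the probability-ordered conditional binomial
test. Everything is computed in log space and matches a direct enumeration
oracle to 1e-12 for all totals up to 50; at the defaults the cost is
linear in `K_S`.

Fold changes are `log2((mean_patient + 1) / (mean_control + 1))` on
normalized counts, pseudocount-protected, with direction patients versus
controls throughout. A gene is **selected** when `|log2FC| >= 1` and
`p <= 0.05` in at least one mark. These are the defaults because they are
the thresholds stated with the selection rule itself; where a figure legend
elsewhere implies `p < 0.01`, the cutoff is a plain config knob. No
multiple-testing correction is applied by default (the selection rule is
stated on raw p-values); `bh_adjust()` is available and enrichment results
carry BH-adjusted p-values alongside raw ones.

## Clustering and phenotype labels

Selected genes are clustered on their genes x marks log2FC matrix (three
columns) with complete-linkage agglomeration on Euclidean distances —
`stats::hclust`, the same algorithm family the originating analyses in this
field use. The z-scaled count matrix (per-gene, size-factor-normalized,
n - 1 denominator, zero-variance rows mapped to zero) is computed for
heatmap export only, not for clustering: the fold-change matrix is the
stated clustered quantity, and the alternative is available by passing the
z-matrix to `hier_cluster()` directly.

The number of clusters `k` is a required choice — there is no defensible
universal cut height. The analysis scripts use `k = 4` on data with two
implanted archetypes plus noise; an emulation of a richer real dataset
would use a larger k (e.g. 25) and inspect the summary table.

Cluster phenotypes are labeled from per-cluster mean log2FCs with a
magnitude threshold `t = 0.5` log2 units (visual calls in the field
correspond roughly to this): **silenced** = active marks down, H3K27me3
up; **active** = the mirror image; **poised_up/poised_down** = all marks
concordant; otherwise **mixed**. The threshold is configurable; 0.5 is
half the selection threshold so that cluster means diluted by a few
misassigned genes still label correctly.

## Gene-set statistics

Over-representation of a gene set in a cluster is the upper-tail
hypergeometric `P(X >= overlap)` with the universe defined as **all genes
with a quantified promoter** — only those genes could have been selected,
so a larger universe would inflate significance. Sets are intersected with
the universe before testing. Group-versus-background fold-change
comparisons use the two-sample Mann-Whitney U (exact by enumeration when
`n1 * n2 <= 400` and tie-free, otherwise normal approximation with tie and
continuity corrections); the comparison design here is unpaired and
two-sample, and a paired t-test is provided separately for paired designs.

## The synthetic-data generator

The generator emulates the target study's structure: 3 marks + an input
library of pure background, 2 patients vs 4 controls, promoter-localized
enrichment, and implanted differential archetypes

* silenced: H3K4me3 -2, H3K9ac -2, H3K27me3 +2 (log2, patients vs controls),
* active: the mirror image,

each in 5% of genes by default, at NB dispersion 0.05 — moderate
biological replication noise for ChIP-seq promoter counts. Genes are placed
with pairwise-disjoint promoter windows on alternating strands; per-gene
baselines are Gamma(5)-distributed and scaled so the expected signal reads
per library total `(1 - background_fraction) * library_size` (default
background fraction 0.3). Promoter reads have fragment midpoints drawn from
a symmetric triangular distribution spanning +/-1 kb of the TSS — peaked,
like real promoter marks, so meta-profile code sees realistic structure —
and per-sample sequencing depths are modulated by size factors cycling
0.5/1/2, which is what makes size-factor recovery a meaningful test.
Every random stream is derived from the master seed by an arithmetic key
on (purpose, mark, group, sample), so adding a sample never changes
another sample's data, and full regeneration is byte-identical.

What the generator does **not** emulate: mappability and sequence content
(reads are positions, not sequences), PCR-duplicate structure, input-track
biases (the input library is pure background; no input correction is
applied anywhere, since none is part of the modeled workflow),
copy-number variation, and overlapping/multi-TSS gene models. Passing
tests on simulations therefore validate the statistical machinery and the
coordinate conventions, not robustness to those real-data artifacts.

## Numerical choices and degenerate inputs

* NB test: log-space accumulation with a `1 + 1e-7` relative tolerance on
  the observed-probability cutoff (float-equal splits count as ties);
  `K_S = 0` gives p = 1; p is clamped into `(0, 1]`.
* Size factors require at least one all-positive gene and fail with
  guidance otherwise.
* Dispersion of an all-zero or constant gene is the floor.
* Smoothing of an even window widens it by one base; truncation at ends.
* `hclust` ties: resolved by the platform-stable implementation in R's
  `stats`; the test oracle avoids ties by using continuous data.
* Zero-variance rows z-scale to zero rather than NaN.
* Cluster ids are relabeled in leaf order so output is stable.

## Problem sizes

The bundled analysis scripts and the acceptance script run a compact study
(150-300 genes at read level on 2 x 250-400 kb chromosomes; 2,000-5,000
genes at count level), chosen so the full workflow, including per-base
quantile normalization of six tracks, completes in seconds while leaving
every statistical property measurable. All sizes are plain config
parameters; nothing in the implementation assumes these scales.

## Worked mini-example

```{r example}
cfg <- simulation_config(n_chroms = 2, chrom_length = 3e5, n_genes = 200,
                         library_size = 3e4, seed = 1)
genome <- simulate_genome(cfg)
truth <- assign_archetypes(genome$genes, cfg)
tabs <- lapply(stats::setNames(cfg$marks, cfg$marks), function(mk)
  differential_table(simulate_count_matrix(truth, mk, cfg)))
sel <- select_significant(tabs)
fc <- fold_change_matrix(tabs, sel)
asg <- cut_clusters(hier_cluster(fc), 4)
cluster_summary(asg, fc)
```

## Known limitations

* One TSS per gene record; multi-transcript genes must be reduced to a
  representative transcript upstream.
* Quantile normalization loads one mark's tracks into memory; genome-scale
  (3 Gb) per-base use would need the binned mode or chunking.
* The exact test enumerates all splits of `K_S`; totals far beyond 1e6
  would warrant a tail-pruned implementation.
* No input-chromatin correction and no peak calling — promoter windows are
  fixed, annotation-driven intervals.
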