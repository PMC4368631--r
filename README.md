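# promdiff

Differential promoter histone-modification occupancy from multi-mark
ChIP-seq, for small patient-versus-control designs.

Monocytes from sepsis patients, and many other disease states, show
promoter-level chromatin changes: loss of the active marks H3K4me3 and
H3K9ac with gain of repressive H3K27me3 ("silenced" promoters), the mirror
pattern ("activated"), or concordant movement of both ("poised"). Detecting
these combinations from ChIP-seq with only a handful of samples per group
requires count statistics built for few replicates. `promdiff` implements
that analysis end-to-end, plus a ground-truth simulator so the whole chain
is testable offline:

- **Coverage**: read deduplication, 5'-anchored fragment extension,
  per-base coverage, per-million scaling, 1 kb smoothing, rank-based
  quantile normalization across samples; bedGraph export and strand-aware
  TSS meta-profiles in 50 bp bins.
- **Promoter quantification**: TSS ± 1 kb windows (0-based half-open,
  strand-mirrored), gene × sample count matrices per mark.
- **Differential occupancy**: median-of-ratios size factors
  `s_j = median_i k_ij / (prod_v k_iv)^{1/m}`; per-gene NB dispersion
  (method-of-moments on pooled within-group variance, with a conservative
  log-log trend floor); the exact conditional NB test of group-summed
  counts given their total,

  `p = [sum over a+b=K_S with P(a)P(b) <= P(K_A)P(K_B) of P(a)P(b)] / [sum over a+b=K_S of P(a)P(b)]`;

  pseudocount-protected log2 fold changes; any-mark selection at
  `|log2FC| >= 1` and `p <= 0.05`.
- **Chromatin-state clustering**: complete-linkage hierarchical clustering
  of the genes × marks log2FC matrix on Euclidean distances, cluster
  phenotype labels (silenced / active / poised_up / poised_down / mixed),
  z-scaled heatmap matrices, per-cluster meta-profiles.
- **Gene-set statistics**: upper-tail hypergeometric over-representation
  against a quantified-promoter universe (GMT input, BH adjustment), and
  Mann-Whitney U group-versus-background fold-change comparisons.
- **Simulator**: 3 marks + input, 2 patients vs 4 controls, implanted
  silenced/active archetypes at |log2 effect| = 2, NB dispersion 0.05,
  per-sample depth factors cycling 0.5/1/2, triangular promoter signal —
  with a ground-truth table for every gene.

## Worked example

The numbered scripts under `analysis/` run a complete study on simulated
data (300 genes, 3 marks, 2 patients vs 4 controls, 15 + 15 implanted
archetype genes), writing tables under `results/`:

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_coverage_profiles.R
Rscript analysis/03_promoter_counts.R
Rscript analysis/04_differential.R
Rscript analysis/05_clustering.R
Rscript analysis/06_enrichment.R
```

Output of stages 4-6 on this dataset:

```
H3K4me3: size factors 0.50/1.01/1.98/0.50/1.01/1.99 | median dispersion 0.025 | min p 6.9e-23
Selected 29 / 300 genes with >= 2-fold change at p <= 0.05 in at least one mark
Of the 30 implanted genes, 29 are selected (97%)

Clustered 29 selected genes into 4 clusters:
  cluster size mean_lfc_H3K4me3 mean_lfc_H3K27me3 mean_lfc_H3K9ac phenotype
1       1   11           -1.262             1.787           -1.06  silenced
2       2    3           -0.923             1.398           -1.53  silenced
3       3    8            1.444            -0.763            1.58    active
4       4    7            1.851            -1.330            1.50    active
silenced: 14/15 implanted genes recovered, 0 false members
active: 15/15 implanted genes recovered, 0 false members

Cluster gene-set enrichments at p < 0.05:
 cluster                  set overlap     pval
       1    MHC_like_silenced      11 3.70e-17
       2    MHC_like_silenced       3 1.02e-04
       3 immune_response_like       8 4.34e-12
       4 immune_response_like       7 1.59e-10
MHC-like group vs all genes, H3K4me3 log2FC: U = 114, p = 5.47e-10 (medians -1.16 vs -0.02)
```

Reading: the estimated size factors recover the simulated depth cycle
(0.5/1/2); 29 of 30 implanted genes pass the two-fold / p <= 0.05
selection; clustering the selected genes' three-mark fold-change vectors
and labeling cluster means separates the silenced archetype (active marks
down ~1-1.5 log2 units, H3K27me3 up) from the activated one with no false
members; and the synthetic "MHC-like" gene set is strongly
over-represented in the silenced clusters, with its H3K4me3 fold changes
clearly below background (median -1.16 vs -0.02).

The same machinery is available programmatically — `run_pipeline()`
executes all stages from a single validated `run_config()`, and
`vignettes/promoter-occupancy-methods.Rmd` documents the models, defaults
and limitations.

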