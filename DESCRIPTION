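Package: promdiff
Title: Differential Promoter Histone-Modification Occupancy from Multi-Mark ChIP-seq
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for genome-wide promoter histone-modification
    comparisons between small patient and control groups, as used in studies of
    monocyte chromatin in sepsis. From aligned ChIP-seq reads (BED) it builds
    normalized per-base coverage tracks (per-million scaling, 1 kb smoothing,
    rank-based quantile normalization), strand-aware TSS meta-profiles in 50 bp
    bins, promoter (TSS +/- 1 kb) count matrices, negative-binomial differential
    occupancy calls (median-of-ratios size factors, method-of-moments dispersion
    with trend shrinkage, exact conditional test), complete-linkage hierarchical
    clustering of multi-mark log2 fold changes into chromatin-state phenotypes
    (silenced, active, poised), and hypergeometric gene-set over-representation.
    Includes a seeded synthetic-data generator that emulates a three-mark,
    two-patients-versus-four-controls design with implanted differential
    chromatin-state archetypes and ground truth, so the whole pipeline is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
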