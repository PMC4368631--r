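# End-to-end orchestration: reads -> coverage tracks -> promoter counts ->
# differential tables -> clusters and phenotypes -> enrichment, with a
# fixed output layout and a run report.

#' Build a run configuration
#'
#' @param reads named list: `reads[[mark]][[sample]]` = BED path.
#' @param annotation path to the refFlat-style annotation TSV.
#' @param chrom_sizes path to the two-column chromosome sizes TSV.
#' @param groups named character vector: sample id -> `patient`/`control`.
#' @param out_dir output directory.
#' @param gmt optional GMT path for enrichment.
#' @param fragment_length,smooth_window,flank,bin,upstream,downstream
#'   coverage/counting parameters (bp).
#' @param lfc_threshold,p_threshold significance thresholds.
#' @param k number of clusters to cut.
#' @param phenotype_threshold log2 magnitude for phenotype labels.
#' @param counting_mode `"read_5prime"` or `"fragment_overlap"`.
#' @param deduplicate apply the unique-reads filter before counting.
#' @param active_marks,repressive_marks mark roles for phenotype labels.
#' @return list of class `run_config`.
#' @export
run_config <- function(reads, annotation, chrom_sizes, groups, out_dir,
                       gmt = NULL, fragment_length = 200,
                       smooth_window = 1000, flank = 1000, bin = 50,
                       upstream = 1000, downstream = 1000,
                       lfc_threshold = 1, p_threshold = 0.05, k = 4,
                       phenotype_threshold = 0.5,
                       counting_mode = "read_5prime", deduplicate = TRUE,
                       active_marks = c("H3K4me3", "H3K9ac"),
                       repressive_marks = "H3K27me3") {
  cfg <- as.list(environment())
  class(cfg) <- "run_config"
  cfg
}

#' Validate a run configuration
#'
#' Checks every cross-reference (samples vs files vs marks vs groups) and
#' every parameter range, aggregating all violations instead of stopping
#' at the first.
#'
#' @param cfg a `run_config`.
#' @return character vector of violations (length 0 when valid).
#' @export
validate_config <- function(cfg) {
  errs <- character(0)
  add <- function(msg) errs <<- c(errs, msg)
  if (!length(cfg$reads) || is.null(names(cfg$reads)))
    add("reads: need a named list of marks")
  for (mk in names(cfg$reads)) {
    smp <- cfg$reads[[mk]]
    if (is.null(names(smp))) { add(paste0("reads[", mk, "]: unnamed samples")); next }
    for (sid in names(smp)) {
      if (!file.exists(smp[[sid]]))
        add(sprintf("missing reads file for sample %s/%s: %s", sid, mk, smp[[sid]]))
      if (!sid %in% names(cfg$groups))
        add(sprintf("sample %s (%s) has no group label", sid, mk))
    }
  }
  if (!all(cfg$groups %in% c("patient", "control")))
    add("groups must be 'patient' or 'control'")
  if (!any(cfg$groups == "patient") || !any(cfg$groups == "control"))
    add("each group needs at least one sample")
  for (p in c("annotation", "chrom_sizes"))
    if (!file.exists(cfg[[p]])) add(paste0(p, ": no such file: ", cfg[[p]]))
  if (!is.null(cfg$gmt) && !file.exists(cfg$gmt))
    add(paste0("gmt: no such file: ", cfg$gmt))
  if (!(cfg$p_threshold > 0 && cfg$p_threshold <= 1))
    add("p_threshold must be in (0, 1]")
  if (cfg$lfc_threshold < 0) add("lfc_threshold must be >= 0")
  for (p in c("fragment_length", "smooth_window", "flank", "bin", "k"))
    if (cfg[[p]] < 1) add(paste0(p, " must be >= 1"))
  if (cfg$flank %% cfg$bin != 0) add("flank must be a multiple of bin")
  marks <- names(cfg$reads)
  roled <- c(cfg$active_marks, cfg$repressive_marks)
  if (!all(marks %in% roled))
    add(paste0("mark without an active/repressive role: ",
               paste(setdiff(marks, roled), collapse = ", ")))
  errs
}

.log_stage <- function(con, stage, msg) {
  line <- sprintf("[%s] %s: %s", format(Sys.time(), "%H:%M:%S"), stage, msg)
  message(line)
  if (!is.null(con)) writeLines(line, con)
}

#' Run the full pipeline
#'
#' Stages: read + deduplicate, coverage (extend, per-million, smooth,
#' quantile-normalize within each mark), TSS meta-profiles, promoter
#' counting, per-mark differential tables, any-mark significance
#' selection, complete-linkage clustering of the log2FC matrix with
#' phenotype labels and per-cluster profiles, and (when a GMT is given)
#' hypergeometric enrichment per cluster. All outputs are TSV/bedGraph
#' under `out_dir/{coverage,counts,diff,clusters,enrichment,report}`.
#' The pipeline is deterministic: rerunning reproduces identical tables.
#'
#' @param cfg a validated `run_config`.
#' @param write_bedgraphs export per-sample smoothed+normalized tracks
#'   (off by default: large).
#' @return invisibly, a list with the main in-memory results and the
#'   report.
#' @export
run_pipeline <- function(cfg, write_bedgraphs = FALSE) {
  errs <- validate_config(cfg)
  if (length(errs)) stop("invalid config:\n  ", paste(errs, collapse = "\n  "))
  dirs <- file.path(cfg$out_dir, c("coverage", "counts", "diff", "clusters",
                                   "enrichment", "report"))
  for (d in dirs) dir.create(d, recursive = TRUE, showWarnings = FALSE)
  logcon <- file(file.path(cfg$out_dir, "run.log"), "w")
  on.exit(close(logcon))
  report <- list()

  sizes <- read_chrom_sizes(cfg$chrom_sizes)
  genes <- read_annotation(cfg$annotation)
  windows <- promoter_windows(genes, cfg$upstream, cfg$downstream, sizes)
  marks <- names(cfg$reads)

  tracks <- list(); count_mats <- list(); diff_tables <- list()
  dedup_stats <- list()
  for (mk in marks) {
    sample_reads <- lapply(cfg$reads[[mk]], read_bed_reads)
    if (cfg$deduplicate) {
      kept <- lapply(sample_reads, deduplicate_reads)
      dedup_stats[[mk]] <- data.frame(
        sample = names(sample_reads), mark = mk,
        reads_in = vapply(sample_reads, nrow, 1L),
        reads_kept = vapply(kept, nrow, 1L))
      sample_reads <- kept
    }
    .log_stage(logcon, "coverage", paste0(mk, ": building tracks for ",
                                          length(sample_reads), " samples"))
    trk <- lapply(sample_reads, function(rd) {
      fr <- extend_reads(rd, cfg$fragment_length, sizes)
      smooth_track(normalize_per_million(
        build_coverage(fr, sizes, library_size = nrow(rd))),
        cfg$smooth_window)
    })
    trk <- quantile_normalize(trk)
    names(trk) <- names(sample_reads)
    tracks[[mk]] <- trk
    if (write_bedgraphs) {
      for (sid in names(trk))
        write_bedgraph(trk[[sid]],
                       file.path(cfg$out_dir, "coverage",
                                 sprintf("%s_%s.bedGraph", sid, mk)))
    }
    prof <- meta_profile(trk, windows, cfg$flank, cfg$bin)
    utils::write.table(prof, file.path(cfg$out_dir, "coverage",
                                       sprintf("metaprofile_%s.tsv", mk)),
                       sep = "\t", quote = FALSE, row.names = FALSE)

    .log_stage(logcon, "count", paste0(mk, ": counting promoter reads"))
    vecs <- lapply(sample_reads, count_reads_in_windows, windows = windows,
                   mode = cfg$counting_mode)
    pcm <- assemble_count_matrix(vecs, mk, cfg$groups)
    write_count_matrix(pcm, file.path(cfg$out_dir, "counts",
                                      sprintf("counts_%s.tsv", mk)))
    count_mats[[mk]] <- pcm

    .log_stage(logcon, "diff", paste0(mk, ": differential occupancy test"))
    tb <- differential_table(pcm)
    utils::write.table(tb, file.path(cfg$out_dir, "diff",
                                     sprintf("diff_%s.tsv", mk)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    diff_tables[[mk]] <- tb
  }
  if (length(dedup_stats)) {
    dd <- do.call(rbind, dedup_stats)
    utils::write.table(dd, file.path(cfg$out_dir, "report", "dedup.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    report$dedup <- dd
  }

  selection <- select_significant(diff_tables, cfg$lfc_threshold,
                                  cfg$p_threshold)
  utils::write.table(selection, file.path(cfg$out_dir, "diff",
                                          "significance.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  n_sel <- sum(selection$selected)
  .log_stage(logcon, "diff", paste0(n_sel, " genes selected"))

  assignment <- NULL; summary_tb <- NULL
  if (n_sel >= 2 && n_sel >= cfg$k) {
    fc <- fold_change_matrix(diff_tables, selection)
    dend <- hier_cluster(fc)
    assignment <- cut_clusters(dend, cfg$k)
    summary_tb <- cluster_summary(assignment, fc, cfg$active_marks,
                                  cfg$repressive_marks,
                                  cfg$phenotype_threshold)
    assignment$phenotype <-
      summary_tb$phenotype[match(assignment$cluster, summary_tb$cluster)]
    utils::write.table(assignment,
                       file.path(cfg$out_dir, "clusters", "assignment.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(summary_tb,
                       file.path(cfg$out_dir, "clusters", "summary.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    merges <- data.frame(a = dend$merge[, 1L], b = dend$merge[, 2L],
                         height = dend$height)
    utils::write.table(merges,
                       file.path(cfg$out_dir, "clusters", "merges.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    # z-scaled, group-averaged heatmap matrix over selected genes
    zlist <- lapply(marks, function(mk) {
      z <- zscale_counts(count_mats[[mk]])
      gz <- group_average_z(z[selection$gene_id[selection$selected], ,
                              drop = FALSE], cfg$groups)
      colnames(gz) <- paste(mk, colnames(gz), sep = "_")
      gz
    })
    heat <- data.frame(gene_id = selection$gene_id[selection$selected],
                       do.call(cbind, zlist), check.names = FALSE)
    utils::write.table(heat,
                       file.path(cfg$out_dir, "clusters", "heatmap.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    # per-cluster, per-mark group meta-profiles
    for (k_id in unique(assignment$cluster)) {
      cg <- assignment$gene_id[assignment$cluster == k_id]
      for (mk in marks) {
        pr <- cluster_meta_profiles(cg, tracks[[mk]], windows, cfg$groups,
                                    cfg$flank, cfg$bin)
        utils::write.table(pr, file.path(cfg$out_dir, "clusters",
                                         sprintf("profile_cluster%d_%s.tsv",
                                                 k_id, mk)),
                           sep = "\t", quote = FALSE, row.names = FALSE)
      }
    }
  } else {
    .log_stage(logcon, "cluster", "too few selected genes; skipping clustering")
  }

  enrichment <- NULL
  if (!is.null(cfg$gmt) && !is.null(assignment)) {
    sets <- read_gmt(cfg$gmt)
    universe <- genes$gene_id
    enr <- lapply(unique(assignment$cluster), function(k_id) {
      cg <- assignment$gene_id[assignment$cluster == k_id]
      e <- hypergeom_enrichment(cg, sets, universe)
      cbind(cluster = k_id, e)
    })
    enrichment <- do.call(rbind, enr)
    utils::write.table(enrichment,
                       file.path(cfg$out_dir, "enrichment", "enrichment.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    .log_stage(logcon, "enrich", paste0(nrow(enrichment), " cluster-set tests"))
  }

  report$n_genes <- nrow(genes)
  report$n_selected <- n_sel
  report$clusters <- summary_tb
  rep_lines <- c(
    sprintf("promdiff run report"),
    sprintf("genes quantified: %d", nrow(genes)),
    sprintf("marks: %s", paste(marks, collapse = ", ")),
    sprintf("samples: %s", paste(names(cfg$groups), cfg$groups,
                                 sep = "=", collapse = ", ")),
    sprintf("selected genes (|log2FC| >= %g, p <= %g, any mark): %d",
            cfg$lfc_threshold, cfg$p_threshold, n_sel))
  if (!is.null(summary_tb))
    rep_lines <- c(rep_lines, sprintf("cluster %d: n=%d, phenotype=%s",
                                      summary_tb$cluster, summary_tb$size,
                                      summary_tb$phenotype))
  writeLines(rep_lines, file.path(cfg$out_dir, "report", "report.txt"))
  invisible(list(tracks = tracks, counts = count_mats, diff = diff_tables,
                 selection = selection, assignment = assignment,
                 cluster_summary = summary_tb, enrichment = enrichment,
                 report = report))
}
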