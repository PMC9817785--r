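#' End-to-end analysis configuration
#'
#' One configuration object drives both cohort arms with shared
#' thresholds, mirroring a two-cohort design analysed under one set of
#' rules.
#'
#' @param stratify_rule `"ihc"` (score >= 2+ positive) or `"mean"`
#'   (marker expression above the cohort mean).
#' @param marker_gene Stratifying marker id (ERBB2 in the motivating
#'   study); required for the mean rule and the microarray arm.
#' @param deg A [deg_filter_config()].
#' @param gsea A [gsea_config()]; its seed is filled from `seed` when
#'   unset.
#' @param probe A [probe_filter_config()] (microarray arm).
#' @param k Length of the top-gene frequency list (default 20).
#' @param restrict_to_degs Rank only the genes called differentially
#'   expressed instead of the full tested universe before GSEA.
#' @param metric Ranking metric (see [rank_genes()]).
#' @param seed Master seed for every stochastic stage.
#' @param outdir Optional directory; when set, every intermediate table
#'   is written there so any stage can be re-entered.
#' @return An object of class `"analysis_config"`.
#' @export
analysis_config <- function(stratify_rule = c("ihc", "mean"),
                            marker_gene = NULL,
                            deg = deg_filter_config(),
                            gsea = gsea_config(),
                            probe = probe_filter_config(),
                            k = 20L,
                            restrict_to_degs = FALSE,
                            metric = "signal_to_noise",
                            seed = NULL,
                            outdir = NULL) {
  stratify_rule <- match.arg(stratify_rule)
  if (k < 1) stop("k must be >= 1")
  if (is.null(gsea$seed) && !is.null(seed)) gsea$seed <- as.integer(seed)
  structure(list(stratify_rule = stratify_rule, marker_gene = marker_gene,
                 deg = deg, gsea = gsea, probe = probe, k = as.integer(k),
                 restrict_to_degs = restrict_to_degs, metric = metric,
                 seed = if (is.null(seed)) NULL else as.integer(seed),
                 outdir = outdir),
            class = "analysis_config")
}

#' Run the RNA-seq cohort arm
#'
#' The full chain for a count-based cohort: stratify samples, normalize by
#' median-of-ratios size factors, test genes with the NB Wald test, apply
#' the study filters, rank the tested universe, score every gene-set
#' collection, and rank genes by leading-edge frequency across the
#' significant sets.
#'
#' @param counts Integer gene-by-sample count matrix.
#' @param samples Sample table with `sample_id` matching the count
#'   columns and, for the IHC rule, an `ihc_score` column.
#' @param collection A [gene_set_collection()].
#' @param cfg An [analysis_config()].
#' @return An object of class `"analysis_report"` (see Details in
#'   [print.analysis_report()]): labels, size factors, DEG table and
#'   summary, ranked list, GSEA table, frequency table, top genes,
#'   per-gene pathway annotations, filter log and a provenance block.
#' @export
run_rnaseq_arm <- function(counts, samples, collection, cfg) {
  stopifnot(inherits(cfg, "analysis_config"))
  if (is.null(cfg$seed)) stop("analysis_config$seed must be set")
  if (!identical(samples$sample_id, colnames(counts)))
    stop("samples$sample_id must match the count matrix columns in order")

  sf <- size_factors(counts)
  norm <- normalize_counts(counts, sf)

  labels <- if (cfg$stratify_rule == "ihc") {
    classify_ihc(stats::setNames(samples$ihc_score, samples$sample_id))
  } else {
    if (is.null(cfg$marker_gene)) stop("mean rule needs cfg$marker_gene")
    if (!cfg$marker_gene %in% rownames(norm))
      stop("marker gene ", cfg$marker_gene, " absent from the count matrix")
    classify_by_cohort_mean(norm[cfg$marker_gene, ])
  }

  de <- nb_wald_test(counts, labels, cfg$deg, sf = sf)
  filt <- apply_deg_filters(de, cfg$deg)
  tested <- filt$records$gene[filt$records$status != "filtered_low_count"]
  if (cfg$restrict_to_degs)
    tested <- filt$records$gene[filt$records$status %in% c("up", "down")]
  if (length(tested) < 2)
    stop("fewer than 2 genes survive filtering; nothing to rank")

  ranked <- rank_genes(norm[tested, , drop = FALSE], labels, cfg$metric)
  gsea_res <- run_gsea_collection(ranked, collection, cfg$gsea,
                                  expr = norm[tested, , drop = FALSE],
                                  labels = labels, metric = cfg$metric)
  freq <- gene_frequency(gsea_res)
  top <- top_k(freq, cfg$k)
  ann <- if (nrow(top)) annotate_genes(top, gsea_res) else list()

  sig_by_coll <- if (nrow(gsea_res))
    table(gsea_res$collection[gsea_res$significant]) else table(character(0))

  report <- structure(list(
    arm = "rnaseq",
    labels = labels,
    size_factors = sf,
    deg_records = filt$records,
    deg_summary = filt$summary,
    ranked = ranked,
    gsea = gsea_res,
    n_significant_sets = sum(gsea_res$significant),
    significant_by_collection = sig_by_coll,
    frequency = freq,
    top_genes = top,
    annotations = ann,
    filter_log = list(
      genes_in = nrow(counts),
      genes_tested = sum(filt$records$status != "filtered_low_count"),
      genes_de = filt$summary$n_de,
      sets_in = length(collection),
      sets_scored = nrow(gsea_res),
      sets_significant = sum(gsea_res$significant)
    ),
    provenance = .provenance(cfg)
  ), class = "analysis_report")

  if (!is.null(cfg$outdir)) .write_report(report, cfg$outdir)
  report
}

#' Run the microarray cohort arm
#'
#' The probe-level chain: adaptive probe filtering (MAS5 presence, GCRMA
#' CV window, control/unassigned exclusion), probe-to-gene collapse by
#' maximum expression, cohort-mean stratification on the marker gene's
#' collapsed row, ranking, GSEA and leading-edge frequency ranking.
#'
#' @param pair A [probe_matrix_pair()].
#' @param ann Probe annotation (`probe_id`, `gene`, `control`).
#' @param collection A [gene_set_collection()].
#' @param cfg An [analysis_config()]; `marker_gene` is required.
#' @return An `"analysis_report"` as in [run_rnaseq_arm()], with probe
#'   cardinalities in the filter log.
#' @export
run_microarray_arm <- function(pair, ann, collection, cfg) {
  stopifnot(inherits(cfg, "analysis_config"))
  if (is.null(cfg$seed)) stop("analysis_config$seed must be set")
  if (is.null(cfg$marker_gene))
    stop("microarray arm needs cfg$marker_gene for stratification")

  kept <- filter_probes(pair, ann, cfg$probe)
  if (length(kept) == 0) stop("no probe survives the adaptive filter")
  gexpr <- collapse_probes(pair$log2[kept, , drop = FALSE], ann)
  if (!cfg$marker_gene %in% rownames(gexpr))
    stop("marker gene ", cfg$marker_gene,
         " absent after probe filtering and collapse")

  labels <- classify_by_cohort_mean(gexpr[cfg$marker_gene, ])
  ranked <- rank_genes(gexpr, labels, cfg$metric)
  gsea_res <- run_gsea_collection(ranked, collection, cfg$gsea,
                                  expr = gexpr, labels = labels,
                                  metric = cfg$metric)
  freq <- gene_frequency(gsea_res)
  top <- top_k(freq, cfg$k)
  ann_top <- if (nrow(top)) annotate_genes(top, gsea_res) else list()

  report <- structure(list(
    arm = "microarray",
    labels = labels,
    gene_expression = gexpr,
    gsea = gsea_res,
    n_significant_sets = sum(gsea_res$significant),
    significant_by_collection = if (nrow(gsea_res))
      table(gsea_res$collection[gsea_res$significant]) else table(character(0)),
    frequency = freq,
    top_genes = top,
    annotations = ann_top,
    filter_log = list(
      probes_in = nrow(pair$linear),
      probes_kept = length(kept),
      genes_collapsed = nrow(gexpr),
      sets_in = length(collection),
      sets_scored = nrow(gsea_res),
      sets_significant = sum(gsea_res$significant)
    ),
    probe_drop_log = attr(kept, "drop_log"),
    provenance = .provenance(cfg)
  ), class = "analysis_report")

  if (!is.null(cfg$outdir)) .write_report(report, cfg$outdir)
  report
}

#' Compare two completed cohort reports
#'
#' Delegates to [compare_cohorts()] on the GSEA tables and top-gene lists
#' of two reports, and optionally writes the overlap as JSON together
#' with a Venn-count table.
#'
#' @param a,b `"analysis_report"` objects.
#' @param outdir Optional output directory for `overlap.json` and
#'   `venn_counts.tsv`.
#' @return An `"overlap_report"`.
#' @export
run_comparison <- function(a, b, outdir = NULL) {
  for (r in list(a, b)) {
    if (!inherits(r, "analysis_report"))
      stop("inputs must be analysis_report objects")
    missing <- setdiff(c("gsea", "top_genes"), names(r))
    if (length(missing))
      stop("incomplete report; missing section(s): ",
           paste(missing, collapse = ", "))
  }
  ov <- compare_cohorts(list(records = a$gsea, top = a$top_genes),
                        list(records = b$gsea, top = b$top_genes))
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(unclass(ov), file.path(outdir, "overlap.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    venn <- data.frame(
      region = c("a_only_pathways", "common_pathways", "b_only_pathways",
                 "a_only_genes", "common_genes", "b_only_genes"),
      count = c(length(ov$exclusive_pathways_a), ov$n_common_pathways,
                length(ov$exclusive_pathways_b),
                length(ov$exclusive_genes_a), ov$n_common_genes,
                length(ov$exclusive_genes_b))
    )
    utils::write.table(venn, file.path(outdir, "venn_counts.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  ov
}

.provenance <- function(cfg) {
  list(
    package = "her2lead",
    version = as.character(utils::packageVersion("her2lead")),
    r_version = R.version.string,
    seed = cfg$seed,
    config = unclass_recursive(cfg)
  )
}

# strip S3 classes so the config serializes cleanly to JSON
unclass_recursive <- function(x) {
  if (is.list(x)) lapply(unclass(x), unclass_recursive) else x
}

.write_report <- function(report, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(
    data.frame(sample_id = names(report$labels), label = report$labels,
               stringsAsFactors = FALSE),
    file.path(outdir, "labels.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  if (!is.null(report$deg_records))
    utils::write.table(report$deg_records, file.path(outdir, "degs.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(report$ranked))
    utils::write.table(report$ranked, file.path(outdir, "ranked.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  write_gsea_tsv(report$gsea, file.path(outdir, "gsea.tsv"))
  utils::write.table(report$frequency, file.path(outdir, "frequency.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(report$top_genes, file.path(outdir, "top_genes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (length(report$annotations)) {
    ann_df <- data.frame(
      gene = rep(names(report$annotations),
                 lengths(report$annotations)),
      set = unlist(report$annotations, use.names = FALSE),
      stringsAsFactors = FALSE)
    utils::write.table(ann_df, file.path(outdir, "annotations.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  jsonlite::write_json(
    list(arm = report$arm,
         deg_summary = report$deg_summary,
         n_significant_sets = report$n_significant_sets,
         filter_log = report$filter_log,
         provenance = report$provenance),
    file.path(outdir, "report.json"), auto_unbox = TRUE, pretty = TRUE,
    null = "null")
  invisible(outdir)
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("analysis_report (", x$arm, " arm)\n", sep = "")
  cat("  samples:", length(x$labels), "(",
      sum(x$labels == "positive"), "positive /",
      sum(x$labels == "negative"), "negative )\n")
  if (!is.null(x$deg_summary))
    cat("  DEGs:", x$deg_summary$n_de, "(", x$deg_summary$n_up, "up /",
        x$deg_summary$n_down, "down );",
        x$deg_summary$n_filtered_low_count, "genes below count filter\n")
  cat("  significant gene sets:", x$n_significant_sets, "of",
      x$filter_log$sets_scored, "scored\n")
  if (nrow(x$top_genes)) {
    cat("  top genes by leading-edge frequency:\n")
    print(utils::head(x$top_genes, 10), row.names = FALSE)
  }
  invisible(x)
}
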