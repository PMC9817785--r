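#' Generate a synthetic bulk RNA-seq count matrix with planted truth
#'
#' Draws an integer gene-by-sample count matrix from a negative-binomial
#' model (`Var = mu + alpha * mu^2`).  Per-gene baseline means are
#' log-normal; a `de_fraction` of genes is planted as differentially
#' expressed, with the positive group's mean multiplied by
#' `2^(signed true_lfc)` and the sign split 50/50 up/down.
#'
#' @param config A [sim_config()] with `seed` set.
#' @return A list with components
#'   \describe{
#'     \item{counts}{integer matrix, genes x samples, with dimnames.}
#'     \item{sample_info}{data frame: `sample_id`, `group`
#'       (`"negative"`/`"positive"`).}
#'     \item{truth}{list: `de_genes` (data frame `gene`, `true_lfc`),
#'       `base_mean` (named vector), `dispersion`.}
#'   }
#' @examples
#' sim <- gen_count_matrix(sim_config(n_genes = 100, seed = 1))
#' dim(sim$counts)
#' @export
gen_count_matrix <- function(config) {
  validate_sim_config(config)
  .require_seed(config)
  set.seed(config$seed)

  n <- config$n_genes
  ns <- config$group_sizes
  n_samp <- sum(ns)
  genes <- sprintf("G%06d", seq_len(n))
  samples <- sprintf("S%03d", seq_len(n_samp))
  group <- rep(c("negative", "positive"), times = ns)

  base_mean <- stats::rlnorm(n, config$baseline_log_mean, config$baseline_log_sd)
  names(base_mean) <- genes

  n_de <- round(config$de_fraction * n)
  de_idx <- if (n_de > 0) sort(sample.int(n, n_de)) else integer(0)
  signs <- rep_len(c(1, -1), n_de)
  lfc <- numeric(n)
  lfc[de_idx] <- signs * config$true_lfc

  mu_neg <- base_mean
  mu_pos <- base_mean * 2^lfc
  mu <- cbind(
    matrix(rep(mu_neg, ns[1]), nrow = n),
    matrix(rep(mu_pos, ns[2]), nrow = n)
  )
  counts <- matrix(
    stats::rnbinom(n * n_samp, mu = as.vector(mu), size = 1 / config$dispersion),
    nrow = n, dimnames = list(genes, samples)
  )
  storage.mode(counts) <- "integer"

  truth <- list(
    de_genes = data.frame(
      gene = genes[de_idx],
      true_lfc = signs * config$true_lfc,
      stringsAsFactors = FALSE
    ),
    base_mean = base_mean,
    dispersion = config$dispersion
  )
  list(
    counts = counts,
    sample_info = data.frame(sample_id = samples, group = group,
                             stringsAsFactors = FALSE),
    truth = truth
  )
}

#' Generate a gene-set collection with planted enrichment
#'
#' Emits `n_sets` gene sets with sizes uniform in
#' `[set_size_min, set_size_max]`, tagged round-robin with the MSigDB-style
#' collection labels C2, C5-BP, C5-MF, C6, C7.  `n_enriched_sets` of them
#' are planted as truly enriched: at least `enriched_de_fraction` of their
#' members are drawn from planted DE genes sharing one sign, so the
#' enrichment running sum has a single dominant peak.  An optional
#' `driver_gene` (which must be a planted DE gene) is forced into the DE
#' core of every planted set, giving a known high-frequency gene for
#' end-to-end recovery experiments.
#'
#' @param config A [sim_config()] with `seed` set.
#' @param truth The `truth` component returned by [gen_count_matrix()]
#'   (defines the gene universe and the DE genes).
#' @param driver_gene Optional gene id to plant in every enriched set.
#' @return A list with `collection` (a [gene_set_collection()]) and
#'   `truth` (the input truth with `enriched_sets` added).
#' @export
gen_gene_sets <- function(config, truth, driver_gene = NULL) {
  validate_sim_config(config)
  .require_seed(config)
  set.seed(config$seed + 1L)

  universe <- names(truth$base_mean)
  tags <- c("C2", "C5-BP", "C5-MF", "C6", "C7")
  collections <- tags[(seq_len(config$n_sets) - 1L) %% length(tags) + 1L]
  sizes <- sample(seq(config$set_size_min, config$set_size_max),
                  config$n_sets, replace = TRUE)
  enriched_idx <- if (config$n_enriched_sets > 0)
    sort(sample.int(config$n_sets, config$n_enriched_sets)) else integer(0)

  de <- truth$de_genes
  if (!is.null(driver_gene)) {
    if (!driver_gene %in% de$gene)
      stop("driver_gene must be one of the planted DE genes")
    driver_sign <- sign(de$true_lfc[de$gene == driver_gene])
  }

  sets <- vector("list", config$n_sets)
  names(sets) <- sprintf("%s_SET%03d", collections, seq_len(config$n_sets))
  for (i in seq_len(config$n_sets)) {
    if (i %in% enriched_idx) {
      s <- if (is.null(driver_gene)) sample(c(1, -1), 1) else driver_sign
      pool <- de$gene[sign(de$true_lfc) == s]
      n_core <- ceiling(config$enriched_de_fraction * sizes[i])
      if (n_core > length(pool))
        stop("not enough DE genes of one sign to plant an enriched set of size ",
             sizes[i], " (need ", n_core, ", have ", length(pool), ")")
      core <- if (is.null(driver_gene)) sample(pool, n_core)
        else c(driver_gene, sample(setdiff(pool, driver_gene), n_core - 1L))
      filler <- sample(setdiff(universe, core), sizes[i] - n_core)
      sets[[i]] <- sort(c(core, filler))
    } else {
      sets[[i]] <- sort(sample(universe, sizes[i]))
    }
  }

  truth$enriched_sets <- names(sets)[enriched_idx]
  list(
    collection = gene_set_collection(sets, collections),
    truth = truth
  )
}

#' Generate a paired probe-level microarray matrix pair
#'
#' Emulates the structure of an Affymetrix-style expression array after the
#' two standard normalizations: a log2-scale background-adjusted matrix
#' (GCRMA-like) and the matching linear-scale presence-oriented matrix
#' (MAS5-like, here the elementwise `2^log2` transform, so the two matrices
#' are monotone transforms of each other per probe).  Each gene receives
#' 1..`probes_per_gene_max` probes with probe-specific affinity offsets and
#' Gaussian log-scale noise; gene base levels are drawn so that probe means
#' straddle the conventional MAS5 presence threshold of 50.  A configurable
#' fraction of probes are positive controls (`"AFFX-"`-prefixed ids, bright
#' and nearly constant) and a fraction are left unassigned to any gene.
#'
#' If `truth` is supplied, planted DE genes are shifted by their true log2
#' fold change in the positive group, and `marker_gene` (if given) is
#' shifted by `marker_shift`, so that mean-expression stratification on the
#' marker recovers the groups.
#'
#' @param config A [sim_config()] with `seed` set.
#' @param truth Optional truth from [gen_count_matrix()] for planting group
#'   effects.
#' @param marker_gene Optional gene id given a dedicated group shift.
#' @param marker_shift Log2 shift for the marker gene in the positive
#'   group; defaults to `config$true_lfc`.
#' @return A list with `pair` (a [probe_matrix_pair()]), `annotation`
#'   (data frame `probe_id`, `gene`, `control`; unassigned probes carry
#'   `NA` gene), and `sample_info` as in [gen_count_matrix()].
#' @export
gen_microarray <- function(config, truth = NULL, marker_gene = NULL,
                           marker_shift = NULL) {
  validate_sim_config(config)
  .require_seed(config)
  set.seed(config$seed + 2L)

  n <- config$n_genes
  ns <- config$group_sizes
  n_samp <- sum(ns)
  genes <- sprintf("G%06d", seq_len(n))
  samples <- sprintf("S%03d", seq_len(n_samp))
  pos <- rep(c(FALSE, TRUE), times = ns)

  base <- stats::rnorm(n, mean = 6, sd = 2)
  # per-gene biological variability across samples (Gamma: mean
  # array_bio_sd, CV 0.5) spreads the row CVs over and around the
  # adaptive filter's window, as on real arrays
  bio_sd <- if (cfg_bio <- config$array_bio_sd)
    stats::rgamma(n, shape = 4, scale = cfg_bio / 4) else numeric(n)
  shift <- numeric(n)
  if (!is.null(truth) && nrow(truth$de_genes) > 0) {
    idx <- match(truth$de_genes$gene, genes)
    shift[idx] <- truth$de_genes$true_lfc
  }
  if (!is.null(marker_gene)) {
    if (!marker_gene %in% genes) stop("unknown marker gene: ", marker_gene)
    shift[match(marker_gene, genes)] <-
      if (is.null(marker_shift)) config$true_lfc else marker_shift
  }
  # gene-level log2 signal, genes x samples
  signal <- matrix(base, n, n_samp) +
    outer(shift, as.numeric(pos)) +
    matrix(stats::rnorm(n * n_samp, 0, bio_sd), n)

  n_probes_per_gene <- sample.int(config$probes_per_gene_max, n, replace = TRUE)
  gene_of_probe <- rep(seq_len(n), times = n_probes_per_gene)
  p_tot <- length(gene_of_probe)
  affinity <- stats::rnorm(p_tot, 0, 0.7)
  log_mat <- signal[gene_of_probe, , drop = FALSE] + affinity +
    matrix(stats::rnorm(p_tot * n_samp, 0, config$array_noise_sd), p_tot)

  probe_id <- sprintf("P%06d_at", seq_len(p_tot))
  gene <- genes[gene_of_probe]
  control <- rep(FALSE, p_tot)

  n_ctrl <- round(config$control_probe_fraction * p_tot)
  if (n_ctrl > 0) {
    ci <- sample.int(p_tot, n_ctrl)
    control[ci] <- TRUE
    gene[ci] <- NA_character_
    probe_id[ci] <- sprintf("AFFX-P%06d_at", seq_len(n_ctrl))
    # positive controls: bright, nearly invariant spikes
    log_mat[ci, ] <- stats::rnorm(n_ctrl, 11, 0.4) +
      matrix(stats::rnorm(n_ctrl * n_samp, 0, 0.02), n_ctrl)
  }
  n_unas <- round(config$unassigned_fraction * p_tot)
  if (n_unas > 0) {
    ui <- sample(which(!control), n_unas)
    gene[ui] <- NA_character_
  }

  dimnames(log_mat) <- list(probe_id, samples)
  linear <- 2^log_mat

  list(
    pair = probe_matrix_pair(linear, log_mat),
    annotation = data.frame(probe_id = probe_id, gene = gene,
                            control = control, stringsAsFactors = FALSE),
    sample_info = data.frame(
      sample_id = samples,
      group = ifelse(pos, "positive", "negative"),
      stringsAsFactors = FALSE
    )
  )
}

#' Generate cohort metadata with IHC scores tied to marker expression
#'
#' Assigns each sample an ordinal immunohistochemistry score in
#' `{0, 1, 2, 3}` such that scores >= 2 co-occur with above-cohort-mean
#' marker-gene expression with probability `concordance`.  With
#' `concordance = 1` the IHC score rule and the mean-expression rule yield
#' identical HER2 labels.
#'
#' @param config A [sim_config()] with `seed` set.
#' @param expr Numeric gene-by-sample expression matrix containing
#'   `marker_gene` (e.g. normalized counts).
#' @param marker_gene Row id of the stratifying marker (ERBB2 in the
#'   motivating study).
#' @param concordance Probability that the IHC label agrees with the
#'   mean-expression label, in `[0, 1]`.
#' @param cohort Cohort label attached to every sample.
#' @return A data frame: `sample_id`, `cohort`, `ihc_score`,
#'   `marker_expression`.
#' @export
gen_cohort_metadata <- function(config, expr, marker_gene,
                                concordance = 1.0, cohort = "cohort1") {
  validate_sim_config(config)
  .require_seed(config)
  if (!marker_gene %in% rownames(expr))
    stop("unknown marker gene: ", marker_gene)
  if (concordance < 0 || concordance > 1)
    stop("concordance must lie in [0, 1]")
  set.seed(config$seed + 3L)

  x <- expr[marker_gene, ]
  n <- length(x)
  mean_pos <- x > mean(x)
  agree <- stats::runif(n) < concordance
  ihc_pos <- ifelse(agree, mean_pos, !mean_pos)
  score <- ifelse(ihc_pos, 2L, 0L) + sample(0:1, n, replace = TRUE)

  data.frame(
    sample_id = colnames(expr),
    cohort = cohort,
    ihc_score = as.integer(score),
    marker_expression = as.numeric(x),
    stringsAsFactors = FALSE
  )
}
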