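#' Simulation configuration for the synthetic study inputs
#'
#' Bundles every tunable of the synthetic-data generators into one
#' validated object.  The defaults emulate the study design the analysis
#' was built for: a targeted bulk RNA-seq panel of ~20,000 genes measured
#' on an unbalanced two-group cohort (3 biomarker-negative vs 11
#' biomarker-positive samples), with roughly a tenth of the genes
#' differentially expressed at a two-fold change, and MSigDB-like gene-set
#' collections in which a handful of sets are planted as truly enriched.
#'
#' @param n_genes Number of genes in the simulated panel.
#' @param group_sizes Integer pair: samples in the negative and positive
#'   group respectively.  Both must be >= 2 so group variances exist.
#' @param de_fraction Proportion of genes planted as differentially
#'   expressed (in `[0, 1]`).
#' @param true_lfc Log2 fold-change magnitude of planted DE genes; the sign
#'   is split 50/50 up/down across the planted genes.
#' @param dispersion Negative-binomial dispersion `alpha` (> 0), so that
#'   `Var = mu + alpha * mu^2`.
#' @param baseline_log_mean,baseline_log_sd Log-normal parameters for the
#'   per-gene baseline mean counts.
#' @param n_sets Number of gene sets to generate.
#' @param set_size_min,set_size_max Inclusive bounds for gene-set sizes.
#' @param n_enriched_sets Number of sets planted as truly enriched.
#' @param enriched_de_fraction Minimum proportion of each planted set drawn
#'   from concordant-sign DE genes (in `[0, 1]`).
#' @param probes_per_gene_max Maximum number of array probes per gene
#'   (each gene gets 1..`probes_per_gene_max` probes, >= 1).
#' @param control_probe_fraction Fraction of probes emitted as positive
#'   control probes (ids prefixed `"AFFX-"`, unassigned to any gene).
#' @param unassigned_fraction Fraction of non-control probes left without a
#'   gene assignment.
#' @param array_noise_sd Gaussian measurement-noise standard deviation on
#'   the log2 array scale.
#' @param array_bio_sd Mean of the per-gene biological standard deviation
#'   on the log2 scale (per-gene values drawn from a Gamma distribution
#'   with this mean); this is what gives probes a realistic spread of
#'   coefficients of variation, some below and some inside the adaptive
#'   filter's CV window.
#' @param seed Integer seed; required before any generator is called so
#'   that every simulated object is exactly reproducible.
#'
#' @return An object of class `"sim_config"` (a validated named list).
#' @examples
#' cfg <- sim_config(n_genes = 500, group_sizes = c(3, 11), seed = 1)
#' cfg$de_fraction
#' @export
sim_config <- function(n_genes = 20000L,
                       group_sizes = c(3L, 11L),
                       de_fraction = 0.1,
                       true_lfc = 2,
                       dispersion = 0.2,
                       baseline_log_mean = log(100),
                       baseline_log_sd = 1.2,
                       n_sets = 50L,
                       set_size_min = 15L,
                       set_size_max = 100L,
                       n_enriched_sets = 5L,
                       enriched_de_fraction = 0.8,
                       probes_per_gene_max = 10L,
                       control_probe_fraction = 0.02,
                       unassigned_fraction = 0.03,
                       array_noise_sd = 0.25,
                       array_bio_sd = 0.8,
                       seed = NULL) {
  cfg <- list(
    n_genes = as.integer(n_genes),
    group_sizes = as.integer(group_sizes),
    de_fraction = de_fraction,
    true_lfc = true_lfc,
    dispersion = dispersion,
    baseline_log_mean = baseline_log_mean,
    baseline_log_sd = baseline_log_sd,
    n_sets = as.integer(n_sets),
    set_size_min = as.integer(set_size_min),
    set_size_max = as.integer(set_size_max),
    n_enriched_sets = as.integer(n_enriched_sets),
    enriched_de_fraction = enriched_de_fraction,
    probes_per_gene_max = as.integer(probes_per_gene_max),
    control_probe_fraction = control_probe_fraction,
    unassigned_fraction = unassigned_fraction,
    array_noise_sd = array_noise_sd,
    array_bio_sd = array_bio_sd,
    seed =if (is.null(seed)) NULL else as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$n_genes < 1L) stop("n_genes must be a positive integer")
  if (length(cfg$group_sizes) != 2L || any(cfg$group_sizes < 2L))
    stop("group_sizes must be two integers >= 2 (group variances are needed)")
  if (cfg$de_fraction < 0 || cfg$de_fraction > 1)
    stop("de_fraction must lie in [0, 1]")
  if (cfg$dispersion <= 0) stop("dispersion must be > 0")
  if (cfg$set_size_min > cfg$set_size_max || cfg$set_size_max > cfg$n_genes)
    stop("need set_size_min <= set_size_max <= n_genes")
  if (cfg$n_enriched_sets > cfg$n_sets)
    stop("n_enriched_sets cannot exceed n_sets")
  if (cfg$enriched_de_fraction < 0 || cfg$enriched_de_fraction > 1)
    stop("enriched_de_fraction must lie in [0, 1]")
  if (cfg$probes_per_gene_max < 1L) stop("probes_per_gene_max must be >= 1")
  if (cfg$control_probe_fraction < 0 || cfg$control_probe_fraction >= 1 ||
      cfg$unassigned_fraction < 0 || cfg$unassigned_fraction >= 1)
    stop("probe annotation fractions must lie in [0, 1)")
  if (cfg$array_noise_sd < 0) stop("array_noise_sd must be >= 0")
  if (cfg$array_bio_sd < 0) stop("array_bio_sd must be >= 0")
  invisible(cfg)
}

.require_seed <- function(cfg) {
  if (is.null(cfg$seed))
    stop("sim_config$seed must be set before calling a generator")
  invisible(cfg$seed)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config:", x$n_genes, "genes,",
      paste(x$group_sizes, collapse = " vs "), "samples,",
      sprintf("%.0f%% DE at |log2FC| = %g,", 100 * x$de_fraction, x$true_lfc),
      x$n_sets, "gene sets (", x$n_enriched_sets, "enriched ), seed =",
      if (is.null(x$seed)) "unset" else x$seed, "\n")
  invisible(x)
}
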