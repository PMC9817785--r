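#' Differential-expression filter configuration
#'
#' The three study filters: genes with fewer than `min_norm_count` mean
#' normalized read counts are excluded from testing; a fold change of 2
#' (`lfc_threshold = 1` on the log2 scale) is the effect-size cutoff; and
#' nominal `p < alpha` is called significant (no multiplicity adjustment
#' by default, mirroring the stated threshold; see [apply_deg_filters()]).
#'
#' @param min_norm_count Minimum mean normalized count for a gene to be
#'   tested (default 10).
#' @param lfc_threshold Absolute log2 fold-change cutoff (default 1, i.e.
#'   fold change 2).
#' @param alpha Nominal significance level (default 0.05).
#' @return An object of class `"deg_filter_config"`.
#' @export
deg_filter_config <- function(min_norm_count = 10, lfc_threshold = 1,
                              alpha = 0.05) {
  if (min_norm_count <= 0 || lfc_threshold <= 0)
    stop("min_norm_count and lfc_threshold must be positive")
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  structure(list(min_norm_count = min_norm_count,
                 lfc_threshold = lfc_threshold, alpha = alpha),
            class = "deg_filter_config")
}

#' Median-of-ratios size factors
#'
#' Library-size normalization against a geometric-mean pseudo-reference:
#' the size factor of sample `j` is the median over eligible genes of
#' `count_gj / geomean_g`, where `geomean_g` is the geometric mean of gene
#' `g` across samples and eligible genes have `geomean_g > 0` (i.e. no
#' zero count in any sample).
#'
#' @param counts Non-negative integer gene-by-sample matrix.
#' @return Named numeric vector of positive per-sample size factors.
#' @examples
#' m <- matrix(c(10, 20, 20, 40), 2, dimnames = list(c("g1", "g2"),
#'                                                   c("s1", "s2")))
#' size_factors(m)  # c(1/sqrt(2), sqrt(2))
#' @export
size_factors <- function(counts) {
  .check_counts(counts)
  log_geo <- rowMeans(log(counts))         # -Inf for any gene with a zero
  eligible <- is.finite(log_geo)
  if (!any(eligible))
    stop("no gene has nonzero counts in every sample; size factors ",
         "undefined (consider a pseudo-reference fallback on filtered data)")
  sf <- apply(log(counts[eligible, , drop = FALSE]) - log_geo[eligible],
              2, stats::median)
  sf <- exp(sf)
  names(sf) <- colnames(counts)
  sf
}

#' Divide counts by per-sample size factors
#'
#' @param counts Gene-by-sample count matrix.
#' @param sf Positive size factors, one per sample (see [size_factors()]).
#' @return Real-valued normalized matrix of the same shape.
#' @export
normalize_counts <- function(counts, sf) {
  .check_counts(counts)
  if (length(sf) != ncol(counts))
    stop("need one size factor per sample")
  if (any(!is.finite(sf)) || any(sf <= 0))
    stop("size factors must be finite and strictly positive")
  sweep(counts, 2, sf, "/")
}

#' Negative-binomial Wald test per gene
#'
#' Tests each gene for a difference between the positive and negative
#' groups on median-of-ratios-normalized counts.  The effect size is
#' `log2fc = log2((m_pos + 0.5) / (m_neg + 0.5))` where `m_neg`, `m_pos`
#' are normalized group means (the 0.5 pseudo-count avoids log of zero).
#' The per-gene NB dispersion is estimated by method of moments from the
#' pooled within-group variances of normalized counts and floored at
#' `1e-8` (no shrinkage).  The standard error of `log2fc` comes from the
#' delta method under NB variance `mu + alpha * mu^2`.  Because the
#' dispersion is itself estimated from few samples, the Wald statistic
#' `log2fc / se` is referred to a Student-t distribution with the pooled
#' within-group degrees of freedom (`n1 + n2 - 2`) rather than the
#' standard normal; with a handful of samples per group the normal
#' reference is visibly anticonservative, and the t reference restores
#' nominal type-I error without shrinking anything.
#'
#' @param counts Integer gene-by-sample count matrix.
#' @param labels `"negative"` / `"positive"` per sample column; each group
#'   needs >= 2 samples.
#' @param cfg A [deg_filter_config()]; only carried through to record the
#'   thresholds used downstream.
#' @param sf Optional precomputed size factors; computed with
#'   [size_factors()] when `NULL`.
#' @return Data frame with one row per gene: `gene`, `base_mean` (mean
#'   normalized count over all samples), `log2fc`, `se`, `p_value`,
#'   `dispersion`; sorted by `p_value` ascending with ties broken by gene
#'   id.
#' @export
nb_wald_test <- function(counts, labels, cfg = deg_filter_config(),
                         sf = NULL) {
  .check_counts(counts)
  .check_labels(labels, ncol(counts))
  if (is.null(sf)) sf <- size_factors(counts)
  norm <- normalize_counts(counts, sf)

  neg <- labels == "negative"
  pos <- labels == "positive"
  n1 <- sum(neg); n2 <- sum(pos)
  m1 <- rowMeans(norm[, neg, drop = FALSE])
  m2 <- rowMeans(norm[, pos, drop = FALSE])
  v1 <- .row_vars(norm[, neg, drop = FALSE], m1)
  v2 <- .row_vars(norm[, pos, drop = FALSE], m2)

  # Poisson part of Var(count/sf) is mu/sf; method-of-moments dispersion
  # pools the within-group excess variance over both groups.
  inv1 <- mean(1 / sf[neg]); inv2 <- mean(1 / sf[pos])
  num <- (n1 - 1) * (v1 - m1 * inv1) + (n2 - 1) * (v2 - m2 * inv2)
  den <- (n1 - 1) * m1^2 + (n2 - 1) * m2^2
  alpha_g <- ifelse(den > 0, pmax(num / den, 1e-8), 1e-8)

  var_m1 <- m1 * inv1 / n1 + alpha_g * m1^2 / n1
  var_m2 <- m2 * inv2 / n2 + alpha_g * m2^2 / n2
  ln2sq <- log(2)^2
  se <- sqrt(var_m1 / ((m1 + 0.5)^2 * ln2sq) +
             var_m2 / ((m2 + 0.5)^2 * ln2sq))
  log2fc <- log2((m2 + 0.5) / (m1 + 0.5))
  z <- ifelse(se > 0, log2fc / se, 0)
  df <- n1 + n2 - 2
  p <- pmax(pmin(2 * stats::pt(-abs(z), df = df), 1), .Machine$double.xmin)

  out <- data.frame(
    gene = rownames(counts),
    base_mean = rowMeans(norm),
    log2fc = log2fc,
    se = se,
    p_value = p,
    dispersion = alpha_g,
    stringsAsFactors = FALSE,
    row.names = NULL
  )
  out[order(out$p_value, out$gene), , drop = FALSE]
}

#' Apply the study's differential-expression filters
#'
#' Assigns each tested gene a status: `filtered_low_count` when the mean
#' normalized count is below `min_norm_count` (such genes are excluded
#' from the testing summary entirely); otherwise `up` when
#' `log2fc >= lfc_threshold` and `p < alpha`, `down` when
#' `log2fc <= -lfc_threshold` and `p < alpha`, and `not_significant`
#' otherwise.  P-values are nominal by default; set `adjust = TRUE` to
#' gate significance on Benjamini-Hochberg adjusted p-values instead.
#'
#' @param records Output of [nb_wald_test()].
#' @param cfg A [deg_filter_config()].
#' @param adjust Use BH-adjusted p-values for the significance gate.
#' @return A list with `records` (the input plus `status` and, when
#'   `adjust = TRUE`, `p_adjusted`) and `summary`
#'   (`n_up`, `n_down`, `n_de`, `n_not_significant`, `n_filtered_low_count`).
#' @export
apply_deg_filters <- function(records, cfg = deg_filter_config(),
                              adjust = FALSE) {
  if (nrow(records) == 0) {
    records$status <- character(0)
    return(list(records = records,
                summary = list(n_up = 0L, n_down = 0L, n_de = 0L,
                               n_not_significant = 0L,
                               n_filtered_low_count = 0L)))
  }
  p_gate <- if (adjust) stats::p.adjust(records$p_value, "BH")
            else records$p_value
  if (adjust) records$p_adjusted <- p_gate

  status <- rep("not_significant", nrow(records))
  status[p_gate < cfg$alpha & records$log2fc >= cfg$lfc_threshold] <- "up"
  status[p_gate < cfg$alpha & records$log2fc <= -cfg$lfc_threshold] <- "down"
  status[records$base_mean < cfg$min_norm_count] <- "filtered_low_count"
  records$status <- status

  n_up <- sum(status == "up")
  n_down <- sum(status == "down")
  list(
    records = records,
    summary = list(
      n_up = n_up,
      n_down = n_down,
      n_de = n_up + n_down,
      n_not_significant = sum(status == "not_significant"),
      n_filtered_low_count = sum(status == "filtered_low_count")
    )
  )
}

.check_counts <- function(counts) {
  if (!is.matrix(counts) || !is.numeric(counts))
    stop("counts must be a numeric matrix")
  if (nrow(counts) < 1 || ncol(counts) < 1)
    stop("counts must have at least one gene and one sample")
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must carry gene rownames and sample colnames")
  if (anyDuplicated(rownames(counts)) || anyDuplicated(colnames(counts)))
    stop("gene and sample ids must be unique")
  if (anyNA(counts) || any(counts < 0))
    stop("counts must be non-negative with no missing cells")
  invisible(counts)
}

.row_vars <- function(x, means = rowMeans(x)) {
  n <- ncol(x)
  if (n < 2) stop("variance needs at least 2 columns")
  rowSums((x - means)^2) / (n - 1)
}
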