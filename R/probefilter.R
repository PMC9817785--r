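#' Probe-filter configuration
#'
#' The adaptive filter keeps probes that are present (mean linear-scale
#' MAS5 value strictly above `mas5_min`) and variable but not erratic
#' (coefficient of variation of the log2-scale GCRMA row within
#' `[cv_lo, cv_hi]` percent), and always drops positive control probes
#' and probes with no gene assignment.
#'
#' @param mas5_min Presence threshold on the mean linear value (default 50).
#' @param cv_lo,cv_hi Inclusive CV%% bounds (defaults 10 and 100).
#' @return An object of class `"probe_filter_config"`.
#' @export
probe_filter_config <- function(mas5_min = 50, cv_lo = 10, cv_hi = 100) {
  if (mas5_min <= 0) stop("mas5_min must be positive")
  if (cv_lo < 0 || cv_lo >= cv_hi) stop("need 0 <= cv_lo < cv_hi")
  structure(list(mas5_min = mas5_min, cv_lo = cv_lo, cv_hi = cv_hi),
            class = "probe_filter_config")
}

#' Adaptive probe filtering on a paired matrix
#'
#' Keeps a probe iff (a) its mean linear-scale value across samples
#' exceeds `mas5_min`, (b) the coefficient of variation of its log2-scale
#' row, `100 * sd / mean` with the sample standard deviation, lies within
#' `[cv_lo, cv_hi]`, (c) it is not a control probe, and (d) it is assigned
#' to a gene.  Constant rows (CV = 0, "unchanged" probes) fail (b);
#' probes whose log-scale row mean is not positive have an undefined CV
#' and are dropped with a logged reason.
#'
#' @param pair A [probe_matrix_pair()].
#' @param ann Annotation data frame with columns `probe_id`, `gene`
#'   (`NA` = unassigned) and `control` (logical); every probe in the
#'   matrices must be annotated.
#' @param cfg A [probe_filter_config()].
#' @return Character vector of kept probe ids (in matrix row order), with
#'   attribute `"drop_log"`: a data frame `probe_id`, `reason` for every
#'   dropped probe.
#' @export
filter_probes <- function(pair, ann, cfg = probe_filter_config()) {
  stopifnot(inherits(pair, "probe_matrix_pair"))
  if (ncol(pair$linear) < 2)
    stop("probe filtering needs at least 2 samples (CV requires variance)")
  probes <- rownames(pair$linear)
  idx <- match(probes, ann$probe_id)
  if (anyNA(idx))
    stop("unannotated probe(s): ",
         paste(utils::head(probes[is.na(idx)], 5), collapse = ", "))
  gene <- ann$gene[idx]
  control <- ann$control[idx]

  lin_mean <- rowMeans(pair$linear)
  log_mean <- rowMeans(pair$log2)
  log_sd <- sqrt(.row_vars(pair$log2, log_mean))
  cv_ok <- log_mean > 0
  cv <- ifelse(cv_ok, 100 * log_sd / log_mean, NA_real_)

  reason <- rep(NA_character_, length(probes))
  reason[!cv_ok] <- "cv_undefined_nonpositive_mean"
  reason[cv_ok & cv > cfg$cv_hi] <- "cv_above_range"
  reason[cv_ok & cv < cfg$cv_lo] <- "cv_below_range"
  reason[cv_ok & log_sd == 0] <- "unchanged"
  reason[lin_mean <= cfg$mas5_min] <- "low_mas5"
  reason[is.na(gene)] <- "unassigned"
  reason[control] <- "control"

  keep <- is.na(reason)
  kept <- probes[keep]
  attr(kept, "drop_log") <- data.frame(
    probe_id = probes[!keep], reason = reason[!keep],
    stringsAsFactors = FALSE)
  kept
}

#' Collapse probes to genes by maximum expression
#'
#' For each gene, selects the single probe with the highest mean
#' expression across samples and copies that probe's entire row into the
#' gene-level matrix, so every output row equals one input row and
#' within-probe covariance is preserved.  Ties are broken by probe id
#' ascending.
#'
#' @param log_matrix Log2-scale matrix restricted to the kept probes
#'   (see [filter_probes()]).
#' @param ann Probe annotation; every row of `log_matrix` must be
#'   assigned to a gene.
#' @return Gene-by-sample matrix (genes sorted), with attribute
#'   `"chosen_probes"`: named character vector gene -> selected probe.
#' @export
collapse_probes <- function(log_matrix, ann) {
  if (nrow(log_matrix) == 0) {
    out <- log_matrix
    rownames(out) <- character(0)
    attr(out, "chosen_probes") <- stats::setNames(character(0), character(0))
    return(out)
  }
  probes <- rownames(log_matrix)
  idx <- match(probes, ann$probe_id)
  if (anyNA(idx)) stop("probe(s) missing from annotation")
  gene <- ann$gene[idx]
  if (anyNA(gene) || any(ann$control[idx]))
    stop("collapse requires every probe to be gene-assigned and non-control")

  means <- rowMeans(log_matrix)
  ord <- order(gene, -means, probes)   # per gene: max mean first, tie by id
  first <- ord[!duplicated(gene[ord])]
  first <- first[order(gene[first])]
  out <- log_matrix[first, , drop = FALSE]
  rownames(out) <- gene[first]
  attr(out, "chosen_probes") <- stats::setNames(probes[first], gene[first])
  out
}
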