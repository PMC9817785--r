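#' Gene frequency across significant leading edges
#'
#' The headline ranking statistic: for every gene, the number of
#' significant gene sets whose leading edge contains it.  Only records
#' flagged significant contribute, and each record contributes at most
#' once per gene, so the frequencies sum exactly to the total leading-edge
#' size over significant sets.
#'
#' @param records GSEA result table from [run_gsea_collection()] (needs
#'   `significant` and the `leading_edge` list-column).
#' @return Data frame `gene`, `frequency`, `rank` (dense, 1-based), sorted
#'   by frequency descending then gene id; empty when no record is
#'   significant.
#' @examples
#' rec <- data.frame(set = c("s1", "s2", "s3"),
#'                   significant = TRUE)
#' rec$leading_edge <- list(c("A", "B"), c("A", "C"), c("A", "B", "D"))
#' gene_frequency(rec)  # A:3 B:2 C:1 D:1
#' @export
gene_frequency <- function(records) {
  sig <- records[records$significant, , drop = FALSE]
  genes <- unlist(sig$leading_edge, use.names = FALSE)
  if (length(genes) == 0)
    return(data.frame(gene = character(0), frequency = integer(0),
                      rank = integer(0), stringsAsFactors = FALSE))
  tab <- table(genes)
  out <- data.frame(gene = names(tab), frequency = as.integer(tab),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$frequency, out$gene), , drop = FALSE]
  out$rank <- match(out$frequency,
                    sort(unique(out$frequency), decreasing = TRUE))
  rownames(out) <- NULL
  out
}

#' Top-k genes of a frequency table
#'
#' Genes sorted by frequency descending, ties by gene id ascending; the
#' first `k` are returned.  With `include_ties = TRUE`, every gene tied
#' with the k-th frequency is kept (the list may then exceed `k`).
#'
#' @param freq Frequency table from [gene_frequency()].
#' @param k Number of genes to keep (default 20, the study's headline
#'   list length).
#' @param include_ties Keep all genes tied with the k-th.
#' @return The first rows of `freq` under the rule above.
#' @export
top_k <- function(freq, k = 20, include_ties = FALSE) {
  if (k < 1) stop("k must be >= 1")
  if (nrow(freq) <= k) return(freq)
  if (include_ties) {
    cutoff <- freq$frequency[k]
    freq[freq$frequency >= cutoff, , drop = FALSE]
  } else {
    freq[seq_len(k), , drop = FALSE]
  }
}

#' Pathway annotations for top genes
#'
#' For each top-ranked gene, the significant sets whose leading edge
#' contains it, ordered by p-value then set name.  The per-gene counts
#' reproduce the frequency table exactly.
#'
#' @param top A [top_k()] table.
#' @param records The same GSEA records that produced it.
#' @return Named list: gene id -> character vector of set names.
#' @export
annotate_genes <- function(top, records) {
  sig <- records[records$significant, , drop = FALSE]
  sig <- sig[order(sig$p_value, sig$set), , drop = FALSE]
  out <- lapply(top$gene, function(g) {
    hit <- vapply(sig$leading_edge, function(le) g %in% le, logical(1))
    if (!any(hit))
      stop("gene ", g, " is absent from every significant leading edge; ",
           "records do not match the frequency table")
    sig$set[hit]
  })
  names(out) <- top$gene
  out
}

#' Cross-cohort overlap of pathways and top genes
#'
#' Compares two analyses scored against the same gene-set collections:
#' pathways significant in both cohorts (matched by exact set name), the
#' intersection of the two top-gene lists, and the per-cohort exclusives.
#'
#' @param a,b Each a list with `records` (GSEA table) and `top`
#'   (a [top_k()] table).
#' @return An object of class `"overlap_report"`: list with
#'   `common_pathways`, `n_common_pathways`, `common_genes`,
#'   `n_common_genes`, `exclusive_pathways_a`, `exclusive_pathways_b`,
#'   `exclusive_genes_a`, `exclusive_genes_b`.
#' @export
compare_cohorts <- function(a, b) {
  sig_a <- a$records$set[a$records$significant]
  sig_b <- b$records$set[b$records$significant]
  common_p <- sort(intersect(sig_a, sig_b))
  common_g <- sort(intersect(a$top$gene, b$top$gene))
  structure(list(
    common_pathways = common_p,
    n_common_pathways = length(common_p),
    common_genes = common_g,
    n_common_genes = length(common_g),
    exclusive_pathways_a = sort(setdiff(sig_a, sig_b)),
    exclusive_pathways_b = sort(setdiff(sig_b, sig_a)),
    exclusive_genes_a = sort(setdiff(a$top$gene, b$top$gene)),
    exclusive_genes_b = sort(setdiff(b$top$gene, a$top$gene))
  ), class = "overlap_report")
}

#' @export
print.overlap_report <- function(x, ...) {
  cat("overlap_report:\n",
      " common significant pathways:", x$n_common_pathways, "\n",
      " common top genes:           ", x$n_common_genes, "\n",
      " exclusives (pathways):      ", length(x$exclusive_pathways_a), "vs",
      length(x$exclusive_pathways_b), "\n",
      " exclusives (genes):         ", length(x$exclusive_genes_a), "vs",
      length(x$exclusive_genes_b), "\n")
  invisible(x)
}
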