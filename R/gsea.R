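#' Gene set enrichment configuration
#'
#' @param weight_exponent Exponent `p` applied to `|metric|` when weighting
#'   hits in the running sum; `1` is the standard weighted statistic, `0`
#'   reduces to the classical Kolmogorov-Smirnov form.
#' @param n_perm Number of permutations for the nominal p-value.
#' @param perm_mode `"gene_set"` (resample member positions uniformly) or
#'   `"phenotype"` (permute sample labels and re-rank).  Gene-set
#'   permutation is the default because small unbalanced cohorts admit few
#'   distinct phenotype permutations (a 3-vs-11 design has only
#'   `choose(14, 3) = 364`); phenotype mode enumerates exhaustively, with
#'   a warning, when the distinct-permutation count falls below `n_perm`.
#' @param alpha Significance level for the `significant` flag.
#' @param min_set_size,max_set_size Effective set-size bounds (after
#'   intersection with the ranked universe); sets outside are skipped.
#' @param seed Integer seed driving the permutations.
#' @return An object of class `"gsea_config"`.
#' @export
gsea_config <- function(weight_exponent = 1, n_perm = 1000L,
                        perm_mode = c("gene_set", "phenotype"),
                        alpha = 0.05, min_set_size = 5L,
                        max_set_size = 500L, seed = NULL) {
  perm_mode <- match.arg(perm_mode)
  if (n_perm < 1) stop("n_perm must be >= 1")
  if (weight_exponent < 0) stop("weight_exponent must be >= 0")
  if (min_set_size < 0 || min_set_size > max_set_size)
    stop("need 0 <= min_set_size <= max_set_size")
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  structure(list(weight_exponent = weight_exponent,
                 n_perm = as.integer(n_perm), perm_mode = perm_mode,
                 alpha = alpha, min_set_size = as.integer(min_set_size),
                 max_set_size = as.integer(max_set_size),
                 seed = if (is.null(seed)) NULL else as.integer(seed)),
            class = "gsea_config")
}

#' Rank genes by a group-difference metric
#'
#' Builds the ranked gene list that the enrichment running sum walks.
#' The default signal-to-noise metric is
#' `(mu_pos - mu_neg) / (sd_pos + sd_neg)` with each group standard
#' deviation floored at `0.2 * |mu|` of its group (and at 0.2 absolute
#' when the group mean is zero), which keeps constant or near-constant
#' genes from exploding the statistic.  The `log2fc` metric is
#' `log2((mu_pos + 0.5) / (mu_neg + 0.5))` and is intended for count-scale
#' input.  Genes are ordered by descending metric, ties broken by gene id
#' ascending, so the ranking is deterministic.
#'
#' @param expr Numeric gene-by-sample matrix (normalized counts or
#'   collapsed log2 array intensities).
#' @param labels `"negative"` / `"positive"` per sample; both groups need
#'   >= 2 samples for `signal_to_noise`.
#' @param metric `"signal_to_noise"` (default) or `"log2fc"`.
#' @return Data frame with columns `gene`, `metric`, in ranked order
#'   (rank 1 first).
#' @export
rank_genes <- function(expr, labels,
                       metric = c("signal_to_noise", "log2fc")) {
  metric <- match.arg(metric)
  if (!is.matrix(expr) || is.null(rownames(expr)))
    stop("expr must be a matrix with gene rownames")
  min_n <- if (metric == "signal_to_noise") 2L else 1L
  .check_labels(labels, ncol(expr), min_per_group = min_n)

  neg <- labels == "negative"; pos <- labels == "positive"
  mu_n <- rowMeans(expr[, neg, drop = FALSE])
  mu_p <- rowMeans(expr[, pos, drop = FALSE])
  if (metric == "signal_to_noise") {
    sd_n <- sqrt(.row_vars(expr[, neg, drop = FALSE], mu_n))
    sd_p <- sqrt(.row_vars(expr[, pos, drop = FALSE], mu_p))
    sd_n <- pmax(sd_n, ifelse(mu_n == 0, 0.2, 0.2 * abs(mu_n)))
    sd_p <- pmax(sd_p, ifelse(mu_p == 0, 0.2, 0.2 * abs(mu_p)))
    m <- (mu_p - mu_n) / (sd_p + sd_n)
  } else {
    m <- log2((mu_p + 0.5) / (mu_n + 0.5))
  }
  if (any(!is.finite(m))) stop("ranking metric must be finite")
  out <- data.frame(gene = rownames(expr), metric = as.numeric(m),
                    stringsAsFactors = FALSE, row.names = NULL)
  out[order(-out$metric, out$gene), , drop = FALSE]
}

#' Weighted running-sum enrichment score
#'
#' Walks the ranked list: each hit (gene in the set) adds
#' `|metric_i|^p / sum_hits |metric|^p`, each miss subtracts
#' `1 / (N - N_h)`.  The enrichment score is the signed value of the
#' maximum absolute deviation of this running sum from zero, which by
#' construction lies in `[-1, 1]` and returns to zero at the end of the
#' list.  When every hit metric is zero (possible with `p > 0`), the hits
#' are weighted equally.  If the same absolute deviation occurs at several
#' positions, the earliest position wins.
#'
#' @param ranked Ranked list from [rank_genes()] (columns `gene`,
#'   `metric`, rank 1 first).
#' @param members Character vector of gene ids forming the set; must hit
#'   at least one ranked gene and not cover the whole list.
#' @param weight_exponent Weight exponent `p` (see [gsea_config()]).
#' @return List with `es`, `peak_index` (1-based rank position of the
#'   extreme deviation), `n_hits` (effective set size).
#' @examples
#' rk <- data.frame(gene = paste0("G", 1:5), metric = 5:1)
#' enrichment_score(rk, c("G1", "G3"), weight_exponent = 0)
#' @export
enrichment_score <- function(ranked, members, weight_exponent = 1) {
  hits <- ranked$gene %in% members
  N <- nrow(ranked)
  nh <- sum(hits)
  if (nh == 0) stop("gene set has no member in the ranked list")
  if (nh == N) stop("gene set covers the whole ranked list; miss ",
                    "decrement undefined")
  w <- abs(ranked$metric[hits])^weight_exponent
  sw <- sum(w)
  w <- if (sw > 0) w / sw else rep.int(1 / nh, nh)
  step <- rep.int(-1 / (N - nh), N)
  step[hits] <- w
  rs <- cumsum(step)
  i <- which.max(abs(rs))
  list(es = rs[[i]], peak_index = i, n_hits = nh)
}

# Signed extreme deviation computed from sorted hit positions only
# (O(n_hits) instead of O(N)); used in permutation loops where only |es|
# matters.  `w` are the raw weights aligned with `pos`.
.es_from_positions <- function(pos, w, N) {
  nh <- length(pos)
  sw <- sum(w)
  w <- if (sw > 0) w / sw else rep.int(1 / nh, nh)
  cw <- cumsum(w)
  gap <- (pos - seq_len(nh)) / (N - nh)
  at <- cw - gap          # running sum at each hit
  before <- at - w        # running sum just before each hit
  hi <- max(at); lo <- min(before)
  if (hi >= -lo) hi else lo
}

#' Leading-edge genes of an enrichment result
#'
#' The set members that drive the enrichment signal: for a non-negative
#' enrichment score, the hits at ranks at or before the running-sum peak;
#' for a negative score, the hits at ranks at or after it.  Genes are
#' returned in ranked-list order.
#'
#' @param ranked Ranked list used to compute `es_result`.
#' @param members The same gene set.
#' @param es_result Result of [enrichment_score()] on these inputs.
#' @return Character vector of gene ids.
#' @export
leading_edge <- function(ranked, members, es_result) {
  if (es_result$peak_index < 1 || es_result$peak_index > nrow(ranked))
    stop("peak_index lies outside the ranked list")
  hit_ranks <- which(ranked$gene %in% members)
  keep <- if (es_result$es >= 0) hit_ranks <= es_result$peak_index
          else hit_ranks >= es_result$peak_index
  ranked$gene[hit_ranks[keep]]
}

#' Permutation p-value for an enrichment score
#'
#' Nominal two-sided p-value
#' `p = (#\{|es_perm| >= |es_obs|\} + 1) / (n_perm + 1)`, which is always
#' in `(0, 1]`.  In `gene_set` mode the null redraws the set's positions
#' uniformly without replacement from the ranked list, reusing the
#' observed metric weights at the resampled positions.  In `phenotype`
#' mode the sample labels are permuted and the list re-ranked each time;
#' when the number of distinct label assignments is below `n_perm` the
#' distinct assignments are enumerated exhaustively instead (with a
#' warning), and the add-one formula uses the enumeration count.
#'
#' @param ranked Ranked list from [rank_genes()].
#' @param members Gene set member ids.
#' @param cfg A [gsea_config()] with `seed` set.
#' @param expr,labels Required for `perm_mode = "phenotype"`: the
#'   expression matrix and labels that produced `ranked`.
#' @param metric Ranking metric used when re-ranking in phenotype mode.
#' @return The nominal p-value (scalar in `(0, 1]`).
#' @export
gsea_pvalue <- function(ranked, members, cfg = gsea_config(),
                        expr = NULL, labels = NULL,
                        metric = "signal_to_noise") {
  if (is.null(cfg$seed)) stop("gsea_config$seed must be set")
  obs <- enrichment_score(ranked, members, cfg$weight_exponent)
  set.seed(cfg$seed)

  if (cfg$perm_mode == "gene_set") {
    N <- nrow(ranked)
    nh <- obs$n_hits
    wts <- abs(ranked$metric)^cfg$weight_exponent
    exceed <- 0L
    for (b in seq_len(cfg$n_perm)) {
      pos <- sort.int(sample.int(N, nh))
      if (abs(.es_from_positions(pos, wts[pos], N)) >= abs(obs$es))
        exceed <- exceed + 1L
    }
    return((exceed + 1) / (cfg$n_perm + 1))
  }

  # phenotype mode
  if (is.null(expr) || is.null(labels))
    stop("phenotype permutation needs expr and labels")
  n <- length(labels)
  k <- sum(labels == "positive")
  n_distinct <- choose(n, k)
  perm_es <- if (n_distinct <= cfg$n_perm) {
    warning("only ", n_distinct, " distinct phenotype permutations ",
            "(< n_perm = ", cfg$n_perm, "); enumerating exhaustively")
    combos <- utils::combn(n, k)
    vapply(seq_len(ncol(combos)), function(j) {
      lab <- rep("negative", n)
      lab[combos[, j]] <- "positive"
      rk <- rank_genes(expr, lab, metric)
      enrichment_score(rk, members, cfg$weight_exponent)$es
    }, numeric(1))
  } else {
    vapply(seq_len(cfg$n_perm), function(b) {
      lab <- sample(labels)
      rk <- rank_genes(expr, lab, metric)
      enrichment_score(rk, members, cfg$weight_exponent)$es
    }, numeric(1))
  }
  (sum(abs(perm_es) >= abs(obs$es)) + 1) / (length(perm_es) + 1)
}

#' Score every set of a collection against a ranked list
#'
#' Intersects each set with the ranked universe, skips sets whose
#' effective size falls outside `[min_set_size, max_set_size]` (recorded
#' in the `"skipped"` attribute with a reason), and computes for the rest
#' the enrichment score, permutation p-value, significance flag
#' (`p < alpha`) and leading-edge genes.  Results are sorted by p-value,
#' ties by set name, and each set draws its permutations from a seed
#' offset by its position in the collection so the whole table is
#' reproducible.
#'
#' @param ranked Ranked list from [rank_genes()].
#' @param collection A [gene_set_collection()].
#' @param cfg A [gsea_config()] with `seed` set.
#' @param expr,labels Passed through to [gsea_pvalue()] for phenotype
#'   permutation.
#' @param metric Ranking metric for phenotype re-ranking.
#' @return Data frame with columns `set`, `collection`, `size` (effective),
#'   `es`, `peak_index`, `p_value`, `significant`, and a list-column
#'   `leading_edge`; attribute `"skipped"` holds a data frame of skipped
#'   sets and reasons.
#' @export
run_gsea_collection <- function(ranked, collection, cfg = gsea_config(),
                                expr = NULL, labels = NULL,
                                metric = "signal_to_noise") {
  stopifnot(inherits(collection, "gene_set_collection"))
  if (is.null(cfg$seed)) stop("gsea_config$seed must be set")

  skipped <- data.frame(set = character(0), reason = character(0),
                        stringsAsFactors = FALSE)
  rows <- list()
  universe <- ranked$gene
  for (i in seq_along(collection$sets)) {
    nm <- names(collection$sets)[i]
    eff <- intersect(collection$sets[[i]], universe)
    if (length(eff) < cfg$min_set_size || length(eff) > cfg$max_set_size) {
      skipped <- rbind(skipped, data.frame(
        set = nm,
        reason = sprintf("effective size %d outside [%d, %d]",
                         length(eff), cfg$min_set_size, cfg$max_set_size),
        stringsAsFactors = FALSE))
      next
    }
    es_res <- enrichment_score(ranked, eff, cfg$weight_exponent)
    cfg_i <- cfg
    cfg_i$seed <- cfg$seed + i
    p <- gsea_pvalue(ranked, eff, cfg_i, expr = expr, labels = labels,
                     metric = metric)
    rows[[nm]] <- data.frame(
      set = nm,
      collection = collection$info$collection[i],
      size = length(eff),
      es = es_res$es,
      peak_index = es_res$peak_index,
      p_value = p,
      significant = p < cfg$alpha,
      stringsAsFactors = FALSE
    )
    rows[[nm]]$leading_edge <- list(leading_edge(ranked, eff, es_res))
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(set = character(0), collection = character(0),
               size = integer(0), es = numeric(0), peak_index = integer(0),
               p_value = numeric(0), significant = logical(0),
               leading_edge = I(list()), stringsAsFactors = FALSE)
  out <- out[order(out$p_value, out$set), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  out
}
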