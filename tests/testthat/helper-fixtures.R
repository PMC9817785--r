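# Shared fixtures and independent oracles for the test suite.

# small simulation config used by most unit tests
small_cfg <- function(seed, ...) {
  args <- list(n_genes = 400L, group_sizes = c(5L, 6L),
               de_fraction = 0.1, true_lfc = 2, dispersion = 0.2,
               n_sets = 12L, set_size_min = 8L, set_size_max = 25L,
               n_enriched_sets = 3L, probes_per_gene_max = 4L,
               seed = seed)
  args[names(list(...))] <- list(...)
  do.call(sim_config, args)
}

# Brute-force running-sum oracle, written independently of the package
# implementation: explicit position-by-position walk of the ranked list.
es_oracle <- function(metric, hits, p_w) {
  N <- length(metric)
  nh <- sum(hits)
  w <- abs(metric[hits])^p_w
  if (sum(w) == 0) w <- rep(1, nh)
  w <- w / sum(w)
  rs <- numeric(N)
  cur <- 0
  k <- 0
  for (i in seq_len(N)) {
    if (hits[i]) {
      k <- k + 1
      cur <- cur + w[k]
    } else {
      cur <- cur - 1 / (N - nh)
    }
    rs[i] <- cur
  }
  peak <- which.max(abs(rs))
  list(es = rs[peak], peak_index = peak, final = rs[N])
}

# tiny ranked list builder
mk_ranked <- function(metric, genes = sprintf("g%02d", seq_along(metric))) {
  out <- data.frame(gene = genes, metric = metric,
                    stringsAsFactors = FALSE)
  out[order(-out$metric, out$gene), ]
}
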