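test_that("signal-to-noise ranking applies the variance floors", {
  expr <- rbind(A = c(2, 2, 4, 4),
                B = c(1, 3, 1, 3))
  colnames(expr) <- paste0("s", 1:4)
  labels <- c("negative", "negative", "positive", "positive")
  rk <- rank_genes(expr, labels)
  # gene A: sd floors 0.2*|mu| give (4-2)/(0.8+0.4)
  expect_equal(rk$metric[rk$gene == "A"], 2 / 1.2, tolerance = 1e-12)
  # zero-mean group floors at 0.2 absolute
  expr0 <- rbind(Z = c(0, 0, 1, 1))
  colnames(expr0) <- paste0("s", 1:4)
  rk0 <- rank_genes(expr0, labels)
  expect_equal(rk0$metric, 1 / (0.2 + 0.2))
})

test_that("ranking is antisymmetric in the labels and breaks ties by id", {
  cfg <- small_cfg(seed = 31)
  sim <- gen_count_matrix(cfg)
  norm <- normalize_counts(sim$counts, size_factors(sim$counts))
  lab <- sim$sample_info$group
  rk <- rank_genes(norm, lab)
  flipped <- rank_genes(norm, ifelse(lab == "positive", "negative",
                                     "positive"))
  flipped <- flipped[match(rk$gene, flipped$gene), ]
  expect_equal(flipped$metric, -rk$metric)

  tied <- rbind(b2 = c(1, 1, 2, 2), a1 = c(1, 1, 2, 2))
  colnames(tied) <- paste0("s", 1:4)
  rkt <- rank_genes(tied, c("negative", "negative", "positive", "positive"))
  expect_identical(rkt$gene, c("a1", "b2"))
})

test_that("enrichment score reproduces hand-computed running sums", {
  rk <- mk_ranked(5:1)
  # hits at ranks 1 and 3, unweighted: 0.5, 0.1667, 0.6667, 0.3333, 0
  res <- enrichment_score(rk, c("g01", "g03"), weight_exponent = 0)
  expect_equal(res$es, 2 / 3, tolerance = 1e-12)
  expect_identical(res$peak_index, 3L)
  expect_identical(leading_edge(rk, c("g01", "g03"), res), c("g01", "g03"))

  # single-member set ranked first / last
  first <- enrichment_score(rk, "g01", weight_exponent = 0)
  expect_equal(first$es, 1)
  expect_identical(first$peak_index, 1L)

  rk10 <- mk_ranked(10:1)
  last <- enrichment_score(rk10, "g10", weight_exponent = 0)
  expect_equal(last$es, -1)
  expect_identical(last$peak_index, 9L)
  expect_identical(leading_edge(rk10, "g10", last), "g10")

  expect_error(enrichment_score(rk, "absent"), "no member")
  expect_error(enrichment_score(rk, rk$gene), "whole ranked list")
})

test_that("enrichment score agrees exhaustively with the brute-force oracle", {
  # every hit configuration for lists up to length 8, both exponents
  for (N in 2:8) {
    set.seed(N)
    metric <- sort(round(rnorm(N), 3), decreasing = TRUE)
    rk <- mk_ranked(metric)
    for (mask in 1:(2^N - 2)) {
      hits <- as.logical(bitwAnd(mask, 2^(0:(N - 1))))
      members <- rk$gene[hits]
      for (p_w in c(0, 1)) {
        mine <- enrichment_score(rk, members, p_w)
        ref <- es_oracle(rk$metric, hits, p_w)
        expect_equal(mine$es, ref$es, tolerance = 1e-12)
        expect_identical(mine$peak_index, ref$peak_index)
        # running sum conservation
        expect_equal(ref$final, 0, tolerance = 1e-12)
        expect_lte(abs(mine$es), 1)
      }
    }
  }
})

test_that("enrichment score matches fgsea on random configurations", {
  skip_if_not_installed("fgsea")
  set.seed(32)
  stats <- sort(setNames(rnorm(200), sprintf("G%03d", 1:200)),
                decreasing = TRUE)
  rk <- data.frame(gene = names(stats), metric = as.numeric(stats),
                   stringsAsFactors = FALSE)
  for (i in 1:20) {
    members <- sample(names(stats), sample(3:40, 1))
    idx <- which(names(stats) %in% members)
    for (p_w in c(0, 1)) {
      expect_equal(enrichment_score(rk, members, p_w)$es,
                   fgsea::calcGseaStat(stats, idx, gseaParam = p_w),
                   tolerance = 1e-9)
    }
  }
})

test_that("fast permutation scorer agrees with the full running sum", {
  set.seed(33)
  for (i in 1:200) {
    N <- sample(5:60, 1)
    nh <- sample(1:(N - 1), 1)
    metric <- sort(rnorm(N), decreasing = TRUE)
    rk <- mk_ranked(metric, genes = sprintf("x%03d", 1:N))
    pos <- sort(sample.int(N, nh))
    members <- rk$gene[pos]
    for (p_w in c(0, 1)) {
      full <- enrichment_score(rk, members, p_w)
      fast <- her2lead:::.es_from_positions(
        pos, abs(rk$metric[pos])^p_w, N)
      expect_equal(abs(fast), abs(full$es), tolerance = 1e-12)
    }
  }
})

test_that("leading edge sits on the correct side of the peak", {
  set.seed(34)
  for (i in 1:50) {
    N <- sample(10:80, 1)
    rk <- mk_ranked(sort(rnorm(N), decreasing = TRUE),
                    genes = sprintf("x%03d", 1:N))
    members <- sample(rk$gene, sample(2:8, 1))
    res <- enrichment_score(rk, members, 1)
    le <- leading_edge(rk, members, res)
    expect_true(all(le %in% members))
    expect_gte(length(le), 1)
    ranks <- match(le, rk$gene)
    if (res$es >= 0) expect_true(all(ranks <= res$peak_index))
    else expect_true(all(ranks >= res$peak_index))
  }
})

test_that("permutation p-values follow the add-one formula and are reproducible", {
  rk <- mk_ranked(20:1, genes = sprintf("x%02d", 1:20))
  cfg <- gsea_config(n_perm = 99, seed = 5, weight_exponent = 0)
  # a set at the very top should beat (nearly) every permutation
  p_top <- gsea_pvalue(rk, c("x01", "x02", "x03"), cfg)
  expect_gte(p_top, 1 / 100)
  expect_gt(p_top, 0)
  expect_lte(p_top, 1)
  # add-one formula puts p on the 1/(n_perm + 1) grid
  expect_lt(abs(p_top * 100 - round(p_top * 100)), 1e-9)
  expect_identical(p_top, gsea_pvalue(rk, c("x01", "x02", "x03"), cfg))
  cfg2 <- cfg; cfg2$seed <- 6L
  # a different seed may move p, but both remain valid probabilities
  expect_gt(gsea_pvalue(rk, c("x01", "x02", "x03"), cfg2), 0)
  expect_error(gsea_pvalue(rk, "x01", gsea_config(n_perm = 9)), "seed")
})

test_that("phenotype permutation enumerates exhaustively when few are distinct", {
  cfg <- small_cfg(seed = 35, n_genes = 60L, group_sizes = c(2L, 3L))
  sim <- gen_count_matrix(cfg)
  norm <- normalize_counts(sim$counts, size_factors(sim$counts))
  lab <- sim$sample_info$group
  rk <- rank_genes(norm, lab)
  members <- rk$gene[c(1, 3, 5, 8)]
  gcfg <- gsea_config(n_perm = 999, perm_mode = "phenotype", seed = 1)
  expect_warning(
    p <- gsea_pvalue(rk, members, gcfg, expr = norm, labels = lab),
    "enumerating exhaustively")
  # choose(5, 3) = 10 distinct assignments -> p on the /11 grid
  expect_true(abs(p * 11 - round(p * 11)) < 1e-9)
})

test_that("collection scoring filters by effective size, flags and sorts", {
  rk <- mk_ranked(30:1, genes = sprintf("x%02d", 1:30))
  coll <- gene_set_collection(
    list(top = c("x01", "x02", "x03", "x04", "x05"),
         tiny = c("x01", "x02"),
         foreign = c("z1", "z2", "z3", "z4", "z5", "x07"),
         mid = c("x10", "x15", "x20", "x25", "x30")),
    c("C2", "C5-BP", "C6", "C7"))
  cfg <- gsea_config(n_perm = 199, seed = 9, min_set_size = 3,
                     weight_exponent = 0)
  res <- run_gsea_collection(rk, coll, cfg)
  skipped <- attr(res, "skipped")
  expect_setequal(skipped$set, c("tiny", "foreign"))
  expect_setequal(res$set, c("top", "mid"))
  expect_identical(res$significant, res$p_value < cfg$alpha)
  expect_false(is.unsorted(res$p_value))
  # leading edges are subsets of the effective members
  for (i in seq_len(nrow(res)))
    expect_true(all(res$leading_edge[[i]] %in% coll$sets[[res$set[i]]]))

  empty <- run_gsea_collection(rk, gene_set_collection(list()), cfg)
  expect_identical(nrow(empty), 0L)
})

test_that("planted enriched sets are detected with high power", {
  cfg <- sim_config(n_genes = 2000L, group_sizes = c(10L, 10L),
                    de_fraction = 0.1, true_lfc = 2, dispersion = 0.2,
                    n_sets = 50L, set_size_min = 15L, set_size_max = 60L,
                    n_enriched_sets = 5L, enriched_de_fraction = 0.8,
                    seed = 36)
  sim <- gen_count_matrix(cfg)
  gs <- gen_gene_sets(cfg, sim$truth)
  norm <- normalize_counts(sim$counts, size_factors(sim$counts))
  rk <- rank_genes(norm, sim$sample_info$group)
  res <- run_gsea_collection(rk, gs$collection, gsea_config(seed = 36))
  detected <- sum(gs$truth$enriched_sets %in% res$set[res$significant])
  expect_gte(detected, 4)
})
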