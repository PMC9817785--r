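test_that("count generator is deterministic and honours its truth table", {
  cfg <- small_cfg(seed = 1)
  a <- gen_count_matrix(cfg)
  b <- gen_count_matrix(cfg)
  expect_identical(a$counts, b$counts)
  expect_identical(a$truth, b$truth)
  c2 <- gen_count_matrix(small_cfg(seed = 2))
  expect_false(identical(a$counts, c2$counts))

  expect_identical(dim(a$counts), c(cfg$n_genes, sum(cfg$group_sizes)))
  expect_true(all(a$counts >= 0))
  expect_true(all(a$truth$de_genes$gene %in% rownames(a$counts)))
  # 50/50 sign split
  expect_lte(abs(sum(sign(a$truth$de_genes$true_lfc))), 1)

  none <- gen_count_matrix(small_cfg(seed = 1, de_fraction = 0))
  expect_identical(nrow(none$truth$de_genes), 0L)
})

test_that("planted fold changes shift the positive-group means", {
  cfg <- small_cfg(seed = 3, group_sizes = c(40L, 40L))
  sim <- gen_count_matrix(cfg)
  grp <- sim$sample_info$group
  de <- sim$truth$de_genes
  m_neg <- rowMeans(sim$counts[de$gene, grp == "negative", drop = FALSE])
  m_pos <- rowMeans(sim$counts[de$gene, grp == "positive", drop = FALSE])
  est <- log2((m_pos + 0.5) / (m_neg + 0.5))
  expect_lt(mean(abs(est - de$true_lfc)), 0.5)
})

test_that("NB moment structure var = mu + alpha mu^2 is recovered", {
  for (setting in list(c(mu = 4, alpha = 0.1), c(mu = 4.6, alpha = 0.2),
                       c(mu = 3.5, alpha = 0.5))) {
    cfg <- sim_config(n_genes = 2000L, group_sizes = c(25L, 25L),
                      de_fraction = 0, dispersion = setting[["alpha"]],
                      baseline_log_mean = setting[["mu"]],
                      baseline_log_sd = 0.8,
                      seed = 40 + round(10 * setting[["alpha"]]))
    sim <- gen_count_matrix(cfg)
    m <- rowMeans(sim$counts)
    v <- apply(sim$counts, 1, var)
    # pooled moment fit of the quadratic term, regression through origin
    alpha_hat <- sum((v - m) * m^2) / sum(m^4)
    expect_lt(abs(alpha_hat - setting[["alpha"]]) / setting[["alpha"]], 0.1)
  }
})

test_that("gene-set generator plants enrichment as configured", {
  cfg <- small_cfg(seed = 4, enriched_de_fraction = 0.8)
  sim <- gen_count_matrix(cfg)
  gs <- gen_gene_sets(cfg, sim$truth)
  expect_s3_class(gs$collection, "gene_set_collection")
  expect_length(gs$collection$sets, cfg$n_sets)
  sizes <- lengths(gs$collection$sets)
  expect_true(all(sizes >= cfg$set_size_min & sizes <= cfg$set_size_max))
  expect_length(gs$truth$enriched_sets, cfg$n_enriched_sets)
  expect_true(all(unlist(gs$collection$sets) %in% names(sim$truth$base_mean)))

  # planted sets: >= 80% concordant-sign DE members
  de <- sim$truth$de_genes
  for (nm in gs$truth$enriched_sets) {
    members <- gs$collection$sets[[nm]]
    in_de <- members %in% de$gene
    expect_gte(mean(in_de), 0.8)
    signs <- sign(de$true_lfc[match(members[in_de], de$gene)])
    expect_length(unique(signs), 1L)
  }

  # collection tags round-robin over the five MSigDB-style labels
  expect_setequal(unique(gs$collection$info$collection),
                  c("C2", "C5-BP", "C5-MF", "C6", "C7"))

  none <- gen_gene_sets(small_cfg(seed = 4, n_enriched_sets = 0), sim$truth)
  expect_length(none$truth$enriched_sets, 0L)

  # a driver gene is forced into every planted core
  driver <- de$gene[1]
  gd <- gen_gene_sets(cfg, sim$truth, driver_gene = driver)
  for (nm in gd$truth$enriched_sets)
    expect_true(driver %in% gd$collection$sets[[nm]])
  expect_error(gen_gene_sets(cfg, sim$truth, driver_gene = "NOT_A_GENE"),
               "driver_gene")
})

test_that("impossible planting requests error out", {
  cfg <- small_cfg(seed = 5, de_fraction = 0.01, set_size_min = 20L,
                   set_size_max = 25L, enriched_de_fraction = 1)
  sim <- gen_count_matrix(cfg)
  expect_error(gen_gene_sets(cfg, sim$truth), "not enough DE genes")
})

test_that("microarray generator produces a consistent paired matrix", {
  cfg <- small_cfg(seed = 6)
  arr <- gen_microarray(cfg)
  expect_s3_class(arr$pair, "probe_matrix_pair")
  expect_identical(dimnames(arr$pair$linear), dimnames(arr$pair$log2))
  ann <- arr$annotation

  # every probe annotated; non-control assigned probes map to one gene
  expect_setequal(ann$probe_id, rownames(arr$pair$linear))
  assigned <- ann[!ann$control & !is.na(ann$gene), ]
  expect_true(all(assigned$gene %in% sprintf("G%06d", 1:cfg$n_genes)))
  expect_false(anyDuplicated(assigned$probe_id) > 0)

  # control fraction as configured (up to rounding)
  expect_equal(sum(ann$control), round(cfg$control_probe_fraction * nrow(ann)))
  expect_true(all(startsWith(ann$probe_id[ann$control], "AFFX-")))
  expect_true(all(is.na(ann$gene[ann$control])))

  # linear and log matrices are monotone transforms per probe
  rho <- vapply(seq_len(nrow(arr$pair$linear)), function(i)
    cor(arr$pair$linear[i, ], arr$pair$log2[i, ], method = "spearman"),
    numeric(1))
  expect_true(all(rho == 1))

  # spans the MAS5 presence threshold in both directions
  lin_means <- rowMeans(arr$pair$linear)
  expect_gt(sum(lin_means > 50), 0)
  expect_gt(sum(lin_means <= 50), 0)

  expect_identical(gen_microarray(cfg)$pair, arr$pair)
})

test_that("cohort metadata ties IHC scores to marker expression", {
  cfg <- small_cfg(seed = 7)
  sim <- gen_count_matrix(cfg)
  norm <- normalize_counts(sim$counts, size_factors(sim$counts))
  marker <- sim$truth$de_genes$gene[1]

  meta <- gen_cohort_metadata(cfg, norm, marker, concordance = 1)
  expect_true(all(meta$ihc_score %in% 0:3))
  expect_identical(
    unname(classify_ihc(meta$ihc_score)),
    unname(classify_by_cohort_mean(meta$marker_expression)))

  big <- sim_config(n_genes = 50L, group_sizes = c(100L, 100L),
                    de_fraction = 0, set_size_min = 5L,
                    set_size_max = 20L, seed = 8)
  simb <- gen_count_matrix(big)
  metab <- gen_cohort_metadata(big, simb$counts, "G000001",
                               concordance = 0.5)
  agree <- mean(classify_ihc(metab$ihc_score) ==
                classify_by_cohort_mean(metab$marker_expression))
  expect_gte(agree, 0.4)
  expect_lte(agree, 0.6)

  expect_error(gen_cohort_metadata(cfg, norm, "NOPE"), "unknown marker")
})
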