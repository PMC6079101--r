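test_that("identical config and seed reproduce the experiment bit-for-bit", {
  cfg <- sim_config(n_genes = 300, design = two_group_design(6, 6),
                    temporal_group_sizes = c(g1 = 20, g2 = 0, g3 = 0, g4 = 10,
                                             g5 = 10, g6 = 0, g7 = 0),
                    predictive_gene_count = 10, seed = 7)
  a <- simulate_experiment(cfg)
  b <- simulate_experiment(cfg)
  expect_identical(a$matrix, b$matrix)
  expect_identical(a$metadata, b$metadata)
  expect_identical(a$truth, b$truth)
  c2 <- simulate_experiment(sim_config(n_genes = 300,
                                       design = two_group_design(6, 6),
                                       temporal_group_sizes = cfg$temporal_group_sizes,
                                       predictive_gene_count = 10, seed = 8))
  expect_false(identical(a$matrix, c2$matrix))
})

test_that("emitted values are non-negative with consistent dimensions and truth", {
  cfg <- sim_config(n_genes = 400, design = dg_timecourse_design(0.3),
                    temporal_group_sizes = c(g1 = 20, g2 = 5, g3 = 5, g4 = 15,
                                             g5 = 10, g6 = 5, g7 = 5),
                    predictive_gene_count = 12, seed = 11)
  sim <- simulate_experiment(cfg)
  expect_true(all(sim$matrix >= 0))
  expect_equal(dim(sim$matrix), c(400L, sum(cfg$design$n)))
  # exactly one truth record per gene and nucleus
  expect_setequal(sim$truth$gene_truth$gene, rownames(sim$matrix))
  expect_setequal(sim$truth$nucleus_truth$nucleus_id, colnames(sim$matrix))
  expect_false(anyDuplicated(sim$truth$gene_truth$gene) > 0)
  expect_false(anyDuplicated(sim$truth$nucleus_truth$nucleus_id) > 0)
  # metadata read/gene counts consistent with the matrix
  expect_equal(sim$metadata$detected_genes,
               unname(colSums(sim$matrix > 0)))
})

test_that("noise-free per-group count means match the configured model", {
  # dispersion -> 0 (Poisson), no dropout, no batch effect: empirical group
  # means must sit within 3 standard errors of the configured NB means
  des <- rbind(
    data.frame(cell_type = "DG", condition = "HC", fos = "neg", arc = "neg",
               n = 250),
    data.frame(cell_type = "DG", condition = "NE1h", fos = "pos", arc = "pos",
               n = 250))
  cfg <- sim_config(n_genes = 60, design = des, marker_genes_per_type = 0,
                    temporal_group_sizes = c(g1 = 20, g2 = 0, g3 = 0, g4 = 0,
                                             g5 = 0, g6 = 0, g7 = 0),
                    predictive_gene_count = 0, effect_size = 2,
                    dropout_rate = 0, nb_dispersion = 0, batch_count = 1,
                    batch_effect_sd = 0, down_fraction = 0, seed = 5)
  sim <- simulate_experiment(cfg, keep_counts = TRUE)
  gt <- sim$truth$gene_truth
  nt <- sim$truth$nucleus_truth
  early <- nt$nucleus_id[nt$activity_state == "early"]
  base <- nt$nucleus_id[nt$activity_state == "baseline"]
  g1 <- gt$gene[gt$temporal_group == "1" & !gt$ieg]
  # configured means recovered from the baseline group, fold-change 2^2 in
  # the early group (canonical IEGs carry their own stronger induction and
  # are excluded); Poisson SE = sqrt(mean / n)
  base_mean <- rowMeans(sim$counts[g1, base])
  early_mean <- rowMeans(sim$counts[g1, early])
  # Var(early_mean - 4 base_mean) = 4 mu / n_early + 16 mu / n_base;
  # the per-gene 3 SE band holds jointly only up to multiplicity, so the
  # family-wise bound uses a Bonferroni critical value at alpha = 0.01
  se <- sqrt(4 * base_mean / length(early) + 16 * base_mean / length(base))
  z <- abs(early_mean - 4 * base_mean) / se
  expect_gte(mean(z < 3), 0.9)
  expect_true(all(z < stats::qnorm(1 - 0.01 / (2 * length(z)))))
  # null genes in this config stay flat: no leakage of the early effect
  null_g <- gt$gene[gt$temporal_group == "none"]
  mb <- rowMeans(sim$counts[null_g, base])
  se0 <- sqrt(mb / length(early) + mb / length(base))
  z0 <- abs(rowMeans(sim$counts[null_g, early]) - mb) / se0
  expect_true(all(z0 < stats::qnorm(1 - 0.01 / (2 * length(z0)))))
})

test_that("late-signature genes do not leak into early-state nuclei", {
  cfg <- sim_config(n_genes = 300, design = dg_timecourse_design(0.5),
                    temporal_group_sizes = c(g1 = 20, g2 = 0, g3 = 0, g4 = 20,
                                             g5 = 0, g6 = 0, g7 = 0),
                    predictive_gene_count = 0, dropout_rate = 0,
                    nb_dispersion = 0, batch_count = 1, batch_effect_sd = 0,
                    down_fraction = 0, seed = 13)
  sim <- simulate_experiment(cfg, keep_counts = TRUE)
  gt <- sim$truth$gene_truth
  nt <- sim$truth$nucleus_truth
  g4 <- gt$gene[gt$temporal_group == "4"]
  early <- nt$nucleus_id[nt$activity_state == "early" &
                           nt$condition == "NE1h"]
  base <- nt$nucleus_id[nt$activity_state == "baseline"]
  m_early <- rowMeans(sim$counts[g4, early])
  m_base <- rowMeans(sim$counts[g4, base])
  se <- sqrt(m_base / length(early) + m_base / length(base))
  expect_true(all(abs(m_early - m_base) < 4 * se + 1e-9))
})

test_that("the primed fraction of single-exposure late nuclei matches config", {
  cfg <- sim_config(n_genes = 100, design = dg_timecourse_design(2),
                    temporal_group_sizes = c(g1 = 5, g2 = 0, g3 = 0, g4 = 5,
                                             g5 = 5, g6 = 0, g7 = 0),
                    predictive_gene_count = 10,
                    reactivated_fraction = 0.4, seed = 3)
  sim <- simulate_experiment(cfg)
  nt <- sim$truth$nucleus_truth
  single_late <- nt[nt$condition %in% c("NE4h", "NE5h"), ]
  phat <- mean(single_late$primed)
  n <- nrow(single_late)
  expect_lt(abs(phat - 0.4), 3 * sqrt(0.4 * 0.6 / n) + 1 / n)
  # Reactivated fraction of A>A ARC+FOS+ nuclei is exact (rounded count)
  aa <- nt[nt$condition == "AA" & nt$activity_state != "late", ]
  expect_equal(sum(aa$activity_state == "reactivated"),
               round(0.4 * nrow(aa)))
})

test_that("unsatisfiable configurations are rejected up front", {
  expect_error(
    sim_config(n_genes = 50,
               temporal_group_sizes = c(g1 = 40, g2 = 10, g3 = 10, g4 = 0,
                                        g5 = 0, g6 = 0, g7 = 0),
               design = two_group_design(4, 4), marker_genes_per_type = 10,
               predictive_gene_count = 0),
    "not satisfiable")
  expect_error(sim_config(dropout_rate = 1.5), "\\[0, 1\\]")
  expect_error(sim_config(effect_size = -1), "effect_size")
})

test_that("null effect size yields near-zero significant genes downstream", {
  cfg <- sim_config(n_genes = 400, design = two_group_design(15, 15),
                    marker_genes_per_type = 0,
                    temporal_group_sizes = c(g1 = 40, g2 = 0, g3 = 0, g4 = 0,
                                             g5 = 0, g6 = 0, g7 = 0),
                    predictive_gene_count = 0, effect_size = 0,
                    batch_count = 1, batch_effect_sd = 0, seed = 21)
  sim <- simulate_experiment(cfg)
  md <- sim$metadata
  iA <- md$nucleus_id[md$condition == "NE1h"]
  iB <- md$nucleus_id[md$condition == "HC"]
  de <- rots_test(sim$matrix[, iA], sim$matrix[, iB],
                  rots_params(B = 40, n_perm = 300))
  expect_lte(sum(de$p_adj < 0.05), 0.05 * nrow(sim$matrix))
})

test_that("simulated GO annotations are deterministic and cover every gene", {
  a <- simulate_go_annotation(50, 20, max_parents = 8, seed = 2)
  b <- simulate_go_annotation(50, 20, max_parents = 8, seed = 2)
  expect_identical(a, b)
  expect_setequal(unique(a$gene2term$gene), paste0("gene", 1:50))
  expect_true(all(table(a$gene2term$gene) >= 1))
  expect_true(all(a$parent_count >= 0 & a$parent_count <= 8))
  # single shared term implies zero pairwise distance downstream
  one <- simulate_go_annotation(10, 1, max_parents = 3, seed = 1)
  D <- go_gene_distance(paste0("gene", 1:10), one,
                        weight_fn = function(p) p + 1)
  expect_true(all(D == 0))
})
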