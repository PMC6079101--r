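test_that("fixed-regularization statistic equals hand arithmetic on toy groups", {
  # two groups of 3 with printed values
  xa <- c(2.0, 3.0, 4.0)
  xb <- c(5.0, 7.0, 6.0)
  m <- rbind(gA = c(xa, xb), gB = c(1, 1, 1, 1, 1, 1))
  colnames(m) <- paste0("n", 1:6)
  de <- rots_test(m[, 1:3], m[, 4:6],
                  rots_params(alpha1 = 0, alpha2 = 1, B = 2))
  expect_equal(de$d[de$gene == "gA"], oracle_d(xa, xb, 0, 1))
  expect_equal(de$direction[de$gene == "gA"], "down")  # A below B
  # zero-variance gene: no NaN, d = 0 when means equal
  expect_equal(de$d[de$gene == "gB"], 0)
  # alpha1 regularization protects a zero-variance shifted gene
  m2 <- rbind(gC = c(1, 1, 1, 2, 2, 2))
  colnames(m2) <- paste0("n", 1:6)
  de2 <- rots_test(m2[, 1:3, drop = FALSE], m2[, 4:6, drop = FALSE],
                   rots_params(alpha1 = 0.5, alpha2 = 1, B = 2))
  expect_equal(de2$d, 1 / 0.5)
})

test_that("permutation p-values match exhaustive enumeration on 3+3 and 4+4", {
  for (n_per in c(3, 4)) {
    set.seed(100 + n_per)
    ng <- 12
    m <- matrix(abs(rnorm(ng * 2 * n_per, 4, 1.5)), ng,
                dimnames = list(paste0("g", seq_len(ng)),
                                paste0("n", seq_len(2 * n_per))))
    m[1, seq_len(n_per)] <- m[1, seq_len(n_per)] + 3  # one shifted gene
    de <- rots_test(m[, seq_len(n_per)], m[, n_per + seq_len(n_per)],
                    rots_params(alpha1 = 0.2, alpha2 = 1, B = 2))
    expect_identical(attr(de, "p_method"), "exhaustive")
    expected <- sapply(seq_len(ng), function(g)
      oracle_perm_p(m[g, seq_len(n_per)], m[g, n_per + seq_len(n_per)],
                    0.2, 1))
    expect_equal(de$p_raw, expected, tolerance = 1e-12)
    # BH is monotone: adjusted p is non-decreasing along increasing raw p
    expect_true(all(diff(de$p_adj[order(de$p_raw)]) >= -1e-15))
    expect_true(all(de$p_adj >= de$p_raw))
  }
})

test_that("identical groups give a null result and group swap flips direction only", {
  m <- random_matrix(30, 4, seed = 5)
  de <- rots_test(m, m, rots_params(alpha1 = 0.1, alpha2 = 1, B = 2))
  expect_true(all(de$d == 0))
  expect_true(all(de$p_adj >= 0.99))
  # exchange symmetry on distinct groups (exhaustive mode is deterministic)
  m2 <- random_matrix(20, 8, seed = 6)
  p <- rots_params(alpha1 = 0.2, alpha2 = 1, B = 2)
  ab <- rots_test(m2[, 1:4], m2[, 5:8], p)
  ba <- rots_test(m2[, 5:8], m2[, 1:4], p)
  expect_equal(ab$d, ba$d)
  expect_equal(ab$p_raw, ba$p_raw)
  up <- ab$direction == "up"
  expect_true(all(ba$direction[up] == "down"))
})

test_that("planted shifts are recovered with controlled error at effect size 2", {
  # operating characteristics: 2000 genes, 20+20 nuclei, 10% balanced shifts
  sens <- fdr <- numeric(3)
  for (s in 1:3) {
    cfg <- sim_config(n_genes = 2000, design = two_group_design(20, 20),
                      marker_genes_per_type = 0,
                      temporal_group_sizes = c(g1 = 200, g2 = 0, g3 = 0,
                                               g4 = 0, g5 = 0, g6 = 0, g7 = 0),
                      effect_size = 2, predictive_gene_count = 0,
                      batch_count = 1, batch_effect_sd = 0,
                      down_fraction = 0.5, seed = s)
    sim <- simulate_experiment(cfg)
    md <- sim$metadata
    de <- rots_test(sim$matrix[, md$condition == "NE1h"],
                    sim$matrix[, md$condition == "HC"],
                    rots_params(B = 100, n_perm = 500))
    truth <- sim$truth$gene_truth$gene[sim$truth$gene_truth$temporal_group == "1"]
    sig <- de$gene[de$p_adj < 0.05]
    sens[s] <- mean(truth %in% sig)
    fdr[s] <- if (length(sig)) mean(!sig %in% truth) else 0
  }
  expect_true(all(sens >= 0.8))
  expect_true(all(fdr <= 0.1))
})

test_that("groups below two nuclei are rejected", {
  m <- random_matrix(10, 4)
  expect_error(rots_test(m[, 1, drop = FALSE], m[, 2:4]), "at least 2")
})

test_that("subsampled DEG counts rank the responsive population first", {
  des <- do.call(rbind, lapply(c("DG", "CA1", "VIP"), function(ct) rbind(
    data.frame(cell_type = ct, condition = "HC", fos = "neg", arc = "neg",
               n = 14),
    data.frame(cell_type = ct, condition = "NE1h", fos = "pos", arc = "pos",
               n = 14))))
  cfg <- sim_config(n_genes = 800, design = des, marker_genes_per_type = 10,
                    temporal_group_sizes = c(g1 = 80, g2 = 0, g3 = 0, g4 = 0,
                                             g5 = 0, g6 = 0, g7 = 0),
                    effect_size = 2, predictive_gene_count = 0,
                    batch_count = 1, batch_effect_sd = 0,
                    response_scale = c(DG = 1, CA1 = 0, VIP = 0), seed = 17)
  sim <- simulate_experiment(cfg)
  md <- sim$metadata
  res <- subsample_deg_counts(sim$matrix, md$population, md$fos_protein,
                              n_per_group = 10, reps = 3,
                              params = rots_params(B = 40, n_perm = 300),
                              seed = 4)
  # the responsive type leads in every repetition
  expect_true(all(res$counts[, "DG"] > res$counts[, "CA1"]))
  expect_true(all(res$counts[, "DG"] > res$counts[, "VIP"]))
  expect_lt(res$anova_p, 0.05)
  expect_error(
    subsample_deg_counts(sim$matrix, md$population, md$fos_protein,
                         n_per_group = 15),
    "fewer than")
})

test_that("a single repetition flags the undefined SD", {
  m <- random_matrix(50, 24, seed = 8)
  ct <- rep("DG", 24)
  fos <- rep(c("pos", "neg"), each = 12)
  res <- subsample_deg_counts(m, ct, fos, n_per_group = 10, reps = 1,
                              params = rots_params(B = 10, n_perm = 100),
                              seed = 1)
  expect_false(res$sd_defined)
  expect_true(is.na(res$summary$sd[1]))
})

test_that("overlap test matches closed-form and boundary cases", {
  U <- paste0("g", 1:10)
  # all three of A inside B of size 3: p = 1 / C(10,3) = 1/120
  r <- overlap_test(U[1:3], U[1:3], U)
  expect_equal(r$p.value, 1 / choose(10, 3), tolerance = 1e-12)
  expect_equal(unname(r$statistic), 3)
  # zero overlap: P(X >= 0) = 1
  expect_equal(overlap_test(U[1:3], U[4:6], U)$p.value, 1)
  # full sets
  expect_equal(overlap_test(U, U, U)$p.value, 1)
  expect_error(overlap_test(U[1:2], U[1:2], character(0)), "non-empty")
  expect_error(overlap_test(c(U[1], "zz"), U[1:2], U), "zz")
})
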