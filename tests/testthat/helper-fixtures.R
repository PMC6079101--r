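# Shared fixture builders for the test suite. Everything is generated in
# code; no data files.

# Minimal two-condition DG design (home cage vs 1 h FOS+).
two_group_design <- function(n_hc = 20, n_1h = 20) {
  rbind(
    data.frame(cell_type = "DG", condition = "HC", fos = "neg", arc = "neg",
               n = n_hc),
    data.frame(cell_type = "DG", condition = "NE1h", fos = "pos", arc = "pos",
               n = n_1h))
}

# Full DG time course plus double exposure, scaled by `scale`.
dg_timecourse_design <- function(scale = 1) {
  d <- rbind(
    data.frame(cell_type = "DG", condition = "HC",   fos = "neg", arc = "neg", n = 30),
    data.frame(cell_type = "DG", condition = "NE1h", fos = "pos", arc = "pos", n = 30),
    data.frame(cell_type = "DG", condition = "NE1h", fos = "neg", arc = "neg", n = 20),
    data.frame(cell_type = "DG", condition = "NE4h", fos = "neg", arc = "pos", n = 25),
    data.frame(cell_type = "DG", condition = "NE5h", fos = "neg", arc = "pos", n = 25),
    data.frame(cell_type = "DG", condition = "AA",   fos = "pos", arc = "pos", n = 88),
    data.frame(cell_type = "DG", condition = "AA",   fos = "neg", arc = "pos", n = 65))
  d$n <- pmax(4L, as.integer(round(d$n * scale)))
  d
}

# Small random expression matrix with valid dimnames.
random_matrix <- function(n_genes = 5, n_nuclei = 4, seed = 42) {
  set.seed(seed)
  m <- matrix(round(abs(rnorm(n_genes * n_nuclei, 4, 2)), 4),
              n_genes, n_nuclei,
              dimnames = list(paste0("g", seq_len(n_genes)),
                              paste0("n", seq_len(n_nuclei))))
  m
}

# Independent brute-force oracle for the regularized statistic and its
# exhaustive permutation p-values: direct arithmetic, no package internals.
oracle_d <- function(xa, xb, a1, a2) {
  na <- length(xa); nb <- length(xb)
  pooled <- sqrt(((sum((xa - mean(xa))^2) + sum((xb - mean(xb))^2)) /
                    (na + nb - 2)) * (1 / na + 1 / nb))
  den <- a1 + a2 * pooled
  if (den == 0) return(if (mean(xa) == mean(xb)) 0 else Inf)
  abs(mean(xa) - mean(xb)) / den
}

oracle_perm_p <- function(xa, xb, a1, a2) {
  x <- c(xa, xb)
  na <- length(xa)
  combos <- utils::combn(length(x), na)
  d_obs <- oracle_d(xa, xb, a1, a2)
  d_all <- apply(combos, 2, function(idx)
    oracle_d(x[idx], x[-idx], a1, a2))
  mean(d_all >= d_obs)
}

# Adjusted Rand index between two labellings (contingency-table formula).
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- comb2(sum(tab))
  expected <- sum_a * sum_b / n
  (sum_ij - expected) / ((sum_a + sum_b) / 2 - expected)
}

# Scaled-down full-pipeline configuration used by the workflow tests and
# the acceptance script (same stages and defaults, smaller problem sizes;
# cutoffs that scale with data size are scaled accordingly).
small_pipeline_config <- function(seed = 1) {
  pipeline_config(
    sim = sim_config(
      n_genes = 1200,
      design = rbind(
        data.frame(cell_type = "DG",  condition = "HC",   fos = "neg", arc = "neg", n = 25),
        data.frame(cell_type = "DG",  condition = "NE1h", fos = "pos", arc = "pos", n = 25),
        data.frame(cell_type = "DG",  condition = "NE1h", fos = "neg", arc = "neg", n = 15),
        data.frame(cell_type = "DG",  condition = "NE4h", fos = "neg", arc = "pos", n = 20),
        data.frame(cell_type = "DG",  condition = "NE5h", fos = "neg", arc = "pos", n = 20),
        data.frame(cell_type = "DG",  condition = "AA",   fos = "pos", arc = "pos", n = 60),
        data.frame(cell_type = "DG",  condition = "AA",   fos = "neg", arc = "pos", n = 40),
        data.frame(cell_type = "CA1", condition = "HC",   fos = "neg", arc = "unknown", n = 20),
        data.frame(cell_type = "CA1", condition = "NE1h", fos = "pos", arc = "unknown", n = 20)),
      marker_genes_per_type = 20,
      temporal_group_sizes = c(g1 = 80, g2 = 8, g3 = 8, g4 = 40, g5 = 30,
                               g6 = 8, g7 = 8),
      predictive_gene_count = 25),
    seed = seed,
    qc = list(min_reads = 20000, min_genes = 800),
    de = list(B = 60, n_perm = 400),
    cluster = list(split_B = 40, gini_cutoff = 0.25),
    reactivity = list(n_trees = 1000),
    gonet = list(n_terms = 120))
}

# A>A double-exposure cohort simulation shared by the reactivity and
# workflow-level tests (cached per session).
aa_cohort <- local({
  cache <- list()
  function(seed = 101) {
    key <- as.character(seed)
    if (!is.null(cache[[key]])) return(cache[[key]])
    des <- rbind(
      data.frame(cell_type = "DG", condition = "HC",   fos = "neg", arc = "neg", n = 30),
      data.frame(cell_type = "DG", condition = "NE1h", fos = "pos", arc = "pos", n = 30),
      data.frame(cell_type = "DG", condition = "NE4h", fos = "neg", arc = "pos", n = 25),
      data.frame(cell_type = "DG", condition = "NE5h", fos = "neg", arc = "pos", n = 25),
      data.frame(cell_type = "DG", condition = "AA",   fos = "pos", arc = "pos", n = 88),
      data.frame(cell_type = "DG", condition = "AA",   fos = "neg", arc = "pos", n = 65))
    sim <- simulate_experiment(sim_config(
      n_genes = 2000, design = des, marker_genes_per_type = 0,
      temporal_group_sizes = c(g1 = 100, g2 = 0, g3 = 0, g4 = 40, g5 = 30,
                               g6 = 0, g7 = 0),
      predictive_gene_count = 25, effect_size = 2, seed = seed))
    nt <- sim$truth$nucleus_truth
    lab <- rep(NA_character_, nrow(nt))
    lab[nt$condition == "AA" & nt$activity_state == "reactivated"] <- "Reactivated"
    lab[nt$condition == "AA" & nt$activity_state == "early"] <- "NewlyActivated"
    lab[nt$condition == "AA" & nt$activity_state == "late"] <- "NotReactivated"
    out <- list(sim = sim, X = sim$matrix, nt = nt, md = sim$metadata,
                aa_ids = nt$nucleus_id[!is.na(lab)],
                labels = setNames(lab[!is.na(lab)],
                                  nt$nucleus_id[!is.na(lab)]))
    cache[[key]] <<- out
    out
  }
})

# Full predictive-gene selection + model training on the default cohort.
fit_cohort_model <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    co <- aa_cohort()
    pars <- rots_params(B = 100, n_perm = 500)
    r_ids <- names(co$labels)[co$labels == "Reactivated"]
    nr_ids <- names(co$labels)[co$labels == "NotReactivated"]
    de_r <- rots_test(co$X[, r_ids], co$X[, nr_ids], pars)
    de_1h <- rots_test(co$X[, co$nt$nucleus_id[co$nt$condition == "NE1h"]],
                       co$X[, co$nt$nucleus_id[co$nt$condition == "HC"]],
                       pars)
    batch <- batch_associated_genes(co$X, co$md$batch_id)
    genes <- select_predictive_genes(de_r, co$X, r_ids, de_1h, batch)
    model <- train_reactivity_models(co$X[, co$aa_ids],
                                     co$labels[co$aa_ids], genes,
                                     n_trees = 1000, seed = 5)
    cache <<- list(co = co, de_r = de_r, de_1h = de_1h, batch = batch,
                   genes = genes, model = model)
    cache
  }
})
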