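#' Simulation configuration for a synthetic activity-signature experiment
#'
#' Builds the parameter set for [simulate_experiment()]. Defaults describe a
#' desk-scale cohort with the structure the downstream analysis assumes:
#' cell-type marker genes, FOS/ARC protein labels across home-cage (HC),
#' single novel-environment exposure (1 h, 4 h, 5 h) and double-exposure
#' (A>A, A>C) conditions, seven temporal gene groups (early / sustained /
#' late dynamics), and a bimodally expressed predictive gene set carried by
#' Reactivated nuclei and by a subset of single-exposure late nuclei.
#'
#' @param n_genes total number of genes.
#' @param design data.frame with columns `cell_type`, `condition`, `fos`,
#'   `arc`, `n` giving nucleus counts per stratum; default [default_design()].
#' @param marker_genes_per_type marker genes planted per cell type.
#' @param temporal_group_sizes named integer vector `g1`..`g7`; sizes of the
#'   temporal groups (g1 early, g5 sustained, g4 late).
#' @param effect_size mean log2 shift of induced genes, log2(TPM+1) units.
#' @param predictive_gene_count number of reactivity-predictive genes.
#' @param reactivated_fraction fraction of A>A ARC+FOS+ nuclei that are
#'   Reactivated; also the fraction of single-exposure late nuclei that are
#'   primed (carry the predictive signature).
#' @param reactivated_late_scale multiplier on the late/sustained (group
#'   4/5) effect in Reactivated and primed nuclei. Reactivation selects the
#'   high tail of the late program, so conditioning on it leaves a graded
#'   difference against Not Reactivated cells (default 1.5).
#' @param dropout_rate independent Bernoulli zeroing probability for
#'   lowly expressed genes; the per-entry rate decays with the expected
#'   count as `dropout_rate * exp(-mu / dropout_decay)`, so deeply covered
#'   genes are essentially never zeroed (detection-efficiency behaviour).
#' @param dropout_decay count scale of the dropout decay (default 5).
#' @param nb_dispersion negative-binomial dispersion (0 gives Poisson).
#' @param batch_count,batch_effect_sd number of batches and SD of the
#'   gene-wise additive log2 batch shift.
#' @param baseline_mean_range range of per-gene baseline mean counts.
#' @param response_scale named vector scaling `effect_size` per cell type;
#'   default plants the activity response in DG only.
#' @param down_fraction fraction of group-1/group-4 genes that are repressed
#'   rather than induced.
#' @param marker_shift log2 elevation of marker genes in their own type.
#' @param read_multiplier aligned reads simulated per molecule count.
#' @param fos_low_fraction fraction of HC FOS- nuclei re-labelled FOS-low
#'   with a half-scaled early response (0 disables; default off).
#' @param seed integer RNG seed.
#' @return object of class `sim_config` (a validated list).
#' @seealso [simulate_experiment()]
#' @export
sim_config <- function(n_genes = 5000,
                       design = default_design(),
                       marker_genes_per_type = 30,
                       temporal_group_sizes = c(g1 = 252, g2 = 25, g3 = 25,
                                                g4 = 129, g5 = 107, g6 = 25,
                                                g7 = 25),
                       effect_size = 2,
                       predictive_gene_count = 60,
                       reactivated_fraction = 0.4,
                       reactivated_late_scale = 1.5,
                       dropout_rate = 0.1,
                       dropout_decay = 5,
                       nb_dispersion = 0.3,
                       batch_count = 2,
                       batch_effect_sd = 0.15,
                       baseline_mean_range = c(2, 50),
                       response_scale = c(DG = 1, CA1 = 0, VIP = 0),
                       down_fraction = 0.25,
                       marker_shift = 3,
                       read_multiplier = 25,
                       fos_low_fraction = 0,
                       seed = 1) {
  n_genes <- check_count(n_genes, "n_genes", 1L)
  marker_genes_per_type <- check_count(marker_genes_per_type,
                                       "marker_genes_per_type")
  predictive_gene_count <- check_count(predictive_gene_count,
                                       "predictive_gene_count")
  batch_count <- check_count(batch_count, "batch_count", 1L)
  check_fraction(reactivated_fraction, "reactivated_fraction")
  check_fraction(dropout_rate, "dropout_rate")
  check_fraction(down_fraction, "down_fraction")
  check_fraction(fos_low_fraction, "fos_low_fraction")
  if (effect_size < 0) stopf("'effect_size' must be >= 0")
  if (dropout_decay <= 0) stopf("'dropout_decay' must be > 0")
  if (reactivated_late_scale < 0)
    stopf("'reactivated_late_scale' must be >= 0")
  if (nb_dispersion < 0) stopf("'nb_dispersion' must be >= 0")
  if (batch_effect_sd < 0) stopf("'batch_effect_sd' must be >= 0")
  if (length(baseline_mean_range) != 2L || any(baseline_mean_range <= 0) ||
      diff(baseline_mean_range) < 0)
    stopf("'baseline_mean_range' must be an increasing pair of positive reals")
  req <- c("cell_type", "condition", "fos", "arc", "n")
  if (!is.data.frame(design) || !all(req %in% names(design)))
    stopf("'design' must be a data.frame with columns %s",
          paste(req, collapse = ", "))
  if (any(design$n < 0)) stopf("design nucleus counts must be >= 0")
  bad <- setdiff(design$condition, c("HC", "NE1h", "NE4h", "NE5h", "AA", "AC"))
  if (length(bad))
    stopf("unknown condition(s) in design: %s", paste(bad, collapse = ", "))
  if (length(temporal_group_sizes) != 7L)
    stopf("'temporal_group_sizes' must have 7 entries (g1..g7)")
  names(temporal_group_sizes) <- paste0("g", 1:7)
  types <- unique(design$cell_type)
  n_structured <- sum(temporal_group_sizes) +
    marker_genes_per_type * length(types) + predictive_gene_count
  if (n_structured > n_genes)
    stopf(paste0("configuration not satisfiable: %d structured genes ",
                 "(markers + temporal groups + predictive) exceed n_genes = %d"),
          n_structured, n_genes)
  structure(list(
    n_genes = n_genes, design = design,
    marker_genes_per_type = marker_genes_per_type,
    temporal_group_sizes = temporal_group_sizes,
    effect_size = effect_size,
    predictive_gene_count = predictive_gene_count,
    reactivated_fraction = reactivated_fraction,
    reactivated_late_scale = reactivated_late_scale,
    dropout_rate = dropout_rate, dropout_decay = dropout_decay,
    nb_dispersion = nb_dispersion,
    batch_count = batch_count, batch_effect_sd = batch_effect_sd,
    baseline_mean_range = baseline_mean_range,
    response_scale = response_scale, down_fraction = down_fraction,
    marker_shift = marker_shift, read_multiplier = read_multiplier,
    fos_low_fraction = fos_low_fraction, seed = seed),
    class = "sim_config")
}

#' Default per-stratum nucleus counts
#'
#' Mirrors the reported A>A cohort split (15 training nuclei per class plus a
#' 37/50/21 test set, i.e. 88 ARC+FOS+ and 65 ARC+FOS- double-exposure DG
#' nuclei) and uses round counts for the single-exposure time course and the
#' CA1/VIP comparison populations.
#'
#' @return data.frame with columns `cell_type`, `condition`, `fos`, `arc`, `n`.
#' @export
default_design <- function() {
  d <- rbind(
    data.frame(cell_type = "DG", condition = "HC",   fos = "neg", arc = "neg", n = 40),
    data.frame(cell_type = "DG", condition = "NE1h", fos = "pos", arc = "pos", n = 40),
    data.frame(cell_type = "DG", condition = "NE1h", fos = "neg", arc = "neg", n = 40),
    data.frame(cell_type = "DG", condition = "NE4h", fos = "neg", arc = "pos", n = 30),
    data.frame(cell_type = "DG", condition = "NE5h", fos = "neg", arc = "pos", n = 30),
    data.frame(cell_type = "DG", condition = "AA",   fos = "pos", arc = "pos", n = 88),
    data.frame(cell_type = "DG", condition = "AA",   fos = "neg", arc = "pos", n = 65),
    data.frame(cell_type = "DG", condition = "AC",   fos = "pos", arc = "pos", n = 30),
    data.frame(cell_type = "DG", condition = "AC",   fos = "neg", arc = "pos", n = 30),
    data.frame(cell_type = "CA1", condition = "HC",   fos = "neg", arc = "unknown", n = 25),
    data.frame(cell_type = "CA1", condition = "NE1h", fos = "pos", arc = "unknown", n = 25),
    data.frame(cell_type = "CA1", condition = "NE1h", fos = "neg", arc = "unknown", n = 25),
    data.frame(cell_type = "VIP", condition = "HC",   fos = "neg", arc = "unknown", n = 25),
    data.frame(cell_type = "VIP", condition = "NE1h", fos = "pos", arc = "unknown", n = 25),
    data.frame(cell_type = "VIP", condition = "NE1h", fos = "neg", arc = "unknown", n = 25))
  d
}

# Real gene symbols planted at the head of each structured gene block so the
# synthetic data carries resolvable anchors (Arc in particular).
.sim_symbols <- list(
  g1 = c("Fos", "Fosb", "Egr1", "Nr4a2", "Junb", "Kdm6b"),
  g5 = c("Arc", "Nptx2", "Gadd45b", "Synpo"),
  g4 = c("Sorcs3", "Dlg2", "Gabra4"),
  pred = c("Blnk", "Tnik", "Acan", "Entpd4", "Hes7"),
  marker_DG = "Prox1")

#' Simulate a synthetic single-nucleus activity-signature experiment
#'
#' Draws per-gene, per-nucleus molecule counts from a negative-binomial model
#' with cell-type- and activity-state-dependent means, applies an optional
#' gene-wise additive log2 batch shift and independent dropout, converts to
#' TPM and returns expression on the log2(TPM+1) scale together with nucleus
#' metadata and complete ground truth.
#'
#' Temporal dynamics follow the seven-group scheme: group 1 genes are induced
#' only in early-state (1 h FOS+) nuclei, group 4 only in late-state (4/5 h
#' ARC+FOS-) nuclei, group 5 in both, groups 2/3/6/7 in the remaining
#' time-point patterns. Predictive genes are expressed in Reactivated nuclei
#' and in a `reactivated_fraction`-sized primed subset of single-exposure late
#' nuclei, and are near-absent elsewhere, producing the bimodal pattern the
#' reactivity analysis relies on.
#'
#' @param config a [sim_config()] object.
#' @param keep_counts keep the raw count matrix in the result (for
#'   diagnostics); default FALSE.
#' @return list of class `sim_experiment` with elements `matrix` (genes x
#'   nuclei, log2(TPM+1)), `metadata` (data.frame), `truth` (list with
#'   `nucleus_truth` and `gene_truth` data.frames) and optionally `counts`.
#' @export
simulate_experiment <- function(config = sim_config(), keep_counts = FALSE) {
  if (!inherits(config, "sim_config"))
    stopf("'config' must be created by sim_config()")
  with_seed(config$seed, simulate_experiment_impl(config, keep_counts))
}

simulate_experiment_impl <- function(cfg, keep_counts) {
  types <- unique(cfg$design$cell_type)
  gs <- cfg$temporal_group_sizes
  n_mark <- cfg$marker_genes_per_type * length(types)

  ## ---- gene truth ----
  gene_id <- sprintf("gene%05d", seq_len(cfg$n_genes))
  temporal_group <- rep("none", cfg$n_genes)
  marker_of <- rep("none", cfg$n_genes)
  predictive <- rep(FALSE, cfg$n_genes)
  direction <- rep("none", cfg$n_genes)

  pos <- 0L
  take <- function(k) {
    idx <- pos + seq_len(k); pos <<- pos + k; idx
  }
  marker_idx <- lapply(setNames(types, types), function(ct)
    take(cfg$marker_genes_per_type))
  group_idx <- lapply(setNames(1:7, paste0("g", 1:7)), function(g)
    take(gs[[g]]))
  pred_idx <- take(cfg$predictive_gene_count)

  for (ct in types) {
    marker_of[marker_idx[[ct]]] <- ct
    direction[marker_idx[[ct]]] <- "up"
  }
  for (g in 1:7) {
    idx <- group_idx[[g]]
    temporal_group[idx] <- as.character(g)
    direction[idx] <- "up"
    if (g %in% c(1, 4) && length(idx) > 1) {
      ndown <- floor(cfg$down_fraction * length(idx))
      if (ndown > 0) direction[idx[seq_len(ndown)]] <- "down"
    }
  }
  predictive[pred_idx] <- TRUE
  direction[pred_idx] <- "up"
  if (cfg$predictive_gene_count > 3) {
    ndown <- floor(cfg$down_fraction * cfg$predictive_gene_count)
    if (ndown > 0)
      direction[pred_idx[seq_len(ndown)]] <- "down"
  }

  # plant recognisable symbols at the head of the blocks they belong to;
  # named temporal genes are canonical IEG-like genes: near-zero baseline
  # and strong induction (see below)
  ieg_idx <- integer(0)
  put_names <- function(idx, syms, ieg = FALSE) {
    k <- min(length(idx), length(syms))
    gene_id[idx[seq_len(k)]] <<- syms[seq_len(k)]
    if (ieg) ieg_idx <<- c(ieg_idx, idx[seq_len(k)])
  }
  # keep directions of named genes "up" (they are canonical induced genes)
  if (gs[["g1"]] > 0) {
    put_names(group_idx[["g1"]], .sim_symbols$g1, ieg = TRUE)
    direction[group_idx[["g1"]][seq_len(min(gs[["g1"]], length(.sim_symbols$g1)))]] <- "up"
  }
  if (gs[["g5"]] > 0) put_names(group_idx[["g5"]], .sim_symbols$g5, ieg = TRUE)
  if (gs[["g4"]] > 0) {
    put_names(group_idx[["g4"]], .sim_symbols$g4, ieg = TRUE)
    direction[group_idx[["g4"]][seq_len(min(gs[["g4"]], length(.sim_symbols$g4)))]] <- "up"
  }
  if (cfg$predictive_gene_count > 0) {
    put_names(pred_idx, .sim_symbols$pred)
    direction[pred_idx[seq_len(min(length(pred_idx), length(.sim_symbols$pred)))]] <- "up"
  }
  if ("DG" %in% types && cfg$marker_genes_per_type > 0)
    put_names(marker_idx[["DG"]], .sim_symbols$marker_DG)

  gene_truth <- data.frame(gene = gene_id, temporal_group = temporal_group,
                           marker_of = marker_of, predictive = predictive,
                           direction = direction,
                           ieg = seq_len(cfg$n_genes) %in% ieg_idx,
                           stringsAsFactors = FALSE)

  ## ---- nucleus truth ----
  des <- cfg$design[cfg$design$n > 0, , drop = FALSE]
  nuc <- do.call(rbind, lapply(seq_len(nrow(des)), function(i) {
    r <- des[i, ]
    data.frame(cell_type = r$cell_type, condition = r$condition,
               fos = r$fos, arc = r$arc,
               stringsAsFactors = FALSE)[rep(1, r$n), , drop = FALSE]
  }))
  n_nuc <- nrow(nuc)
  nuc$nucleus_id <- sprintf("nuc%04d", seq_len(n_nuc))
  rownames(nuc) <- NULL

  # activity state per stratum
  state <- rep("baseline", n_nuc)
  primed <- rep(FALSE, n_nuc)
  early1h <- nuc$condition == "NE1h" & nuc$fos == "pos"
  late4 <- nuc$condition == "NE4h" & nuc$arc == "pos" & nuc$fos == "neg"
  late5 <- nuc$condition == "NE5h" & nuc$arc == "pos" & nuc$fos == "neg"
  late2x <- nuc$condition %in% c("AA", "AC") & nuc$arc == "pos" & nuc$fos == "neg"
  dbl_pos <- nuc$condition %in% c("AA", "AC") & nuc$arc == "pos" & nuc$fos == "pos"
  state[early1h] <- "early"
  state[late4 | late5 | late2x] <- "late"
  state[dbl_pos] <- "early"          # Newly Activated unless re-selected below
  aa_pos <- which(nuc$condition == "AA" & nuc$arc == "pos" & nuc$fos == "pos")
  if (length(aa_pos)) {
    n_re <- round(cfg$reactivated_fraction * length(aa_pos))
    re <- sample(aa_pos, n_re)
    state[re] <- "reactivated"
  }
  # primed subset of single-exposure late nuclei carries the predictive set
  single_late <- which(late4 | late5)
  if (length(single_late)) {
    n_pr <- round(cfg$reactivated_fraction * length(single_late))
    primed[sample(single_late, n_pr)] <- TRUE
  }
  # optional FOS-low intermediate state (half-scaled early response)
  fos_low <- rep(FALSE, n_nuc)
  if (cfg$fos_low_fraction > 0) {
    hc_neg <- which(nuc$condition == "HC" & nuc$fos == "neg")
    n_low <- round(cfg$fos_low_fraction * length(hc_neg))
    if (n_low > 0) {
      low <- sample(hc_neg, n_low)
      fos_low[low] <- TRUE
      nuc$fos[low] <- "low"
    }
  }

  batch <- sample(rep_len(seq_len(cfg$batch_count), n_nuc))
  mouse <- paste0("m", as.integer(factor(nuc$condition)) * 2 -
                    (seq_len(n_nuc) %% 2))

  ## ---- expected counts ----
  base_mean <- runif(cfg$n_genes, cfg$baseline_mean_range[1],
                     cfg$baseline_mean_range[2])
  # predictive genes get dedicated on/off means for clean bimodality, with
  # heterogeneous strengths (real predictive genes differ widely in
  # importance)
  up_pred <- pred_idx[direction[pred_idx] == "up"]
  dn_pred <- pred_idx[direction[pred_idx] == "down"]
  pred_on <- 2^runif(length(up_pred), 3, 5.5)     # 8 - 45 counts when on
  pred_dn_base <- runif(length(dn_pred), 10, 40)
  pred_dn_off <- runif(length(dn_pred), 0.2, 1)
  base_mean[up_pred] <- 0.2
  base_mean[dn_pred] <- pred_dn_base
  # canonical IEGs: near-zero baseline so FOS- nuclei sit below the Arc
  # discordance threshold, induced to ~30 counts when their group is on
  base_mean[ieg_idx] <- 0.1

  # log2 effect matrix built from per-nucleus indicator classes
  is_early <- state == "early" | (state == "reactivated")
  is_late4 <- late4 | late2x | state == "reactivated"
  is_late5 <- late5 | late2x | state == "reactivated"
  scale_ct <- cfg$response_scale[nuc$cell_type]
  scale_ct[is.na(scale_ct)] <- 0
  scale_ct[fos_low] <- scale_ct[fos_low] * 0.5

  up_classes <- list(`1` = quote(is_early),
                     `2` = quote(is_late5 & !is_late4),
                     `3` = quote(is_late4 & !is_late5),
                     `4` = quote(is_late4 | is_late5),
                     `5` = quote(is_early | is_late4 | is_late5),
                     `6` = quote(is_early | (is_late5 & !is_late4)),
                     `7` = quote(is_early | (is_late4 & !is_late5)))

  lfc <- matrix(0, cfg$n_genes, n_nuc)
  for (g in 1:7) {
    idx <- group_idx[[g]]
    if (!length(idx)) next
    on <- eval(up_classes[[as.character(g)]])
    sgn <- ifelse(direction[idx] == "down", -1, 1)
    eff <- rep(cfg$effect_size, length(idx))
    eff[idx %in% ieg_idx] <- log2(30 / 0.1)
    lfc[idx, on] <- lfc[idx, on] + outer(sgn * eff, scale_ct[on])
  }
  # reactivation selects the high tail of the late program: boost the
  # late/sustained groups in reactivated and primed nuclei
  if (cfg$reactivated_late_scale != 1) {
    hi <- state == "reactivated" | primed
    if (any(hi)) for (g in c(4, 5)) {
      idx <- group_idx[[g]]
      if (!length(idx)) next
      sgn <- ifelse(direction[idx] == "down", -1, 1)
      lfc[idx, hi] <- lfc[idx, hi] +
        outer(sgn * cfg$effect_size * (cfg$reactivated_late_scale - 1),
              scale_ct[hi])
    }
  }
  for (ct in types) {
    idx <- marker_idx[[ct]]
    if (!length(idx)) next
    lfc[idx, nuc$cell_type == ct] <- lfc[idx, nuc$cell_type == ct] +
      cfg$marker_shift
  }
  if (cfg$predictive_gene_count > 0) {
    on <- state == "reactivated" | primed
    if (length(up_pred))
      lfc[up_pred, on] <- lfc[up_pred, on] + log2(pred_on / 0.2)
    if (length(dn_pred))
      lfc[dn_pred, on] <- lfc[dn_pred, on] -
        log2(pred_dn_base / pred_dn_off)
  }

  mu <- base_mean * 2^lfc
  if (cfg$batch_effect_sd > 0) {
    bshift <- matrix(rnorm(cfg$n_genes * cfg$batch_count, 0,
                           cfg$batch_effect_sd),
                     cfg$n_genes, cfg$batch_count)
    mu <- mu * 2^bshift[, batch, drop = FALSE]
  }

  ## ---- draws, dropout, TPM ----
  n_entries <- length(mu)
  counts <- if (cfg$nb_dispersion > 0) {
    matrix(rnbinom(n_entries, mu = mu, size = 1 / cfg$nb_dispersion),
           cfg$n_genes, n_nuc)
  } else {
    matrix(stats::rpois(n_entries, lambda = mu), cfg$n_genes, n_nuc)
  }
  if (cfg$dropout_rate > 0) {
    p_drop <- cfg$dropout_rate * exp(-mu / cfg$dropout_decay)
    counts <- counts * (runif(n_entries) >= p_drop)
  }
  dimnames(counts) <- list(gene_id, nuc$nucleus_id)

  lib <- colSums(counts)
  lib[lib == 0] <- 1
  expr <- log2(sweep(counts, 2, lib, "/") * 1e6 + 1)

  metadata <- data.frame(
    nucleus_id = nuc$nucleus_id,
    condition = nuc$condition,
    population = nuc$cell_type,
    fos_protein = nuc$fos,
    arc_protein = nuc$arc,
    mouse_id = mouse,
    batch_id = paste0("b", batch),
    total_aligned_reads = as.integer(round(colSums(counts) *
                                             cfg$read_multiplier)),
    detected_genes = as.integer(colSums(counts > 0)),
    stringsAsFactors = FALSE)

  nucleus_truth <- data.frame(
    nucleus_id = nuc$nucleus_id, cell_type = nuc$cell_type,
    condition = nuc$condition, activity_state = state,
    primed = primed, batch = paste0("b", batch), stringsAsFactors = FALSE)

  out <- list(matrix = expr, metadata = metadata,
              truth = list(nucleus_truth = nucleus_truth,
                           gene_truth = gene_truth),
              config = cfg)
  if (keep_counts) out$counts <- counts
  class(out) <- "sim_experiment"
  out
}

#' @export
print.sim_experiment <- function(x, ...) {
  cat(sprintf("sim_experiment: %d genes x %d nuclei\n",
              nrow(x$matrix), ncol(x$matrix)))
  print(table(x$truth$nucleus_truth$condition,
              x$truth$nucleus_truth$activity_state))
  invisible(x)
}

#' Simulate a flat GO annotation
#'
#' Random gene-to-term memberships plus a parent count per term, as a fixture
#' for enrichment testing and the weighted cosine gene distance. Every gene
#' receives at least one term.
#'
#' @param n_genes,n_terms,max_parents positive counts.
#' @param seed integer RNG seed.
#' @param genes optional character vector of gene names (defaults to
#'   `gene1..n`).
#' @return list of class `go_annotation` with `gene2term` (data.frame
#'   gene/term), `parent_count` (named integer vector over terms).
#' @export
simulate_go_annotation <- function(n_genes, n_terms, max_parents = 10,
                                   seed = 1, genes = NULL) {
  n_genes <- check_count(n_genes, "n_genes", 1L)
  n_terms <- check_count(n_terms, "n_terms", 1L)
  max_parents <- check_count(max_parents, "max_parents", 0L)
  if (is.null(genes)) genes <- paste0("gene", seq_len(n_genes))
  if (length(genes) != n_genes) stopf("'genes' must have length n_genes")
  with_seed(seed, {
    terms <- sprintf("GO:%07d", seq_len(n_terms))
    memb <- lapply(seq_len(n_genes), function(i) {
      k <- sample(1:min(4, n_terms), 1)
      sample(terms, k)
    })
    gene2term <- data.frame(
      gene = rep(genes, lengths(memb)),
      term = unlist(memb), stringsAsFactors = FALSE)
    parent_count <- setNames(sample(0:max_parents, n_terms, replace = TRUE),
                             terms)
    go_annotation(gene2term, parent_count)
  })
}

#' Construct a GO annotation object
#'
#' @param gene2term data.frame with columns `gene` and `term`.
#' @param parent_count named non-negative integer vector; must cover every
#'   term referenced by `gene2term`.
#' @return list of class `go_annotation`.
#' @export
go_annotation <- function(gene2term, parent_count) {
  if (!all(c("gene", "term") %in% names(gene2term)))
    stopf("'gene2term' needs columns 'gene' and 'term'")
  missing <- setdiff(unique(gene2term$term), names(parent_count))
  if (length(missing))
    stopf("terms without a parent_count entry: %s",
          paste(head(missing, 5), collapse = ", "))
  if (any(parent_count < 0)) stopf("parent counts must be >= 0")
  structure(list(gene2term = gene2term, parent_count = parent_count),
            class = "go_annotation")
}
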