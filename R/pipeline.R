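#' Pipeline configuration
#'
#' Assembles per-stage parameters for [run_pipeline()]. Defaults follow the
#' workflow's canonical values: QC cutoffs of 100,000 aligned reads and
#' 4,000 detected genes, Arc discordance threshold 2.5 log2(TPM+1), t-SNE
#' perplexity 17, DE with 500 bootstrap pairs and seed 1234 at adjusted
#' p < 0.05, predictive-gene expression fractions 0.8/0.4 at cutoff 1.0,
#' and reactivity forests with 15 training nuclei per class, 10,000 trees
#' and Gini pooling cutoff 0.4.
#'
#' @param sim a [sim_config()] describing the synthetic cohort (its seed is
#'   re-derived from `seed`).
#' @param seed global pipeline seed.
#' @param qc,cluster,de,signatures,reactivity,gonet named lists overriding
#'   individual stage parameters.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(), seed = 1,
                            qc = list(), cluster = list(), de = list(),
                            signatures = list(), reactivity = list(),
                            gonet = list()) {
  defaults <- list(
    qc = list(min_reads = 100000, min_genes = 4000, arc_threshold = 2.5),
    cluster = list(de_alpha = 0.05, min_de_genes = 10, min_leaf = 10,
                   perplexity = 17, split_B = 100, gini_cutoff = 1.0,
                   refine_trees = 1000, min_total_expression = 10),
    de = list(B = 500, alpha = 0.05, seed = 1234, n_perm = 1000),
    signatures = list(alpha = 0.05, threshold_policy = "two_means",
                      fixed_threshold = 10),
    reactivity = list(frac_up = 0.8, frac_down = 0.4, expr_cutoff = 1.0,
                      n_train_per_class = 15, n_trees = 10000,
                      gini_pool_cutoff = 0.4),
    gonet = list(n_terms = 200, max_parents = 10, edge_threshold = 0.25,
                 n_distance_genes = 40))
  merge_stage <- function(name, override) {
    base <- defaults[[name]]
    unknown <- setdiff(names(override), names(base))
    if (length(unknown))
      stopf("unknown %s parameter(s): %s", name,
            paste(unknown, collapse = ", "))
    base[names(override)] <- override
    base
  }
  cfg <- list(sim = sim, seed = check_count(seed, "seed"),
              qc = merge_stage("qc", qc),
              cluster = merge_stage("cluster", cluster),
              de = merge_stage("de", de),
              signatures = merge_stage("signatures", signatures),
              reactivity = merge_stage("reactivity", reactivity),
              gonet = merge_stage("gonet", gonet))
  check_fraction(cfg$reactivity$frac_up, "reactivity$frac_up")
  check_fraction(cfg$reactivity$frac_down, "reactivity$frac_down")
  check_fraction(cfg$gonet$edge_threshold, "gonet$edge_threshold")
  check_fraction(cfg$de$alpha, "de$alpha")
  check_fraction(cfg$signatures$alpha, "signatures$alpha")
  check_fraction(cfg$cluster$de_alpha, "cluster$de_alpha")
  if (!inherits(sim, "sim_config"))
    stopf("'sim' must come from sim_config()")
  class(cfg) <- "pipeline_config"
  cfg
}

#' Run the end-to-end synthetic workflow
#'
#' Executes simulate -> QC -> cell typing -> differential expression ->
#' temporal signatures -> reactivity prediction -> GO network, writing each
#' stage's tables to `out_dir` plus a `manifest.json` recording every
#' parameter. Identical config and seed reproduce every stage output
#' byte-for-byte (the manifest carries the only timestamp). A stage failure
#' halts the run with an error naming the stage; earlier outputs are kept.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if needed).
#' @param verbose print stage progress to stderr.
#' @return invisibly, a list with the in-memory stage results.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir, verbose = TRUE) {
  if (!inherits(config, "pipeline_config"))
    stopf("'config' must come from pipeline_config()")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (verbose) message(sprintf(...))
  stage <- function(name, expr) {
    say("[%s] running", name)
    t0 <- Sys.time()
    out <- tryCatch(expr, error = function(e)
      stopf("stage '%s' failed: %s", name, conditionMessage(e)))
    say("[%s] done in %.1fs", name, as.numeric(Sys.time() - t0, units = "secs"))
    out
  }
  tsv <- function(x, name) {
    write.table(x, file.path(out_dir, name), sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  res <- list()

  ## simulate ----
  sim <- stage("simulate", {
    cfg <- config$sim
    cfg$seed <- (config$seed * 1000003L) %% .Machine$integer.max
    simulate_experiment(cfg)
  })
  tsv(sim$metadata, "metadata.tsv")
  tsv(sim$truth$nucleus_truth, "nucleus_truth.tsv")
  tsv(sim$truth$gene_truth, "gene_truth.tsv")
  write_expression_matrix(sim$matrix, file.path(out_dir, "expression.tsv"))
  res$sim <- sim
  md <- sim$metadata

  ## qc ----
  qc <- stage("qc", {
    r1 <- qc_filter_nuclei(sim$matrix, md, config$qc$min_reads,
                           config$qc$min_genes)
    m1 <- sim$matrix[, r1$retained_ids, drop = FALSE]
    # the Arc-discordance rule targets nuclei whose FOS- stain should mean
    # inactive (home cage / 1 h); ARC+FOS- nuclei at later time points are
    # selected by Arc and must not be dropped
    early_md <- md[match(r1$retained_ids, md$nucleus_id), ]
    cand <- r1$retained_ids[early_md$condition %in% c("HC", "NE1h")]
    r2 <- exclude_arc_discordant(m1[, cand, drop = FALSE], md,
                                 config$qc$arc_threshold)
    drop <- setdiff(cand, r2$retained_ids)
    list(reads_genes = r1, arc = r2,
         matrix = m1[, setdiff(r1$retained_ids, drop), drop = FALSE])
  })
  tsv(data.frame(step = c("input", "reads_genes", "arc_rule"),
                 retained = c(qc$reads_genes$n_input,
                              qc$reads_genes$n_retained,
                              qc$arc$n_retained)), "qc_report.tsv")
  jsonlite::write_json(
    list(n_input = qc$reads_genes$n_input,
         n_fail_reads = qc$reads_genes$n_fail_reads,
         n_fail_genes = qc$reads_genes$n_fail_genes,
         n_fail_arc_rule = qc$arc$n_fail_arc_rule,
         n_retained = qc$arc$n_retained),
    file.path(out_dir, "qc_report.json"), auto_unbox = TRUE)
  X <- qc$matrix
  md <- md[match(colnames(X), md$nucleus_id), ]
  res$qc <- qc

  pick <- function(cond = NULL, fos = NULL, arc = NULL, pop = NULL) {
    sel <- rep(TRUE, nrow(md))
    if (!is.null(cond)) sel <- sel & md$condition %in% cond
    if (!is.null(fos)) sel <- sel & md$fos_protein %in% fos
    if (!is.null(arc)) sel <- sel & md$arc_protein %in% arc
    if (!is.null(pop)) sel <- sel & md$population %in% pop
    md$nucleus_id[sel]
  }

  ## cell typing on home-cage and 1 h nuclei ----
  ct <- stage("cluster", {
    ids <- pick(cond = c("HC", "NE1h"))
    sub <- X[, ids, drop = FALSE]
    tree <- iterative_cluster(
      sub, de_alpha = config$cluster$de_alpha,
      min_de_genes = config$cluster$min_de_genes,
      min_leaf = config$cluster$min_leaf,
      perplexity = config$cluster$perplexity,
      de_params = rots_params(B = config$cluster$split_B, n_perm = 200,
                              seed = config$de$seed),
      seed = config$seed)
    refined <- refine_clusters_rf(
      sub, tree, min_total_expression = config$cluster$min_total_expression,
      gini_cutoff = config$cluster$gini_cutoff,
      n_trees = config$cluster$refine_trees, seed = config$seed)
    list(tree = tree, refined = refined, ids = ids)
  })
  tsv(data.frame(nucleus_id = ct$ids,
                 cluster = unname(ct$tree$labels[ct$ids]),
                 refined = as.character(ct$refined$labels[ct$ids])),
      "cluster_labels.tsv")
  tsv(data.frame(cluster = names(ct$refined$precision),
                 precision = unname(ct$refined$precision)),
      "cluster_precision.tsv")
  res$cluster <- ct

  ## differential expression: time points vs home cage (DG) ----
  de_pars <- rots_params(B = config$de$B, n_perm = config$de$n_perm,
                         seed = config$de$seed)
  hc_ids <- pick(cond = "HC", fos = "neg", pop = "DG")
  de <- stage("de", {
    cmp <- list(
      de_1h = pick(cond = "NE1h", fos = "pos", pop = "DG"),
      de_4h = pick(cond = "NE4h", fos = "neg", arc = "pos", pop = "DG"),
      de_5h = pick(cond = "NE5h", fos = "neg", arc = "pos", pop = "DG"))
    lapply(cmp, function(ids)
      rots_test(X[, ids, drop = FALSE], X[, hc_ids, drop = FALSE], de_pars))
  })
  for (nm in names(de)) tsv(de[[nm]], paste0(nm, ".tsv"))
  res$de <- de

  ## temporal signatures and reactivation labels ----
  sg <- stage("signatures", {
    groups <- assign_temporal_groups(de$de_1h, de$de_4h, de$de_5h,
                                     alpha = config$signatures$alpha)
    dg_ids <- pick(pop = "DG")
    scores <- late_signature_score(X[, dg_ids, drop = FALSE],
                                   groups$signatures$late)
    states <- if (config$signatures$threshold_policy == "fixed") {
      classify_activity_state(scores, "fixed",
                              config$signatures$fixed_threshold)
    } else classify_activity_state(scores, "two_means")
    aa_pos <- pick(cond = "AA", fos = "pos", arc = "pos", pop = "DG")
    react <- label_reactivation(states[aa_pos])
    list(groups = groups, scores = scores, states = states, react = react)
  })
  tsv(sg$groups$assignment, "temporal_groups.tsv")
  tsv(data.frame(nucleus_id = names(sg$scores),
                 pc_score = unname(sg$scores),
                 state = unname(sg$states[names(sg$scores)])),
      "signature_scores.tsv")
  tsv(data.frame(nucleus_id = names(sg$react),
                 label = unname(sg$react)), "reactivation_labels.tsv")
  res$signatures <- sg

  ## reactivity prediction ----
  rx <- stage("reactivity", {
    nr_ids <- pick(cond = "AA", fos = "neg", arc = "pos", pop = "DG")
    r_ids <- names(sg$react)[sg$react == "Reactivated"]
    na_ids <- names(sg$react)[sg$react == "NewlyActivated"]
    de_r_nr <- rots_test(X[, r_ids, drop = FALSE],
                         X[, nr_ids, drop = FALSE], de_pars)
    batch_genes <- batch_associated_genes(
      X, md$batch_id[match(colnames(X), md$nucleus_id)])
    genes <- select_predictive_genes(
      de_r_nr, X, r_ids, de_1h_vs_HC = de$de_1h,
      batch_assoc_genes = batch_genes,
      frac_up = config$reactivity$frac_up,
      frac_down = config$reactivity$frac_down,
      expr_cutoff = config$reactivity$expr_cutoff,
      alpha = config$de$alpha)
    aa_ids <- c(r_ids, na_ids, nr_ids)
    labels <- setNames(c(rep("Reactivated", length(r_ids)),
                         rep("NewlyActivated", length(na_ids)),
                         rep("NotReactivated", length(nr_ids))), aa_ids)
    model <- train_reactivity_models(
      X[, aa_ids, drop = FALSE], labels[aa_ids], genes,
      n_train_per_class = config$reactivity$n_train_per_class,
      n_trees = config$reactivity$n_trees,
      gini_pool_cutoff = config$reactivity$gini_pool_cutoff,
      seed = config$seed)
    roc_i <- evaluate_roc(model, X[, aa_ids, drop = FALSE], labels[aa_ids],
                          "i")
    roc_ii <- evaluate_roc(model, X[, aa_ids, drop = FALSE], labels[aa_ids],
                           "ii")
    late_ids <- pick(cond = c("NE4h", "NE5h"), pop = "DG")
    primed <- predict_primed(model, X[, late_ids, drop = FALSE])
    fos_pos <- c(r_ids, na_ids)
    probs <- setNames(
      predict_primed(model, X[, fos_pos, drop = FALSE])$prob_reactivated,
      fos_pos)
    comp <- reactivity_component(X[, aa_ids, drop = FALSE], r_ids, na_ids,
                                 probs = probs)
    list(de_r_nr = de_r_nr, genes = genes, model = model,
         roc_i = roc_i, roc_ii = roc_ii, primed = primed, component = comp)
  })
  tsv(rx$genes, "predictive_genes.tsv")
  tsv(rx$model$pooled_genes, "pooled_genes.tsv")
  tsv(data.frame(class = names(rx$model$holdout_error),
                 error = unname(rx$model$holdout_error)),
      "holdout_error.tsv")
  tsv(cbind(model = "i", rx$roc_i$points), "roc_model_i.tsv")
  tsv(cbind(model = "ii", rx$roc_ii$points), "roc_model_ii.tsv")
  tsv(rx$primed, "primed_predictions.tsv")
  res$reactivity <- rx

  ## GO enrichment and network ----
  gn <- stage("gonet", {
    ann <- simulate_go_annotation(nrow(X), config$gonet$n_terms,
                                  config$gonet$max_parents,
                                  seed = config$seed, genes = rownames(X))
    enr <- enrichment_test(sg$groups$signatures$late, ann, rownames(X))
    # genes annotated only to zero-parent (root) terms carry no weighted
    # annotation information; they cannot enter the cosine distance
    informative <- tapply(ann$parent_count[ann$gene2term$term] > 0,
                          ann$gene2term$gene, any)
    dist_genes <- head(intersect(rx$genes$gene,
                                 names(informative)[informative]),
                       config$gonet$n_distance_genes)
    D <- go_gene_distance(dist_genes, ann)
    edges <- export_network(D, config$gonet$edge_threshold,
                            file.path(out_dir, "network.sif"))
    list(annotation = ann, enrichment = enr, distances = D, edges = edges)
  })
  tsv(gn$enrichment, "enrichment.tsv")
  res$gonet <- gn

  jsonlite::write_json(
    list(package = "engramsig",
         version = as.character(utils::packageVersion("engramsig")),
         timestamp = format(Sys.time(), tz = "UTC"),
         seed = config$seed,
         parameters = unclass(config)[setdiff(names(config), "sim")],
         sim = unclass(config$sim)),
    file.path(out_dir, "manifest.json"), auto_unbox = TRUE, digits = NA,
    force = TRUE)
  say("pipeline complete: %s", out_dir)
  invisible(res)
}
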