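#' Genes associated with batch
#'
#' Kruskal-Wallis test of each gene's expression across batches, BH
#' adjusted; genes below `alpha` are flagged as batch-associated and are
#' excluded from predictive-gene selection.
#'
#' @param matrix genes x nuclei expression matrix.
#' @param batch character/factor vector aligned with matrix columns.
#' @param alpha FDR cutoff (default 0.05).
#' @return character vector of batch-associated gene identifiers.
#' @export
batch_associated_genes <- function(matrix, batch, alpha = 0.05) {
  check_matrix(matrix)
  if (length(batch) != ncol(matrix))
    stopf("'batch' must align with matrix columns")
  batch <- factor(batch)
  if (nlevels(batch) < 2) return(character(0))
  p <- apply(matrix, 1, function(x) {
    if (var(x) == 0) return(1)
    kruskal.test(x, batch)$p.value
  })
  rownames(matrix)[p.adjust(p, "BH") < alpha]
}

#' Select reactivity-predictive genes
#'
#' Starts from genes differentially expressed between Reactivated and Not
#' Reactivated nuclei and keeps upregulated genes expressed (above
#' `expr_cutoff` log2(TPM+1)) in at least `frac_up` of Reactivated nuclei
#' and downregulated genes expressed in at most `frac_down`. Genes
#' differentially expressed at 1 h versus home cage (immediate early genes)
#' or associated with batch are excluded, leaving genes whose signal is
#' already present hours after the first exposure.
#'
#' @param de_R_vs_NR DE table from `rots_test(reactivated, not_reactivated)`
#'   (so `direction == "up"` means higher in Reactivated).
#' @param matrix genes x nuclei expression matrix covering the DE genes.
#' @param reactivated_ids nucleus ids of the Reactivated class.
#' @param de_1h_vs_HC optional DE table for the 1 h FOS+ vs HC comparison;
#'   its significant genes are excluded.
#' @param batch_assoc_genes optional character vector of genes to exclude
#'   (see [batch_associated_genes()]).
#' @param frac_up,frac_down expression-fraction filters (defaults 0.8 and
#'   0.4).
#' @param expr_cutoff expression cutoff in log2(TPM+1) (default 1).
#' @param alpha adjusted-p cutoff defining significance (default 0.05).
#' @return data.frame of class `predictive_gene_set` with columns `gene`,
#'   `direction`, `reactivated_expression_fraction`.
#' @export
select_predictive_genes <- function(de_R_vs_NR, matrix, reactivated_ids,
                                    de_1h_vs_HC = NULL,
                                    batch_assoc_genes = NULL,
                                    frac_up = 0.8, frac_down = 0.4,
                                    expr_cutoff = 1.0, alpha = 0.05) {
  check_matrix(matrix)
  if (!length(reactivated_ids)) stopf("'reactivated_ids' must be non-empty")
  if (length(miss <- setdiff(reactivated_ids, colnames(matrix))))
    stopf("reactivated nuclei absent from matrix: %s",
          paste(head(miss, 5), collapse = ", "))
  sig <- de_R_vs_NR[de_R_vs_NR$p_adj < alpha, , drop = FALSE]
  if (length(miss <- setdiff(sig$gene, rownames(matrix))))
    stopf("DE genes absent from matrix: %s",
          paste(head(miss, 5), collapse = ", "))
  drop <- character(0)
  if (!is.null(de_1h_vs_HC))
    drop <- union(drop, de_1h_vs_HC$gene[de_1h_vs_HC$p_adj < alpha])
  if (!is.null(batch_assoc_genes)) drop <- union(drop, batch_assoc_genes)
  sig <- sig[!sig$gene %in% drop, , drop = FALSE]
  frac <- rowMeans(matrix[sig$gene, reactivated_ids, drop = FALSE] >
                     expr_cutoff)
  keep <- ifelse(sig$direction == "up", frac >= frac_up, frac <= frac_down)
  out <- data.frame(gene = sig$gene[keep],
                    direction = sig$direction[keep],
                    reactivated_expression_fraction = unname(frac[keep]),
                    stringsAsFactors = FALSE)
  if (!nrow(out)) stopf("no predictive genes survive filters")
  out <- out[order(out$gene), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("predictive_gene_set", "data.frame")
  out
}

#' Train reactivity random-forest models
#'
#' Trains pairwise forests i (Reactivated vs Newly Activated) and ii
#' (Reactivated vs Not Reactivated) on `n_train_per_class` nuclei per
#' class, pools the genes exceeding `gini_pool_cutoff` Mean Decrease Gini
#' in either pairwise model, trains a three-way forest on the pooled set,
#' and reports the per-class hold-out classification error.
#'
#' @param matrix genes x nuclei expression matrix.
#' @param labels factor/character aligned with matrix columns with values
#'   `NewlyActivated`, `NotReactivated`, `Reactivated`.
#' @param genes a `predictive_gene_set` (or character vector of genes).
#' @param n_train_per_class training nuclei per class (default 15).
#' @param n_trees trees per forest (default 10000).
#' @param gini_pool_cutoff importance cutoff for pooling (default 0.4).
#' @param elim_cutoff optional initial feature-elimination cutoff: a single
#'   three-way forest on the training nuclei drops genes at or below this
#'   Mean Decrease Gini before the pairwise fits (NULL disables, the
#'   default).
#' @param seed RNG seed (controls the train/test split and forests).
#' @return object of class `reactivity_model` with elements `model_i`,
#'   `model_ii`, `model_3way`, `pooled_genes`, `train_ids`, `test_ids`,
#'   `holdout_error` (per class) and `classes`.
#' @export
train_reactivity_models <- function(matrix, labels, genes,
                                    n_train_per_class = 15, n_trees = 10000,
                                    gini_pool_cutoff = 0.4,
                                    elim_cutoff = NULL, seed = 1) {
  check_matrix(matrix)
  if (length(labels) != ncol(matrix))
    stopf("'labels' must align with matrix columns")
  classes <- c("NewlyActivated", "NotReactivated", "Reactivated")
  labels <- factor(as.character(labels), levels = classes)
  if (anyNA(labels))
    stopf("labels must be one of: %s", paste(classes, collapse = ", "))
  tab <- table(labels)
  small <- names(tab)[tab < n_train_per_class + 1]
  if (length(small))
    stopf("class(es) too small for %d training + >=1 test nuclei: %s",
          n_train_per_class, paste(small, collapse = ", "))
  gene_set <- if (is.data.frame(genes)) genes$gene else genes
  if (length(miss <- setdiff(gene_set, rownames(matrix))))
    stopf("genes absent from matrix: %s", paste(head(miss, 5), collapse = ", "))
  ids <- colnames(matrix)

  with_seed(seed, {
    train_ids <- unlist(lapply(classes, function(cl)
      sample(ids[labels == cl], n_train_per_class)))
    test_ids <- setdiff(ids, train_ids)
    y <- setNames(labels, ids)

    fit <- function(use_ids, use_genes) {
      yl <- droplevels(y[use_ids])
      randomForest::randomForest(t(matrix[use_genes, use_ids, drop = FALSE]),
                                 yl, ntree = n_trees)
    }
    gini_of <- function(rf) {
      imp <- randomForest::importance(rf)
      setNames(as.numeric(imp[, "MeanDecreaseGini"]), rownames(imp))
    }

    if (!is.null(elim_cutoff)) {
      g0 <- gini_of(fit(train_ids, gene_set))
      gene_set <- names(g0)[g0 > elim_cutoff]
      if (!length(gene_set))
        stopf("no genes survive initial feature elimination at cutoff %s",
              format(elim_cutoff))
    }

    tr_i <- train_ids[y[train_ids] %in% c("Reactivated", "NewlyActivated")]
    tr_ii <- train_ids[y[train_ids] %in% c("Reactivated", "NotReactivated")]
    model_i <- fit(tr_i, gene_set)
    model_ii <- fit(tr_ii, gene_set)
    gi <- gini_of(model_i)
    gii <- gini_of(model_ii)
    pooled <- union(names(gi)[gi > gini_pool_cutoff],
                    names(gii)[gii > gini_pool_cutoff])
    if (!length(pooled))
      stopf("pooled set empty at gini_pool_cutoff = %s",
            format(gini_pool_cutoff))
    model_3 <- fit(train_ids, pooled)

    pred <- predict(model_3, t(matrix[pooled, test_ids, drop = FALSE]))
    holdout <- sapply(classes, function(cl) {
      idx <- test_ids[y[test_ids] == cl]
      mean(pred[idx] != cl)
    })
    structure(list(model_i = model_i, model_ii = model_ii,
                   model_3way = model_3,
                   pooled_genes = data.frame(
                     gene = pooled,
                     gini_i = as.numeric(gi[pooled]),
                     gini_ii = as.numeric(gii[pooled]), row.names = NULL),
                   features = gene_set,
                   train_ids = train_ids, test_ids = test_ids,
                   holdout_error = holdout, classes = classes,
                   n_trees = n_trees, seed = seed),
              class = "reactivity_model")
  })
}

#' @export
print.reactivity_model <- function(x, ...) {
  cat(sprintf(paste0("reactivity_model: %d feature genes, %d pooled for the ",
                     "three-way forest (%d trees)\n"),
              length(x$features), nrow(x$pooled_genes), x$n_trees))
  cat("hold-out classification error per class:\n")
  print(round(x$holdout_error, 3))
  invisible(x)
}

# probability of the Reactivated class from one of the fitted forests
.react_prob <- function(rf, matrix, ids) {
  genes <- rownames(rf$importance)
  if (length(miss <- setdiff(genes, rownames(matrix))))
    stopf("model genes absent from matrix: %s",
          paste(head(miss, 5), collapse = ", "))
  pr <- predict(rf, t(matrix[genes, ids, drop = FALSE]), type = "prob")
  pr[, "Reactivated"]
}

#' ROC curve and AUC for a score against binary labels
#'
#' Sweeps all score thresholds, reporting (false-positive rate,
#' true-positive rate) points monotone in both coordinates and the
#' trapezoidal area under the curve.
#'
#' @param scores numeric vector (higher = more positive).
#' @param labels logical or factor-like vector; `positive` names the
#'   positive class.
#' @param positive positive-class value (default `TRUE`).
#' @return object of class `roc_result`: `points` (data.frame fpr, tpr),
#'   `auc`.
#' @export
roc_curve <- function(scores, labels, positive = TRUE) {
  pos <- labels == positive
  if (!any(pos) || all(pos))
    stopf("ROC needs both classes present in the labels")
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  pts <- t(sapply(thr, function(t) {
    call_pos <- scores >= t
    c(fpr = sum(call_pos & !pos) / sum(!pos),
      tpr = sum(call_pos & pos) / sum(pos))
  }))
  pts <- as.data.frame(pts)
  auc <- sum(diff(pts$fpr) * (head(pts$tpr, -1) + pts$tpr[-1]) / 2)
  structure(list(points = pts, auc = auc), class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("ROC with %d points, AUC = %.3f\n", nrow(x$points), x$auc))
  invisible(x)
}

#' Evaluate a reactivity model by ROC on held-out nuclei
#'
#' @param model a `reactivity_model`.
#' @param matrix genes x nuclei expression matrix.
#' @param labels class labels aligned with matrix columns.
#' @param which `"i"` (Reactivated vs Newly Activated) or `"ii"`
#'   (Reactivated vs Not Reactivated).
#' @param ids nuclei to evaluate; defaults to the model's held-out test set
#'   restricted to the two classes of the chosen model.
#' @return `roc_result` (see [roc_curve()]).
#' @export
evaluate_roc <- function(model, matrix, labels, which = c("i", "ii"),
                         ids = NULL) {
  which <- match.arg(which)
  if (!inherits(model, "reactivity_model"))
    stopf("'model' must be a reactivity_model")
  labels <- setNames(as.character(labels), colnames(matrix))
  other <- if (which == "i") "NewlyActivated" else "NotReactivated"
  rf <- if (which == "i") model$model_i else model$model_ii
  if (is.null(ids))
    ids <- model$test_ids[labels[model$test_ids] %in%
                            c("Reactivated", other)]
  if (!length(ids)) stopf("no evaluation nuclei available")
  probs <- .react_prob(rf, matrix, ids)
  roc_curve(probs, labels[ids], positive = "Reactivated")
}

#' Predict the primed (pre-reactivation) state of single-exposure nuclei
#'
#' Applies the trained three-way forest to 4/5-h single-exposure nuclei and
#' labels each as predicted Reactivated (`pR`) when the Reactivated class
#' has the highest probability, else predicted Not Reactivated (`pNR`).
#'
#' @param model a `reactivity_model`.
#' @param matrix genes x nuclei matrix of the nuclei to score (must contain
#'   the model's pooled genes).
#' @return data.frame of class `reactivity_prediction` with columns
#'   `nucleus_id`, `prob_reactivated`, `label`, plus one probability column
#'   per class.
#' @export
predict_primed <- function(model, matrix) {
  if (!inherits(model, "reactivity_model"))
    stopf("'model' must be a reactivity_model")
  check_matrix(matrix)
  genes <- rownames(model$model_3way$importance)
  if (length(miss <- setdiff(genes, rownames(matrix))))
    stopf("model genes absent from matrix: %s",
          paste(head(miss, 5), collapse = ", "))
  pr <- predict(model$model_3way, t(matrix[genes, , drop = FALSE]),
                type = "prob")
  top <- colnames(pr)[max.col(pr, ties.method = "first")]
  out <- data.frame(nucleus_id = colnames(matrix),
                    prob_reactivated = pr[, "Reactivated"],
                    label = ifelse(top == "Reactivated", "pR", "pNR"),
                    stringsAsFactors = FALSE, row.names = NULL)
  out <- cbind(out, as.data.frame(pr, row.names = FALSE))
  class(out) <- c("reactivity_prediction", "data.frame")
  out
}

#' Serialize / restore a reactivity model
#'
#' Writes a JSON description (feature genes, pooled genes with importances,
#' training/test split, forest parameters, seed) next to an opaque binary
#' blob holding the fitted forests (`<path>.rds`). The JSON is the
#' human-readable record; the blob is what [read_reactivity_model()]
#' restores.
#'
#' @param model a `reactivity_model`.
#' @param path output path for the JSON description.
#' @return invisibly, `path`.
#' @export
write_reactivity_model <- function(model, path) {
  if (!inherits(model, "reactivity_model"))
    stopf("'model' must be a reactivity_model")
  jsonlite::write_json(
    list(classes = model$classes, n_trees = model$n_trees,
         seed = model$seed, features = model$features,
         pooled_genes = model$pooled_genes,
         train_ids = model$train_ids, test_ids = model$test_ids,
         holdout_error = as.list(model$holdout_error)),
    path, auto_unbox = TRUE, digits = NA)
  saveRDS(model, paste0(path, ".rds"))
  invisible(path)
}

#' @rdname write_reactivity_model
#' @export
read_reactivity_model <- function(path) {
  blob <- paste0(path, ".rds")
  if (!file.exists(blob)) stopf("model blob not found: %s", blob)
  model <- readRDS(blob)
  if (!inherits(model, "reactivity_model"))
    stopf("%s does not hold a reactivity_model", blob)
  model
}

#' Reactivity component: the principal component separating two subgroups
#'
#' Among the leading principal components of the full transcriptome, selects
#' the one maximizing the two-sample t-statistic between the two named
#' subgroups (e.g. FOS+ nuclei split by early/late signature, or
#' late-signature nuclei split by FOS status), oriented so the first group
#' scores higher. The score serves as a continuous ground truth for
#' reactivity and is optionally correlated (Pearson) with model-predicted
#' probabilities.
#'
#' @param matrix genes x nuclei expression matrix.
#' @param group_a_ids,group_b_ids nucleus ids of the two subgroups (at
#'   least 2 each); group A is the reactivated-like group.
#' @param n_components leading components searched (default 10).
#' @param probs optional named vector of predicted reactivation
#'   probabilities to correlate against.
#' @return object of class `reactivity_component`: `scores` (named, all
#'   nuclei), `component` (index), `t`, `t_p`, `correlation` (list r/p or
#'   NULL), `degenerate` flag.
#' @export
reactivity_component <- function(matrix, group_a_ids, group_b_ids,
                                 n_components = 10, probs = NULL) {
  check_matrix(matrix)
  if (length(group_a_ids) < 2 || length(group_b_ids) < 2)
    stopf("each subgroup needs at least 2 nuclei")
  ids <- colnames(matrix)
  if (length(miss <- setdiff(c(group_a_ids, group_b_ids), ids)))
    stopf("subgroup nuclei absent from matrix: %s",
          paste(head(miss, 5), collapse = ", "))
  n_components <- min(n_components, ncol(matrix) - 1, nrow(matrix))
  pc <- prcomp(t(matrix), center = TRUE, scale. = FALSE,
               rank. = n_components)
  degenerate <- FALSE
  tstats <- sapply(seq_len(ncol(pc$x)), function(j) {
    a <- pc$x[group_a_ids, j]; b <- pc$x[group_b_ids, j]
    if (var(a) + var(b) == 0) return(0)
    unname(t.test(a, b)$statistic)
  })
  if (all(tstats == 0)) degenerate <- TRUE
  best <- which.max(abs(tstats))
  score <- pc$x[, best]
  if (!degenerate && tstats[best] < 0) score <- -score
  t_p <- if (degenerate) NA_real_ else
    t.test(score[group_a_ids], score[group_b_ids])$p.value
  correlation <- NULL
  if (!is.null(probs)) {
    common <- intersect(names(probs), ids)
    if (length(common) < 3)
      stopf("need at least 3 shared nuclei to correlate with probabilities")
    ct <- cor.test(score[common], probs[common])
    correlation <- list(r = unname(ct$estimate), p = ct$p.value,
                        n = length(common))
  }
  structure(list(scores = score, component = best,
                 t = abs(tstats[best]), t_p = t_p,
                 correlation = correlation, degenerate = degenerate),
            class = "reactivity_component")
}

#' @export
print.reactivity_component <- function(x, ...) {
  cat(sprintf("reactivity component: PC%d, |t| = %.2f (p = %.3g)%s\n",
              x$component, x$t, x$t_p,
              if (x$degenerate) " [degenerate]" else ""))
  if (!is.null(x$correlation))
    cat(sprintf("Pearson r vs predicted probability: %.3f (p = %.3g, n = %d)\n",
                x$correlation$r, x$correlation$p, x$correlation$n))
  invisible(x)
}
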