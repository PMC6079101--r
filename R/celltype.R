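#' Two-dimensional t-SNE embedding of nuclei
#'
#' @param matrix genes x nuclei expression matrix.
#' @param initial_dims PCA dimensions fed to t-SNE (default 20).
#' @param perplexity t-SNE perplexity (default 17); requires
#'   `n_nuclei > 3 * perplexity`.
#' @param theta Barnes-Hut accuracy parameter; 0 gives the exact algorithm.
#' @param seed RNG seed.
#' @return n_nuclei x 2 matrix of coordinates, rownames = nucleus ids.
#' @export
embed_2d <- function(matrix, initial_dims = 20, perplexity = 17, theta = 0,
                     seed = 1) {
  check_matrix(matrix)
  n <- ncol(matrix)
  if (n <= 3 * perplexity)
    stopf(paste0("t-SNE needs n_nuclei > 3 * perplexity; have %d nuclei ",
                 "for perplexity %s - reduce perplexity to at most %d"),
          n, format(perplexity), floor((n - 2) / 3))
  emb <- with_seed(seed,
    Rtsne::Rtsne(t(matrix), dims = 2,
                 initial_dims = min(initial_dims, n - 1, nrow(matrix)),
                 perplexity = perplexity, theta = theta,
                 check_duplicates = FALSE, pca = TRUE, verbose = FALSE))
  coords <- emb$Y
  rownames(coords) <- colnames(matrix)
  colnames(coords) <- c("tsne1", "tsne2")
  coords
}

#' Hierarchical iterative clustering of nuclei
#'
#' Recursively (1) embeds the current nucleus set in two dimensions by
#' t-SNE, (2) bisects the embedding by hierarchical clustering (Euclidean
#' distance, complete linkage), (3) tests the bisection by differential
#' expression, and (4) recurses into each branch. A branch becomes a leaf
#' when the proposed split yields fewer than `min_de_genes` genes at
#' `de_alpha` (it can no longer support significant differential
#' expression), or when a child would fall below `min_leaf` nuclei.
#'
#' @param matrix QC-filtered genes x nuclei expression matrix.
#' @param de_alpha adjusted-p cutoff for split-supporting genes.
#' @param min_de_genes minimum significant genes for a split to stand.
#' @param min_leaf minimum nuclei per cluster.
#' @param perplexity t-SNE perplexity, automatically reduced on small
#'   branches.
#' @param de_params [rots_params()] used for the split tests; the default
#'   uses a reduced bootstrap count since only the significant-gene count is
#'   needed.
#' @param seed RNG seed (each node derives its own sub-seed).
#' @return object of class `cluster_tree`: `labels` (named integer vector
#'   over nuclei), `tree` (nested node list recording members and split
#'   statistics) and `n_leaves`.
#' @export
iterative_cluster <- function(matrix, de_alpha = 0.05, min_de_genes = 10,
                              min_leaf = 10, perplexity = 17,
                              de_params = rots_params(B = 100, n_perm = 200),
                              seed = 1) {
  check_matrix(matrix)
  if (ncol(matrix) == 0) stopf("empty matrix")
  env <- new.env()
  env$leaf_id <- 0L
  env$node_id <- 0L
  env$labels <- setNames(integer(ncol(matrix)), colnames(matrix))

  grow <- function(ids, depth) {
    env$node_id <- env$node_id + 1L
    node_seed <- (seed + 7919L * env$node_id) %% .Machine$integer.max
    n <- length(ids)
    make_leaf <- function(reason) {
      env$leaf_id <- env$leaf_id + 1L
      env$labels[ids] <- env$leaf_id
      list(leaf = TRUE, label = env$leaf_id, members = ids, n = n,
           reason = reason)
    }
    if (n < 2 * min_leaf) return(make_leaf("too few nuclei to split"))
    perp <- min(perplexity, floor((n - 2) / 3))
    if (perp < 2) return(make_leaf("too few nuclei for embedding"))
    emb <- embed_2d(matrix[, ids, drop = FALSE], perplexity = perp,
                    seed = node_seed)
    hc <- hclust(dist(emb), method = "complete")
    cl <- cutree(hc, k = 2)
    if (min(table(cl)) < min_leaf)
      return(make_leaf("split child below min_leaf"))
    de <- rots_test(matrix[, ids[cl == 1], drop = FALSE],
                    matrix[, ids[cl == 2], drop = FALSE], de_params)
    n_sig <- sum(de$p_adj < de_alpha)
    if (n_sig < min_de_genes)
      return(make_leaf("split not supported by differential expression"))
    top <- de[order(de$p_adj, -de$d), ]
    list(leaf = FALSE, members = ids, n = n, n_de_genes = n_sig,
         split_genes = head(top[, c("gene", "d", "p_adj", "direction")], 20),
         children = list(grow(ids[cl == 1], depth + 1),
                         grow(ids[cl == 2], depth + 1)))
  }
  tree <- grow(colnames(matrix), 0L)
  structure(list(labels = env$labels, tree = tree,
                 n_leaves = env$leaf_id),
            class = "cluster_tree")
}

#' @export
print.cluster_tree <- function(x, ...) {
  cat(sprintf("cluster_tree: %d nuclei in %d leaves\n",
              length(x$labels), x$n_leaves))
  print(table(cluster = x$labels))
  invisible(x)
}

#' Random-forest refinement of cluster labels
#'
#' Two successive random-forest fits each retain genes whose Mean Decrease
#' Gini importance exceeds `gini_cutoff`; the final retained gene set trains
#' a forest whose out-of-bag predictions re-assign each nucleus's label.
#' Per-cluster precision is the out-of-bag proportion of nuclei whose
#' prediction recovers their cluster.
#'
#' @param matrix genes x nuclei expression matrix, log2(TPM+1).
#' @param clusters a `cluster_tree` or a labelling vector aligned with the
#'   matrix columns (at least 2 clusters, each with at least 2 nuclei).
#' @param min_total_expression gene filter: minimum TPM summed over all
#'   nuclei (default 10).
#' @param gini_cutoff importance cutoff for gene retention (default 1).
#' @param n_trees trees per forest (default 1000).
#' @param seed RNG seed.
#' @return object of class `cluster_refinement`: `labels` (out-of-bag
#'   refined labels), `precision` (per-cluster), `predictive_genes`
#'   (data.frame gene, gini) and `forest` (the final fit).
#' @export
refine_clusters_rf <- function(matrix, clusters, min_total_expression = 10,
                               gini_cutoff = 1.0, n_trees = 1000, seed = 1) {
  check_matrix(matrix)
  labels <- if (inherits(clusters, "cluster_tree")) clusters$labels else clusters
  if (length(labels) != ncol(matrix))
    stopf("cluster labels must align with matrix columns")
  labels <- setNames(factor(labels), colnames(matrix))
  tab <- table(labels)
  if (length(tab) < 2) stopf("refinement needs at least 2 clusters")
  if (any(tab < 2))
    stopf("cluster(s) with a single nucleus: %s",
          paste(names(tab)[tab < 2], collapse = ", "))
  tpm_sum <- rowSums(2^matrix - 1)
  keep <- rownames(matrix)[tpm_sum >= min_total_expression]
  if (length(keep) < 2)
    stopf("fewer than 2 genes pass the summed-TPM filter")

  with_seed(seed, {
    fit <- function(genes) {
      randomForest::randomForest(t(matrix[genes, , drop = FALSE]),
                                 labels, ntree = n_trees)
    }
    gini <- function(rf) {
      imp <- randomForest::importance(rf)[, "MeanDecreaseGini"]
      setNames(as.numeric(imp), rownames(randomForest::importance(rf)))
    }
    g1 <- gini(fit(keep))
    keep1 <- names(g1)[g1 > gini_cutoff]
    if (!length(keep1)) stopf("no genes retained at gini_cutoff = %s",
                              format(gini_cutoff))
    g2 <- gini(fit(keep1))
    keep2 <- names(g2)[g2 > gini_cutoff]
    if (!length(keep2)) stopf("no genes retained at gini_cutoff = %s",
                              format(gini_cutoff))
    rf <- fit(keep2)
    oob <- rf$predicted
    precision <- sapply(levels(labels), function(l)
      mean(oob[labels == l] == l))
    structure(list(labels = setNames(oob, colnames(matrix)),
                   precision = precision,
                   predictive_genes = data.frame(
                     gene = keep2, gini = as.numeric(g2[keep2]),
                     row.names = NULL),
                   forest = rf),
              class = "cluster_refinement")
  })
}

#' @export
print.cluster_refinement <- function(x, ...) {
  cat(sprintf("cluster_refinement: %d predictive genes\n",
              nrow(x$predictive_genes)))
  cat("per-cluster out-of-bag precision:\n")
  print(round(x$precision, 3))
  invisible(x)
}
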