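#' Assign genes to temporal response groups
#'
#' Genes are grouped by their pattern of significance (adjusted p below
#' `alpha`) across three comparisons against the home-cage baseline: 1 h
#' FOS+, 4 h ARC+FOS- and 5 h ARC+FOS-. The seven non-empty patterns map to
#' groups: 1 = 1 h only (early), 2 = 5 h only, 3 = 4 h only, 4 = 4 h and
#' 5 h (late), 5 = 1 h, 4 h and 5 h (sustained), 6 = 1 h and 5 h,
#' 7 = 1 h and 4 h; genes significant nowhere map to `"none"`.
#'
#' @param de_1h,de_4h,de_5h DE result data.frames (columns `gene`, `p_adj`)
#'   over an identical gene universe.
#' @param alpha significance cutoff on adjusted p (default 0.05).
#' @return object of class `temporal_groups`: data.frame `assignment`
#'   (gene, group) and convenience gene-set list `signatures` with
#'   `early`, `sustained`, `late`.
#' @export
assign_temporal_groups <- function(de_1h, de_4h, de_5h, alpha = 0.05) {
  tabs <- list(`1h` = de_1h, `4h` = de_4h, `5h` = de_5h)
  for (nm in names(tabs)) {
    if (!all(c("gene", "p_adj") %in% names(tabs[[nm]])))
      stopf("DE table '%s' needs columns 'gene' and 'p_adj'", nm)
  }
  genes <- de_1h$gene
  for (nm in c("4h", "5h")) {
    miss <- union(setdiff(genes, tabs[[nm]]$gene),
                  setdiff(tabs[[nm]]$gene, genes))
    if (length(miss))
      stopf("DE tables disagree on the gene universe; e.g. %s",
            paste(head(miss, 5), collapse = ", "))
  }
  sig <- sapply(tabs, function(t) t$p_adj[match(genes, t$gene)] < alpha)
  # pattern code: bit order (1h, 4h, 5h)
  code <- sig[, "1h"] * 4 + sig[, "4h"] * 2 + sig[, "5h"]
  map <- c(`0` = "none", `4` = "1", `1` = "2", `2` = "3", `3` = "4",
           `7` = "5", `5` = "6", `6` = "7")
  group <- unname(map[as.character(code)])
  assignment <- data.frame(gene = genes, group = group,
                           stringsAsFactors = FALSE)
  structure(list(assignment = assignment,
                 signatures = list(
                   early = genes[group == "1"],
                   sustained = genes[group == "5"],
                   late = genes[group == "4"]),
                 alpha = alpha),
            class = "temporal_groups")
}

#' @export
print.temporal_groups <- function(x, ...) {
  cat("Temporal gene groups (alpha =", x$alpha, "):\n")
  print(table(group = factor(x$assignment$group,
                             levels = c(as.character(1:7), "none"))))
  invisible(x)
}

#' Late-signature principal-component score
#'
#' Projects every nucleus on the first principal component of the
#' late-signature genes (centered, unscaled log2(TPM+1)). The component
#' sign is oriented so that nuclei with the highest summed late-gene
#' expression score positive.
#'
#' @param matrix genes x nuclei expression matrix.
#' @param late_genes late-signature gene identifiers; at least 2 must be
#'   present in the matrix with non-zero variance.
#' @return named numeric vector of per-nucleus PC1 scores; proportion of
#'   late-gene variance explained in attribute `var_explained`.
#' @export
late_signature_score <- function(matrix, late_genes) {
  check_matrix(matrix)
  present <- intersect(late_genes, rownames(matrix))
  if (length(present) < 2)
    stopf("need at least 2 late-signature genes in the matrix, found %d",
          length(present))
  sub <- t(matrix[present, , drop = FALSE])
  v <- apply(sub, 2, var)
  if (all(v == 0))
    stopf("all late-signature genes have zero variance; score undefined")
  pc <- prcomp(sub, center = TRUE, scale. = FALSE)
  score <- pc$x[, 1]
  tot <- colSums(matrix[present, , drop = FALSE])
  if (cor(score, tot) < 0) score <- -score
  attr(score, "var_explained") <- pc$sdev[1]^2 / sum(pc$sdev^2)
  score
}

#' Classify nuclei as early or late from signature scores
#'
#' Two policies: `"fixed"` thresholds the score at `threshold` (boundary
#' values assigned late); `"two_means"` splits the scores by 1-D 2-means
#' and labels the higher-center group late. When the two-means centers are
#' closer than the pooled within-cluster SD the result is flagged as
#' unimodal via the `"warning"` attribute.
#'
#' @param scores named numeric vector (e.g. from
#'   [late_signature_score()]).
#' @param policy `"two_means"` (default) or `"fixed"`.
#' @param threshold score cutoff used by the fixed policy (default 10).
#' @return named character vector with values `"early"`/`"late"`; possible
#'   attribute `"warning"`.
#' @export
classify_activity_state <- function(scores, policy = c("two_means", "fixed"),
                                    threshold = 10) {
  policy <- match.arg(policy)
  warn <- NULL
  if (policy == "fixed") {
    lab <- ifelse(scores >= threshold, "late", "early")
  } else {
    if (var(scores) == 0) {
      lab <- rep("early", length(scores))
      warn <- "all scores identical; two-means split undefined"
    } else {
      km <- kmeans(scores, centers = 2, nstart = 10)
      hi <- which.max(km$centers)
      lab <- ifelse(km$cluster == hi, "late", "early")
      pooled_sd <- sqrt(km$tot.withinss / (length(scores) - 2))
      if (abs(diff(km$centers)) < pooled_sd)
        warn <- "score distribution looks unimodal; two-means split is weakly supported"
    }
  }
  lab <- setNames(lab, names(scores))
  if (!is.null(warn)) attr(lab, "warning") <- warn
  lab
}

#' Label double-exposure ARC+FOS+ nuclei by reactivation status
#'
#' ARC+FOS+ nuclei from a double exposure carrying only the early signature
#' are Newly Activated (recruited by the second exposure); those carrying
#' the late signature are Reactivated (active in both exposures).
#'
#' @param state_labels `"early"`/`"late"` labels from
#'   [classify_activity_state()].
#' @return named character vector with values `"NewlyActivated"` /
#'   `"Reactivated"`.
#' @export
label_reactivation <- function(state_labels) {
  out <- ifelse(state_labels == "late", "Reactivated", "NewlyActivated")
  setNames(out, names(state_labels))
}

#' Activity pseudotime along a minimum-spanning-tree trajectory
#'
#' Restricts the matrix to activity-dependent genes, reduces nuclei to two
#' independent components, builds a Euclidean minimum spanning tree over
#' nuclei in component space and takes pseudotime as the geodesic distance
#' from one end of the tree's diameter path. The root is chosen so that
#' pseudotime increases with the anchor gene's expression (falling back to
#' summed activity-gene expression when the anchor is constant, flagged via
#' the `"orientation"` attribute).
#'
#' @param matrix genes x nuclei expression matrix.
#' @param activity_genes activity-dependent gene identifiers.
#' @param groups optional factor/character vector aligned with nuclei; all
#'   group pairs are compared by Student's t-test on pseudotime.
#' @param anchor_gene orientation anchor (default `"Arc"`,
#'   case-insensitive).
#' @param n_components independent components (default 2).
#' @param seed RNG seed for the ICA initialization.
#' @return object of class `pseudotime_result`: `pseudotime` (named
#'   vector), `components` (nuclei x 2), `comparisons` (data.frame of
#'   pairwise t-tests, or NULL).
#' @export
activity_pseudotime <- function(matrix, activity_genes, groups = NULL,
                                anchor_gene = "Arc", n_components = 2,
                                seed = 1) {
  check_matrix(matrix)
  present <- intersect(activity_genes, rownames(matrix))
  if (length(present) < n_components)
    stopf("need at least %d activity genes in the matrix", n_components)
  if (ncol(matrix) < n_components + 1)
    stopf("need at least %d nuclei", n_components + 1)
  sub <- matrix[present, , drop = FALSE]
  if (all(apply(sub, 1, var) == 0))
    stopf("activity genes are constant across nuclei; trajectory undefined")
  comp <- with_seed(seed, fast_ica(t(sub), n_comp = n_components))

  D <- as.matrix(dist(comp))
  g <- igraph::graph_from_adjacency_matrix(D, mode = "undirected",
                                           weighted = TRUE)
  tree <- igraph::mst(g)
  ends <- igraph::farthest_vertices(tree)$vertices
  pt_a <- igraph::distances(tree, v = ends[1])[1, ]
  anchor_row <- which(tolower(rownames(matrix)) == tolower(anchor_gene))
  orientation <- "anchor"
  if (length(anchor_row) == 1 && sd(matrix[anchor_row, ]) > 0) {
    ref <- matrix[anchor_row, ]
  } else {
    ref <- colSums(sub)
    orientation <- "summed_activity_expression"
  }
  pt <- if (cor(pt_a, ref) >= 0) pt_a else {
    igraph::distances(tree, v = ends[2])[1, ]
  }
  pt <- setNames(as.numeric(pt), colnames(matrix))

  comparisons <- NULL
  if (!is.null(groups)) {
    groups <- as.character(groups)
    gl <- unique(groups)
    pairs <- if (length(gl) > 1) combn(gl, 2) else NULL
    if (!is.null(pairs)) {
      comparisons <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(i) {
        a <- pairs[1, i]; b <- pairs[2, i]
        tt <- t.test(pt[groups == a], pt[groups == b])
        data.frame(group_a = a, group_b = b,
                   mean_a = mean(pt[groups == a]),
                   mean_b = mean(pt[groups == b]),
                   t = unname(tt$statistic), p = tt$p.value,
                   stringsAsFactors = FALSE)
      }))
    }
  }
  structure(list(pseudotime = pt, components = comp,
                 comparisons = comparisons, orientation = orientation),
            class = "pseudotime_result")
}

#' @export
print.pseudotime_result <- function(x, ...) {
  cat(sprintf("pseudotime over %d nuclei (range %.2f - %.2f), oriented by %s\n",
              length(x$pseudotime), min(x$pseudotime), max(x$pseudotime),
              x$orientation))
  if (!is.null(x$comparisons)) print(x$comparisons)
  invisible(x)
}
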