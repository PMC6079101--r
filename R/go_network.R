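#' Read a flat GO annotation from TSV tables
#'
#' @param gene2term_path two-column TSV (gene, term).
#' @param parent_count_path two-column TSV (term, parent_count).
#' @return object of class `go_annotation`.
#' @export
read_go_annotation <- function(gene2term_path, parent_count_path) {
  g2t <- read.delim(gene2term_path, stringsAsFactors = FALSE)
  names(g2t)[1:2] <- c("gene", "term")
  pc <- read.delim(parent_count_path, stringsAsFactors = FALSE)
  go_annotation(g2t, setNames(as.integer(pc[[2]]), pc[[1]]))
}

#' Hypergeometric functional-enrichment test
#'
#' For every annotation term, the upper-tail hypergeometric probability of
#' observing at least the overlap between the query gene set and the term's
#' genes within the universe; Benjamini-Hochberg adjustment across tested
#' terms (by default only terms overlapping the query).
#'
#' @param gene_set query genes (subset of `universe`).
#' @param annotation a `go_annotation`.
#' @param universe background genes.
#' @param min_overlap terms with smaller query overlap are excluded from
#'   testing/adjustment (default 1).
#' @return data.frame with columns `term`, `n_term`, `overlap`, `p`,
#'   `p_adj`, sorted by `p`.
#' @export
enrichment_test <- function(gene_set, annotation, universe, min_overlap = 1) {
  if (!inherits(annotation, "go_annotation"))
    stopf("'annotation' must be a go_annotation")
  if (!length(universe)) stopf("'universe' must be non-empty")
  if (!length(gene_set)) stopf("'gene_set' must be non-empty")
  if (length(bad <- setdiff(gene_set, universe)))
    stopf("gene_set not contained in universe: %s",
          paste(head(bad, 5), collapse = ", "))
  gene_set <- unique(gene_set)
  universe <- unique(universe)
  g2t <- annotation$gene2term[annotation$gene2term$gene %in% universe, ]
  terms <- split(g2t$gene, g2t$term)
  res <- do.call(rbind, lapply(names(terms), function(tm) {
    tg <- unique(terms[[tm]])
    k <- length(intersect(tg, gene_set))
    data.frame(term = tm, n_term = length(tg), overlap = k,
               p = phyper(k - 1, length(tg), length(universe) - length(tg),
                          length(gene_set), lower.tail = FALSE),
               stringsAsFactors = FALSE)
  }))
  if (is.null(res)) return(data.frame(term = character(0),
                                      n_term = integer(0),
                                      overlap = integer(0),
                                      p = numeric(0), p_adj = numeric(0)))
  res <- res[res$overlap >= min_overlap, , drop = FALSE]
  res$p_adj <- p.adjust(res$p, "BH")
  res <- res[order(res$p), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Weighted cosine GO distance between genes
#'
#' Each gene is represented as a weighted indicator vector over annotation
#' terms, the weight of term t being `weight_fn(parent_count_t)` (default
#' `log2(1 + parent_count)`, up-weighting deeper, more specific terms).
#' The gene-gene distance is one minus the cosine similarity of these
#' vectors: 0 for identical term sets, 1 for disjoint ones, and invariant
#' to rescaling all weights by a constant.
#'
#' @param genes gene identifiers; every gene must carry at least one term
#'   with positive weight.
#' @param annotation a `go_annotation`.
#' @param weight_fn function mapping a parent count to a non-negative
#'   weight.
#' @return symmetric genes x genes distance matrix in [0, 1] with zero
#'   diagonal.
#' @export
go_gene_distance <- function(genes, annotation,
                             weight_fn = function(p) log2(1 + p)) {
  if (!inherits(annotation, "go_annotation"))
    stopf("'annotation' must be a go_annotation")
  genes <- unique(genes)
  g2t <- annotation$gene2term
  miss <- setdiff(genes, g2t$gene)
  if (length(miss))
    stopf("unannotated gene(s): %s", paste(head(miss, 5), collapse = ", "))
  terms <- sort(unique(g2t$term[g2t$gene %in% genes]))
  w <- weight_fn(as.numeric(annotation$parent_count[terms]))
  if (any(w < 0)) stopf("weight_fn produced negative weights")
  V <- matrix(0, length(genes), length(terms),
              dimnames = list(genes, terms))
  hit <- g2t[g2t$gene %in% genes, ]
  V[cbind(match(hit$gene, genes), match(hit$term, terms))] <- 1
  V <- sweep(V, 2, w, "*")
  nrm <- sqrt(rowSums(V^2))
  if (any(nrm == 0))
    stopf("gene(s) with zero total annotation weight: %s",
          paste(head(genes[nrm == 0], 5), collapse = ", "))
  S <- tcrossprod(V / nrm)
  D <- 1 - pmin(pmax(S, 0), 1)
  diag(D) <- 0
  D
}

#' Export a gene network from a distance matrix
#'
#' Writes the undirected edge list of gene pairs at or below a distance
#' threshold in simple interaction format (SIF: `gene1 <TAB> sim <TAB>
#' gene2`, one edge per line) and returns the edges as a data.frame.
#'
#' @param distances symmetric distance matrix (e.g. from
#'   [go_gene_distance()]).
#' @param edge_threshold maximum distance for an edge, in [0, 1].
#' @param path optional output file; omitted = no file written.
#' @return data.frame with columns `gene1`, `gene2`, `distance`.
#' @export
export_network <- function(distances, edge_threshold, path = NULL) {
  if (edge_threshold < 0 || edge_threshold > 1)
    stopf("'edge_threshold' must be in [0, 1]")
  if (!isSymmetric(unname(distances)))
    stopf("'distances' must be a symmetric matrix")
  idx <- which(upper.tri(distances) & distances <= edge_threshold,
               arr.ind = TRUE)
  edges <- data.frame(gene1 = rownames(distances)[idx[, 1]],
                      gene2 = colnames(distances)[idx[, 2]],
                      distance = distances[idx], stringsAsFactors = FALSE)
  edges <- edges[order(edges$gene1, edges$gene2), , drop = FALSE]
  rownames(edges) <- NULL
  if (!is.null(path))
    writeLines(sprintf("%s\tsim\t%s", edges$gene1, edges$gene2), path)
  edges
}
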