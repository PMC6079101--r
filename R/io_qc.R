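#' Read a gene-by-nucleus expression matrix
#'
#' Supports a dense tab-separated table (gene identifiers in the first
#' column, nucleus identifiers in the header) and MatrixMarket sparse
#' triplets with sidecar row/column name files (`<path>.rownames` /
#' `<path>.colnames`, one name per line).
#'
#' @param path file path; for `format = "mtx"` the sidecar name files must
#'   sit next to it.
#' @param format `"tsv"` or `"mtx"`.
#' @return numeric matrix (genes x nuclei) of log2(TPM+1) values.
#' @export
read_expression_matrix <- function(path, format = c("tsv", "mtx")) {
  format <- match.arg(format)
  if (!file.exists(path)) stopf("file not found: %s", path)
  if (format == "tsv") {
    tab <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
    ids <- as.character(tab[[1]])
    if (anyDuplicated(ids))
      stopf("duplicate gene identifiers in %s: %s", path,
            paste(unique(ids[duplicated(ids)]), collapse = ", "))
    m <- as.matrix(tab[, -1, drop = FALSE])
    storage.mode(m) <- "double"
    rownames(m) <- ids
  } else {
    sp <- Matrix::readMM(path)
    rn <- readLines(paste0(path, ".rownames"))
    cn <- readLines(paste0(path, ".colnames"))
    if (nrow(sp) != length(rn) || ncol(sp) != length(cn))
      stopf("sidecar name files do not match matrix dimensions for %s", path)
    if (anyDuplicated(rn))
      stopf("duplicate gene identifiers in %s: %s", path,
            paste(unique(rn[duplicated(rn)]), collapse = ", "))
    m <- as.matrix(sp)
    dimnames(m) <- list(rn, cn)
  }
  check_matrix(m, path)
  m
}

#' Write an expression matrix
#'
#' @param matrix genes x nuclei numeric matrix with dimnames.
#' @param path output path.
#' @param format `"tsv"` (dense) or `"mtx"` (MatrixMarket triplets with
#'   sidecar `.rownames`/`.colnames` files).
#' @export
write_expression_matrix <- function(matrix, path, format = c("tsv", "mtx")) {
  format <- match.arg(format)
  check_matrix(matrix)
  if (format == "tsv") {
    tab <- data.frame(gene = rownames(matrix), matrix, check.names = FALSE,
                      stringsAsFactors = FALSE)
    write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    Matrix::writeMM(methods::as(methods::as(Matrix::Matrix(matrix,
                                                           sparse = TRUE),
                                            "generalMatrix"), "CsparseMatrix"),
                    path)
    writeLines(rownames(matrix), paste0(path, ".rownames"))
    writeLines(colnames(matrix), paste0(path, ".colnames"))
  }
  invisible(path)
}

#' Read / write a nucleus metadata table
#'
#' @param path TSV path with a `nucleus_id` column.
#' @return data.frame.
#' @export
read_metadata <- function(path) {
  md <- read.delim(path, stringsAsFactors = FALSE)
  if (!"nucleus_id" %in% names(md))
    stopf("metadata %s lacks a 'nucleus_id' column", path)
  md
}

#' @rdname read_metadata
#' @param metadata data.frame to write.
#' @export
write_metadata <- function(metadata, path) {
  write.table(metadata, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

qc_report <- function(n_input, fail_reads, fail_genes, fail_arc, retained_ids) {
  structure(list(n_input = n_input,
                 n_fail_reads = length(fail_reads),
                 n_fail_genes = length(fail_genes),
                 n_fail_arc_rule = length(fail_arc),
                 n_retained = length(retained_ids),
                 retained_ids = retained_ids,
                 failed = list(reads = fail_reads, genes = fail_genes,
                               arc = fail_arc)),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf(paste0("QC report: %d nuclei in, %d retained (%.1f%%)\n",
                     "  failed read cutoff: %d; gene cutoff: %d; ",
                     "Arc-discordance rule: %d\n"),
              x$n_input, x$n_retained, 100 * x$n_retained / x$n_input,
              x$n_fail_reads, x$n_fail_genes, x$n_fail_arc_rule))
  invisible(x)
}

#' Nucleus-level quality filter
#'
#' Removes nuclei whose total aligned reads or detected gene count falls
#' below the cutoffs. Values exactly at a cutoff are retained: only nuclei
#' *below* the thresholds are outliers.
#'
#' @param matrix genes x nuclei expression matrix.
#' @param metadata data.frame with `nucleus_id`, `total_aligned_reads` and
#'   `detected_genes` covering every matrix column.
#' @param min_reads,min_genes cutoffs; defaults 100000 aligned reads and
#'   4000 detected genes.
#' @return object of class `qc_report`; `retained_ids` lists survivors in
#'   matrix column order.
#' @export
qc_filter_nuclei <- function(matrix, metadata, min_reads = 100000,
                             min_genes = 4000) {
  check_matrix(matrix)
  need <- c("nucleus_id", "total_aligned_reads", "detected_genes")
  miss_col <- setdiff(need, names(metadata))
  if (length(miss_col))
    stopf("metadata lacks column(s): %s", paste(miss_col, collapse = ", "))
  ids <- colnames(matrix)
  missing <- setdiff(ids, metadata$nucleus_id)
  if (length(missing))
    stopf("metadata missing for nuclei: %s",
          paste(head(missing, 5), collapse = ", "))
  md <- metadata[match(ids, metadata$nucleus_id), ]
  bad <- is.na(md$total_aligned_reads) | is.na(md$detected_genes)
  if (any(bad))
    stopf("missing read/gene counts for nuclei: %s",
          paste(head(ids[bad], 5), collapse = ", "))
  fail_reads <- ids[md$total_aligned_reads < min_reads]
  fail_genes <- ids[md$detected_genes < min_genes]
  retained <- setdiff(ids, union(fail_reads, fail_genes))
  qc_report(length(ids), fail_reads, fail_genes, character(0), retained)
}

#' Optional clustering-based extreme-outlier filter
#'
#' Removes nuclei whose silhouette width against their own cluster falls
#' below a cutoff. The original workflow's extreme-outlier criterion is not
#' reconstructable, so this filter is provided as an explicit, configurable
#' stand-in and is not part of the default QC path.
#'
#' @param matrix genes x nuclei expression matrix.
#' @param labels cluster labels aligned with matrix columns (at least 2
#'   clusters).
#' @param min_silhouette silhouette-width cutoff; nuclei strictly below it
#'   are removed (default -0.25, removing only strongly misplaced nuclei).
#' @return list with `n_input`, `n_removed`, `removed_ids`, `retained_ids`
#'   and the per-nucleus `silhouette` widths.
#' @export
qc_extreme_outliers <- function(matrix, labels, min_silhouette = -0.25) {
  check_matrix(matrix)
  if (length(labels) != ncol(matrix))
    stopf("'labels' must align with matrix columns")
  labels <- as.integer(factor(labels))
  if (length(unique(labels)) < 2)
    stopf("silhouette needs at least 2 clusters")
  sil <- cluster::silhouette(labels, dist(t(matrix)))
  widths <- setNames(sil[, "sil_width"], colnames(matrix))
  fail <- colnames(matrix)[widths < min_silhouette]
  list(n_input = ncol(matrix), n_removed = length(fail),
       removed_ids = fail,
       retained_ids = setdiff(colnames(matrix), fail),
       silhouette = widths)
}

#' Exclude FOS-negative nuclei with discordantly high Arc expression
#'
#' A FOS- protein stain with high *Arc* transcript indicates a nucleus that
#' was recently active but has already degraded FOS; such nuclei are removed
#' so the FOS- pool is a genuine inactive baseline. The rule is a strict
#' inequality: `Arc > arc_threshold` on the log2(TPM+1) scale. FOS+ nuclei
#' are never removed.
#'
#' @param matrix genes x nuclei expression matrix containing an Arc row.
#' @param metadata data.frame with `nucleus_id` and `fos_protein`
#'   (`pos`/`neg`/`low`).
#' @param arc_threshold log2(TPM+1) cutoff, default 2.5.
#' @param arc_gene gene identifier for Arc; matched case-insensitively
#'   against rownames when left at the default.
#' @return object of class `qc_report`.
#' @export
exclude_arc_discordant <- function(matrix, metadata, arc_threshold = 2.5,
                                   arc_gene = "Arc") {
  check_matrix(matrix)
  hit <- which(tolower(rownames(matrix)) == tolower(arc_gene))
  if (length(hit) != 1L)
    stopf("Arc gene '%s' not resolvable in the matrix (found %d matches)",
          arc_gene, length(hit))
  ids <- colnames(matrix)
  md <- metadata[match(ids, metadata$nucleus_id), ]
  if (any(is.na(md$fos_protein)))
    stopf("metadata missing for nuclei: %s",
          paste(head(ids[is.na(md$fos_protein)], 5), collapse = ", "))
  arc <- matrix[hit, ]
  fail <- ids[md$fos_protein == "neg" & arc > arc_threshold]
  qc_report(length(ids), character(0), character(0), fail,
            setdiff(ids, fail))
}
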