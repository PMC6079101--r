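#' @importFrom stats aov coef cor cor.test dist hclust cutree kmeans kruskal.test
#'   p.adjust phyper prcomp predict rnbinom rnorm runif sd setNames t.test var
#'   rbinom quantile
#' @importFrom utils combn head read.delim write.table
NULL

# Evaluate expr under a fixed RNG seed, restoring the caller's RNG state after.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv())) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv()))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(expr)
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)

check_fraction <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
    stopf("'%s' must be a single number in [0, 1], got %s", name,
          paste(format(x), collapse = ", "))
  x
}

check_count <- function(x, name, min = 0L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min ||
      x != round(x))
    stopf("'%s' must be a single integer >= %d", name, min)
  as.integer(x)
}

check_matrix <- function(x, name = "matrix") {
  if (!is.matrix(x) || !is.numeric(x))
    stopf("'%s' must be a numeric matrix (genes x nuclei)", name)
  if (is.null(rownames(x)) || is.null(colnames(x)))
    stopf("'%s' must have gene rownames and nucleus colnames", name)
  if (anyDuplicated(rownames(x)))
    stopf("duplicate gene identifiers in '%s': %s", name,
          paste(unique(rownames(x)[duplicated(rownames(x))]), collapse = ", "))
  if (anyDuplicated(colnames(x)))
    stopf("duplicate nucleus identifiers in '%s': %s", name,
          paste(unique(colnames(x)[duplicated(colnames(x))]), collapse = ", "))
  if (any(x < 0))
    stopf("'%s' contains negative values; expected log2(TPM+1) scale", name)
  invisible(x)
}
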