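#' Parameters for the reproducibility-optimized test statistic
#'
#' The test statistic for gene g is
#' \deqn{d_g = |m_{A,g} - m_{B,g}| / (\alpha_1 + \alpha_2 s_g)}
#' where m are group means and s is the pooled standard error. The
#' regularization pair (alpha1, alpha2) is chosen by maximizing the
#' bootstrap reproducibility Z-score of top-K gene lists: overlap of top-K
#' lists across pairs of within-group bootstrap resamples, baselined against
#' pairs with permuted group labels and scaled by the bootstrap SD of the
#' overlap.
#'
#' @param B bootstrap pair count for the reproducibility optimization
#'   (default 500).
#' @param K_grid top-list sizes scanned; default
#'   `c(25, 50, 100, 200, 300, 500)` capped at the gene count.
#' @param alpha1,alpha2 fix the regularization instead of tuning it (both
#'   must be given together); `alpha2` must be 0 or 1.
#' @param alpha_grid candidate alpha1 values scanned with alpha2 = 1; a
#'   scale-free alpha2 = 0 (plain fold-change ranking) candidate is always
#'   included.
#' @param n_perm label permutations for sampled p-values (default 1000).
#' @param exhaustive_limit when `choose(n, nA)` is at most this, p-values
#'   are computed per gene by exhaustive enumeration of all label
#'   assignments instead of sampling.
#' @param seed RNG seed (default 1234).
#' @return list of class `rots_params`.
#' @export
rots_params <- function(B = 500, K_grid = NULL, alpha1 = NULL, alpha2 = NULL,
                        alpha_grid = seq(0, 5, by = 0.1), n_perm = 1000,
                        exhaustive_limit = 200, seed = 1234) {
  B <- check_count(B, "B", 2L)
  if (xor(is.null(alpha1), is.null(alpha2)))
    stopf("supply both 'alpha1' and 'alpha2' to fix the statistic, or neither")
  if (!is.null(alpha2) && !alpha2 %in% c(0, 1))
    stopf("'alpha2' must be 0 or 1")
  if (!is.null(alpha1) && alpha1 < 0) stopf("'alpha1' must be >= 0")
  structure(list(B = B, K_grid = K_grid, alpha1 = alpha1, alpha2 = alpha2,
                 alpha_grid = alpha_grid, n_perm = n_perm,
                 exhaustive_limit = exhaustive_limit, seed = seed),
            class = "rots_params")
}

# group stats for one labelling: difference of means and pooled SE
.group_stats <- function(X, idxA, idxB) {
  XA <- X[, idxA, drop = FALSE]
  XB <- X[, idxB, drop = FALSE]
  mA <- rowMeans(XA)
  mB <- rowMeans(XB)
  ssA <- rowSums((XA - mA)^2)
  ssB <- rowSums((XB - mB)^2)
  nA <- length(idxA); nB <- length(idxB)
  s <- sqrt(((ssA + ssB) / (nA + nB - 2)) * (1 / nA + 1 / nB))
  list(m = mA - mB, s = s, mA = mA, mB = mB)
}

.dstat <- function(m, s, a1, a2) {
  den <- a1 + a2 * s
  d <- abs(m) / den
  zero <- den == 0
  if (any(zero)) d[zero] <- ifelse(m[zero] == 0, 0, Inf)
  d
}

# reproducibility tuning: returns list(alpha1, alpha2, K, Z)
.rots_tune <- function(X, nA, nB, params) {
  n <- nA + nB
  ng <- nrow(X)
  B <- params$B
  Ks <- params$K_grid
  if (is.null(Ks)) Ks <- c(25, 50, 100, 200, 300, 500)
  Ks <- sort(unique(pmin(Ks, ng)))
  Ks <- Ks[Ks >= 2]
  if (!length(Ks)) Ks <- min(2L, ng)
  cand <- rbind(data.frame(a1 = params$alpha_grid, a2 = 1),
                data.frame(a1 = 1, a2 = 0))

  # 2B bootstrap datasets (pairs) and 2B permuted-label datasets
  boot_m <- boot_s <- matrix(0, ng, 2 * B)
  perm_m <- perm_s <- matrix(0, ng, 2 * B)
  for (j in seq_len(2 * B)) {
    bi <- c(sample(seq_len(nA), nA, replace = TRUE),
            nA + sample(seq_len(nB), nB, replace = TRUE))
    st <- .group_stats(X[, bi, drop = FALSE], seq_len(nA),
                       nA + seq_len(nB))
    boot_m[, j] <- st$m; boot_s[, j] <- st$s
    pi <- sample(n)
    st <- .group_stats(X, pi[seq_len(nA)], pi[nA + seq_len(nB)])
    perm_m[, j] <- st$m; perm_s[, j] <- st$s
  }

  odd <- seq(1, 2 * B, by = 2)
  even <- odd + 1
  best <- list(Z = -Inf, a1 = 1, a2 = 1, K = Ks[1])
  for (i in seq_len(nrow(cand))) {
    a1 <- cand$a1[i]; a2 <- cand$a2[i]
    rb <- apply(.dstat(boot_m, boot_s, a1, a2), 2, function(x)
      rank(-x, ties.method = "first"))
    rp <- apply(.dstat(perm_m, perm_s, a1, a2), 2, function(x)
      rank(-x, ties.method = "first"))
    rb_o <- rb[, odd, drop = FALSE]; rb_e <- rb[, even, drop = FALSE]
    rp_o <- rp[, odd, drop = FALSE]; rp_e <- rp[, even, drop = FALSE]
    for (k in Ks) {
      ovb <- colSums(rb_o <= k & rb_e <= k) / k
      ovp <- colSums(rp_o <= k & rp_e <= k) / k
      sdb <- sd(ovb)
      if (sdb == 0) next
      Z <- (mean(ovb) - mean(ovp)) / sdb
      if (is.finite(Z) && Z > best$Z)
        best <- list(Z = Z, a1 = a1, a2 = a2, K = k)
    }
  }
  best
}

#' Reproducibility-optimized two-group differential expression test
#'
#' Computes a regularized t-type statistic per gene, tunes the
#' regularization by bootstrap top-list reproducibility (unless fixed in
#' `params`), derives p-values by group-label permutation and adjusts them
#' by Benjamini-Hochberg. For small samples (`choose(n, nA)` within
#' `params$exhaustive_limit`) the permutation null is enumerated exhaustively
#' per gene; otherwise `n_perm` sampled label permutations are pooled across
#' genes for resolution.
#'
#' @param matrix_A,matrix_B genes x nuclei matrices for the two groups;
#'   shared gene set in identical order, each group with at least 2 nuclei.
#' @param params a [rots_params()] object.
#' @return data.frame of class `rots_result` with columns `gene`, `d`,
#'   `mean_A`, `mean_B`, `direction` (`up` means higher in A), `p_raw`,
#'   `p_adj`; chosen regularization in attributes `alpha1`, `alpha2`, `K`,
#'   `Z` and `p_method`.
#' @export
rots_test <- function(matrix_A, matrix_B, params = rots_params()) {
  if (!inherits(params, "rots_params"))
    stopf("'params' must come from rots_params()")
  if (is.null(dim(matrix_A)) || is.null(dim(matrix_B)))
    stopf("inputs must be genes x nuclei matrices")
  if (!identical(rownames(matrix_A), rownames(matrix_B)))
    stopf("matrix_A and matrix_B must share an identical gene set")
  nA <- ncol(matrix_A); nB <- ncol(matrix_B)
  if (nA < 2 || nB < 2)
    stopf("each group needs at least 2 nuclei (got %d and %d)", nA, nB)
  X <- cbind(matrix_A, matrix_B)
  ng <- nrow(X)
  with_seed(params$seed, {
    if (is.null(params$alpha1)) {
      tuned <- .rots_tune(X, nA, nB, params)
    } else {
      tuned <- list(a1 = params$alpha1, a2 = params$alpha2, K = NA, Z = NA)
    }
    obs <- .group_stats(X, seq_len(nA), nA + seq_len(nB))
    d_obs <- .dstat(obs$m, obs$s, tuned$a1, tuned$a2)

    n <- nA + nB
    n_assign <- choose(n, nA)
    if (n_assign <= params$exhaustive_limit) {
      # exhaustive per-gene permutation p over all label assignments
      combos <- combn(n, nA)
      ge <- integer(ng)
      for (j in seq_len(ncol(combos))) {
        idxA <- combos[, j]
        st <- .group_stats(X, idxA, setdiff(seq_len(n), idxA))
        dp <- .dstat(st$m, st$s, tuned$a1, tuned$a2)
        ge <- ge + (dp >= d_obs)
      }
      p_raw <- ge / n_assign
      p_method <- "exhaustive"
    } else {
      dnull <- numeric(0)
      acc <- vector("list", params$n_perm)
      for (j in seq_len(params$n_perm)) {
        pi <- sample(n)
        st <- .group_stats(X, pi[seq_len(nA)], pi[nA + seq_len(nB)])
        acc[[j]] <- .dstat(st$m, st$s, tuned$a1, tuned$a2)
      }
      dnull <- sort(unlist(acc))
      N <- length(dnull)
      cnt_ge <- N - findInterval(d_obs, dnull, left.open = TRUE)
      p_raw <- (1 + cnt_ge) / (1 + N)
      p_method <- "pooled"
    }
    res <- data.frame(
      gene = rownames(X), d = d_obs, mean_A = obs$mA, mean_B = obs$mB,
      direction = ifelse(obs$m >= 0, "up", "down"),
      p_raw = p_raw, p_adj = p.adjust(p_raw, "BH"),
      stringsAsFactors = FALSE, row.names = NULL)
    attr(res, "alpha1") <- tuned$a1
    attr(res, "alpha2") <- tuned$a2
    attr(res, "K") <- tuned$K
    attr(res, "Z") <- tuned$Z
    attr(res, "p_method") <- p_method
    class(res) <- c("rots_result", "data.frame")
    res
  })
}

#' Cell-type subsampling comparison of DEG counts
#'
#' Tests whether differences in the number of differentially expressed genes
#' across cell types are driven by sample size: each (cell type, FOS status)
#' stratum is subsampled without replacement to the same size, the DE test is
#' run on the reduced data and significant genes are counted; the procedure
#' is repeated and DEG counts are compared across cell types by one-way
#' ANOVA on the untransformed counts.
#'
#' @param matrix genes x nuclei matrix covering all strata.
#' @param cell_type,fos character vectors aligned with matrix columns; `fos`
#'   must contain `"pos"`/`"neg"`.
#' @param n_per_group nuclei drawn per FOS status (default 10).
#' @param reps repetitions (default 5).
#' @param alpha adjusted-p cutoff counted as a DEG.
#' @param params [rots_params()] for the per-subsample tests.
#' @param seed RNG seed for the draws.
#' @return list of class `subsample_deg` with `counts` (reps x cell types),
#'   `summary` (mean, sd per type) and `anova_p`.
#' @export
subsample_deg_counts <- function(matrix, cell_type, fos, n_per_group = 10,
                                 reps = 5, alpha = 0.05,
                                 params = rots_params(), seed = 1) {
  check_matrix(matrix)
  if (length(cell_type) != ncol(matrix) || length(fos) != ncol(matrix))
    stopf("'cell_type' and 'fos' must align with matrix columns")
  types <- unique(cell_type)
  for (ct in types) for (st in c("pos", "neg")) {
    n_have <- sum(cell_type == ct & fos == st)
    if (n_have < n_per_group)
      stopf("stratum (%s, FOS %s) has %d nuclei, fewer than n_per_group = %d",
            ct, st, n_have, n_per_group)
  }
  counts <- with_seed(seed, {
    sapply(types, function(ct) {
      sapply(seq_len(reps), function(r) {
        iA <- sample(which(cell_type == ct & fos == "pos"), n_per_group)
        iB <- sample(which(cell_type == ct & fos == "neg"), n_per_group)
        de <- rots_test(matrix[, iA, drop = FALSE],
                        matrix[, iB, drop = FALSE], params)
        sum(de$p_adj < alpha)
      })
    })
  })
  counts <- matrix(counts, nrow = reps,
                   dimnames = list(NULL, types))
  smry <- data.frame(cell_type = types,
                     mean = colMeans(counts),
                     sd = if (reps > 1) apply(counts, 2, sd) else NA_real_,
                     row.names = NULL)
  long <- data.frame(count = as.vector(counts),
                     cell_type = factor(rep(types, each = reps)))
  anova_p <- if (reps > 1 && length(types) > 1) {
    summary(aov(count ~ cell_type, data = long))[[1]][["Pr(>F)"]][1]
  } else NA_real_
  structure(list(counts = counts, summary = smry, anova_p = anova_p,
                 sd_defined = reps > 1),
            class = "subsample_deg")
}

#' @export
print.subsample_deg <- function(x, ...) {
  cat("Subsampled DEG counts per cell type:\n")
  print(x$summary)
  cat(sprintf("one-way ANOVA across cell types: p = %.3g\n", x$anova_p))
  invisible(x)
}

#' Hypergeometric test of gene-set overlap
#'
#' Upper-tail (at least the observed overlap) hypergeometric probability of
#' the intersection of two gene sets drawn from a shared universe.
#'
#' @param set_A,set_B character vectors, subsets of `universe`.
#' @param universe character vector of all eligible genes.
#' @return object of class `htest` with the overlap size as statistic.
#' @export
overlap_test <- function(set_A, set_B, universe) {
  if (!length(universe)) stopf("'universe' must be non-empty")
  if (length(bad <- setdiff(set_A, universe)))
    stopf("set_A not contained in universe: %s",
          paste(head(bad, 5), collapse = ", "))
  if (length(bad <- setdiff(set_B, universe)))
    stopf("set_B not contained in universe: %s",
          paste(head(bad, 5), collapse = ", "))
  set_A <- unique(set_A); set_B <- unique(set_B)
  k <- length(intersect(set_A, set_B))
  U <- length(unique(universe))
  p <- phyper(k - 1, length(set_A), U - length(set_A), length(set_B),
              lower.tail = FALSE)
  structure(list(statistic = c(overlap = k),
                 parameter = c(`|A|` = length(set_A), `|B|` = length(set_B),
                               `|U|` = U),
                 p.value = p,
                 method = "Hypergeometric test of gene-set overlap",
                 alternative = "overlap at least as large as observed",
                 data.name = "set_A, set_B given universe"),
            class = "htest")
}
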