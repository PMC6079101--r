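# Minimal fastICA (logcosh contrast, symmetric decorrelation).
# x: observations x variables. Returns observations x n_comp source matrix.
fast_ica <- function(x, n_comp = 2, maxit = 200, tol = 1e-6) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (n <= n_comp) stopf("ICA needs more observations than components")
  pc <- prcomp(x, center = TRUE, scale. = FALSE)
  k <- min(n_comp, sum(pc$sdev > 1e-12))
  if (k < n_comp)
    stopf("input is degenerate: fewer than %d non-trivial dimensions", n_comp)
  Z <- sweep(pc$x[, seq_len(k), drop = FALSE], 2, pc$sdev[seq_len(k)], "/")
  W <- qr.Q(qr(matrix(rnorm(k * k), k, k)))
  for (it in seq_len(maxit)) {
    S <- Z %*% W
    G <- tanh(S)
    W1 <- crossprod(Z, G) / n -
      sweep(W, 2, colMeans(1 - G^2), "*")
    # symmetric decorrelation W1 <- W1 (W1'W1)^{-1/2}
    sq <- eigen(crossprod(W1), symmetric = TRUE)
    W1 <- W1 %*% (sq$vectors %*% diag(1 / sqrt(pmax(sq$values, 1e-12)),
                                      k, k) %*% t(sq$vectors))
    delta <- max(abs(abs(colSums(W1 * W)) - 1))
    W <- W1
    if (delta < tol) break
  }
  S <- Z %*% W
  # restore component amplitudes: column j of the mixing matrix has norm
  # sqrt(sum_p (d_p W[p,j])^2); unit-variance sources would inflate noise
  # directions to signal scale and distort downstream geodesics
  amp <- sqrt(colSums((W * pc$sdev[seq_len(k)])^2))
  S <- sweep(S, 2, amp, "*")
  colnames(S) <- paste0("IC", seq_len(k))
  rownames(S) <- rownames(x)
  S
}
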