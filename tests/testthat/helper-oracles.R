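# Independent dense oracles used across the suite. These deliberately avoid
# the package's own code paths: ranks come from a dense QR/eigen
# factorisation, pairwise covariances from entrywise evaluation, residuals
# from explicit dense projection.

# random symmetric PSD matrix of a chosen rank
random_psd <- function(N, rank = N, seed = NULL, scale = 1) {
  if (!is.null(seed)) set.seed(seed)
  X <- matrix(rnorm(N * rank), N, rank)
  C <- tcrossprod(X) * scale
  (C + t(C)) / 2
}

# PSD matrix whose range is spanned by given columns
psd_from_basis <- function(basis, weights = NULL) {
  basis <- as.matrix(basis)
  weights <- weights %||% rep(1, ncol(basis))
  C <- basis %*% (weights * t(basis))
  (C + t(C)) / 2
}
`%||%` <- function(a, b) if (is.null(a)) b else a

# numerical rank of a dense matrix via its singular values
dense_rank <- function(X) {
  s <- svd(X, nu = 0, nv = 0)$d
  if (!length(s) || max(s) == 0) return(0L)
  sum(s > max(dim(X)) * .Machine$double.eps * max(s))
}

# pairs-of-pairs covariance evaluated entrywise from the definition
# Cov(l_i - l_j, l_k - l_l) = C_ik - C_il - C_jk + C_jl
delta_entrywise <- function(C) {
  N <- nrow(C)
  pairs <- which(upper.tri(diag(N)), arr.ind = TRUE)
  pairs <- pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE]
  M <- nrow(pairs)
  D <- matrix(0, M, M)
  for (r in seq_len(M)) {
    for (s in seq_len(M)) {
      i <- pairs[r, 1]; j <- pairs[r, 2]
      k <- pairs[s, 1]; l <- pairs[s, 2]
      D[r, s] <- C[i, k] - C[i, l] - C[j, k] + C[j, l]
    }
  }
  D
}

# dense per-column projection residual of E onto an orthonormal basis Y
dense_column_residuals <- function(Eop, Y) {
  Ed <- as.matrix(Eop)
  P <- Ed - Y %*% crossprod(Y, Ed)
  sqrt(colSums(P^2)) / sqrt(colSums(Ed^2))
}
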