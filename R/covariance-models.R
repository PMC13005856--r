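#' Prior covariance models
#'
#' A `covariance_model` is an `N x N` symmetric positive semidefinite matrix
#' carrying metadata about how it was generated (`family`, `params`, `seed`).
#' It behaves as an ordinary matrix in all linear algebra. Constructors:
#' [laplacian_covariance()], [toeplitz_covariance()],
#' [inverse_wishart_covariance()], [exp_adjacency_covariance()],
#' [normalize_to_correlation()], [as_covariance_model()].
#'
#' @param C A symmetric numeric matrix.
#' @param family Character tag for the generating family.
#' @param params Named list of generation parameters.
#' @param seed Integer seed used at generation, or `NULL`.
#' @return A matrix of class `covariance_model`.
#' @export
as_covariance_model <- function(C, family = "external", params = list(),
                                seed = NULL) {
  C <- as.matrix(C)
  if (nrow(C) != ncol(C)) abort("covariance matrix must be square")
  if (!is.numeric(C)) abort("covariance matrix must be numeric")
  asym <- max(abs(C - t(C))) / max(abs(C), 1e-300)
  if (asym > 1e-8) {
    abort(sprintf("matrix is not symmetric (relative asymmetry %.3g)", asym))
  }
  C <- (C + t(C)) / 2
  structure(C,
    class = c("covariance_model", class(matrix())),
    family = family, params = params, seed = seed
  )
}

#' @export
print.covariance_model <- function(x, ...) {
  cat(sprintf(
    "<covariance_model> %d x %d, family = %s\n",
    nrow(x), ncol(x), attr(x, "family")
  ))
  p <- attr(x, "params")
  if (length(p)) {
    cat("  params:", paste(names(p), unlist(p), sep = " = ", collapse = ", "), "\n")
  }
  print(unclass_cov(x)[seq_len(min(6L, nrow(x))), seq_len(min(6L, ncol(x))), drop = FALSE])
  if (nrow(x) > 6L) cat(sprintf("  ... (%d rows/cols not shown)\n", nrow(x) - 6L))
  invisible(x)
}

unclass_cov <- function(C) {
  attributes(C) <- list(dim = dim(C))
  C
}

#' Erdos-Renyi random graph
#'
#' Simulates a simple undirected graph on `N` nodes where each of the
#' `N(N-1)/2` possible edges is present independently with probability `p`,
#' returned as a `graph_model` (adjacency + degree matrix) ready for
#' [laplacian_covariance()] or [exp_adjacency_covariance()].
#'
#' @param N Number of nodes.
#' @param p Edge probability in `[0, 1]`.
#' @param seed Optional integer seed for reproducibility.
#' @return A list of class `graph_model` with elements `N`, `A` (0/1
#'   adjacency, zero diagonal), `D` (diagonal degree matrix), `p`, `seed`.
#' @export
#' @examples
#' g <- erdos_renyi_adjacency(8, 0.5, seed = 1)
erdos_renyi_adjacency <- function(N, p, seed = NULL) {
  N <- check_n_objects(N)
  if (length(p) != 1L || !is.finite(p) || p < 0 || p > 1) {
    abort("edge probability p must lie in [0, 1]")
  }
  if (!is.null(seed)) set.seed(seed)
  pg <- pair_grid(N)
  present <- runif(nrow(pg)) < p
  A <- matrix(0, N, N)
  A[cbind(pg$i[present], pg$j[present])] <- 1
  A <- A + t(A)
  structure(
    list(N = N, A = A, D = diag(rowSums(A), N), p = p, seed = seed),
    class = "graph_model"
  )
}

#' @export
print.graph_model <- function(x, ...) {
  cat(sprintf(
    "<graph_model> %d nodes, %d edges (p = %s)\n",
    x$N, sum(x$A) / 2, format(x$p)
  ))
  invisible(x)
}

#' Graph-Laplacian prior covariance
#'
#' `C = (D - A + I)^{-1}`, the inverse of the graph Laplacian regularised by
#' the identity. This Gaussian-Markov-random-field-type prior enforces
#' smoothness of qualities across the graph; the `+ I` term makes the
#' Laplacian strictly positive definite for every graph, connected or not.
#'
#' @param G A `graph_model` from [erdos_renyi_adjacency()] (or a compatible
#'   list with elements `A` and `D`).
#' @return A `covariance_model`.
#' @export
laplacian_covariance <- function(G) {
  A <- G$A
  L <- G$D - A + diag(nrow(A))
  C <- chol2inv(chol(L))
  as_covariance_model(C,
    family = "laplacian",
    params = list(p = G$p %||% NA_real_), seed = G$seed
  )
}

#' Toeplitz (AR-1) prior covariance
#'
#' `C[i, j] = rho^|i - j|`: an autoregressive correlation structure for
#' studies with a natural prior ordering of the objects.
#'
#' @param N Number of objects.
#' @param rho Decay parameter, `|rho| < 1`. The canonical setting is 0.5.
#' @return A `covariance_model` with unit diagonal.
#' @export
toeplitz_covariance <- function(N, rho = 0.5) {
  N <- check_n_objects(N)
  if (length(rho) != 1L || !is.finite(rho) || abs(rho) >= 1) {
    abort("|rho| must be < 1")
  }
  C <- rho^abs(outer(seq_len(N), seq_len(N), "-"))
  as_covariance_model(C, family = "toeplitz", params = list(rho = rho))
}

#' Normalised inverse-Wishart prior covariance
#'
#' One draw from the inverse-Wishart distribution with identity scale matrix
#' (a weakly informative prior), rescaled to unit diagonal with
#' [normalize_to_correlation()] so every object has the same prior quality
#' variance.
#'
#' @param N Number of objects.
#' @param df Degrees of freedom; must exceed `N + 1` so the mean is finite.
#'   Default `N + 2`, the smallest such integer.
#' @param seed Optional integer seed.
#' @return A `covariance_model` with unit diagonal.
#' @export
inverse_wishart_covariance <- function(N, df = N + 2, seed = NULL) {
  N <- check_n_objects(N)
  if (length(df) != 1L || !is.finite(df) || df <= N + 1) {
    abort("df must exceed N + 1 for a finite-mean inverse-Wishart draw")
  }
  if (!is.null(seed)) set.seed(seed)
  # if W ~ Wishart(df, I) then W^{-1} ~ inverse-Wishart(df, I)
  W <- rWishart(1, df, diag(N))[, , 1]
  C <- chol2inv(chol(W))
  out <- normalize_to_correlation(C)
  attr(out, "family") <- "inverse_wishart"
  attr(out, "params") <- list(df = df)
  attr(out, "seed") <- seed
  out
}

#' Matrix-exponential adjacency prior covariance
#'
#' `C = D^{-1/2} expm(A) D^{-1/2}` with `D = diag(expm(A))`: a spatial prior
#' that assigns higher covariance to pairs of nodes that are well connected
#' in the graph (walk-counting kernel), normalised to unit diagonal. The
#' matrix exponential is computed exactly through the symmetric
#' eigendecomposition of `A`.
#'
#' @param G A `graph_model`.
#' @return A `covariance_model` with unit diagonal.
#' @export
exp_adjacency_covariance <- function(G) {
  A <- G$A
  es <- eigen(A, symmetric = TRUE)
  Lambda <- es$vectors %*% (exp(es$values) * t(es$vectors))
  out <- normalize_to_correlation((Lambda + t(Lambda)) / 2)
  attr(out, "family") <- "exp_adjacency"
  attr(out, "params") <- list(p = G$p %||% NA_real_)
  attr(out, "seed") <- G$seed
  out
}

#' Rescale a covariance matrix to unit diagonal
#'
#' `C' = D^{-1/2} C D^{-1/2}` with `D = diag(C)`: converts a covariance to a
#' correlation-scaled matrix so all objects share the same prior variance.
#' Positive semidefiniteness and off-diagonal signs are preserved.
#'
#' @param C A symmetric matrix with strictly positive diagonal.
#' @return A `covariance_model` with unit diagonal.
#' @export
normalize_to_correlation <- function(C) {
  C <- as.matrix(C)
  d <- diag(C)
  if (any(d <= 0)) abort("normalisation requires a strictly positive diagonal")
  s <- 1 / sqrt(d)
  out <- C * tcrossprod(s)
  diag(out) <- 1
  as_covariance_model(out, family = "external", params = list())
}

`%||%` <- function(a, b) if (is.null(a)) b else a
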