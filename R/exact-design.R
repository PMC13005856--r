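#' Scheduling distributions
#'
#' A scheduling distribution is a probability distribution over the
#' `M = N(N-1)/2` unordered object pairs: each comparison in the study is
#' drawn independently from it. In this package it is a tibble of class
#' `bt_schedule` with columns `i`, `j` (object labels, `i < j`, ordered by
#' linear pair index) and `q` (the probability the pair is shown to a
#' judge), plus attributes `N` and `method`.
#'
#' @param q Numeric vector of `M` pair probabilities in linear-index order.
#' @param N Number of objects.
#' @param method Character tag ("standard", "rbd", ...).
#' @param meta Optional named list of extra metadata (tolerances, achieved
#'   reduced dimension, ...).
#' @return A `bt_schedule` tibble.
#' @export
new_schedule <- function(q, N, method = "standard", meta = list()) {
  N <- check_n_objects(N)
  M <- N * (N - 1L) / 2L
  if (length(q) != M) {
    abort(sprintf("expected %d pair probabilities for N = %d, got %d", M, N, length(q)))
  }
  if (any(q < -1e-12)) abort("scheduling probabilities must be nonnegative")
  q <- pmax(q, 0)
  if (abs(sum(q) - 1) > 1e-12) {
    abort(sprintf("scheduling probabilities must sum to 1 (got %.15g)", sum(q)))
  }
  out <- pair_grid(N)
  out$q <- as.numeric(q)
  tibble::new_tibble(out,
    N = N, method = method, meta = meta,
    class = "bt_schedule"
  )
}

#' @export
print.bt_schedule <- function(x, ...) {
  cat(sprintf(
    "# Scheduling distribution over %d pairs of %d objects (method: %s)\n",
    nrow(x), attr(x, "N"), attr(x, "method")
  ))
  NextMethod()
}

schedule_n_objects <- function(S) {
  N <- attr(S, "N")
  if (is.null(N)) {
    # reconstruct from the pair count of a plain i/j/q data frame
    M <- nrow(S)
    N <- as.integer(round((1 + sqrt(1 + 8 * M)) / 2))
    if (N * (N - 1) / 2 != M) abort("row count is not a valid pair count N(N-1)/2")
  }
  as.integer(N)
}

#' Pairs-of-pairs covariance matrix
#'
#' Forms the dense `M x M` covariance matrix `Delta = E C E'` of all prior
#' pairwise quality differences, where `E` is the sparse difference
#' operator. Entry for pairs `(i,j)` and `(k,l)` equals
#' `C[i,k] - C[i,l] - C[j,k] + C[j,l]`. Memory grows as `N^4`; for large
#' studies use [rbd_scheduling()], which never forms this matrix.
#'
#' @param C An `N x N` prior covariance matrix (a `covariance_model` or any
#'   symmetric matrix).
#' @param max_n Guard on `N` (default 300) against accidental `O(N^4)`
#'   memory blowups.
#' @return A dense symmetric `M x M` matrix.
#' @export
#' @examples
#' build_delta(toeplitz_covariance(3, 0.5))
build_delta <- function(C, max_n = 300) {
  C <- as_covariance_model(C, family = attr(C, "family") %||% "external")
  N <- nrow(C)
  if (N > max_n) {
    abort(sprintf(paste0(
      "N = %d exceeds the dense-Delta guard (%d): Delta would need O(N^4) ",
      "memory. Use rbd_scheduling(), which never forms Delta."
    ), N, max_n))
  }
  E <- build_difference_operator(N)
  Delta <- as.matrix(E %*% unclass_cov(C) %*% Matrix::t(E))
  (Delta + t(Delta)) / 2
}

#' Prior mean differences for all pairs
#'
#' The companion of [build_delta()]: the vector of prior mean differences
#' `mu[i] - mu[j]` for every pair in linear-index order. It is part of the
#' distribution of pairwise differences but plays no role in design
#' construction, which depends on `Delta` alone.
#'
#' @param mu Length-`N` prior mean vector.
#' @return A numeric vector of length `M`.
#' @export
pair_mean_differences <- function(mu) {
  N <- length(mu)
  check_n_objects(N)
  pg <- pair_grid(N)
  mu[pg$i] - mu[pg$j]
}

#' Scheduling distribution from a spectral decomposition of Delta
#'
#' Implements the principal-component design: decompose
#' `Delta = U Psi U'`, then give pair `r` probability
#' `q_r = sum_c (U[r,c])^2 psi_c / sum_d psi_d`, so pairs contributing more
#' prior variance are compared more often. Eigenvalues are clipped at zero
#' (`Delta` is positive semidefinite; small negative values are numerical
#' noise).
#'
#' @param Delta A symmetric positive semidefinite `M x M` matrix from
#'   [build_delta()].
#' @return A `bt_schedule`.
#' @export
spectral_scheduling <- function(Delta) {
  Delta <- as.matrix(Delta)
  M <- nrow(Delta)
  N <- as.integer(round((1 + sqrt(1 + 8 * M)) / 2))
  if (N * (N - 1) / 2 != M) abort("Delta dimension is not a valid pair count N(N-1)/2")
  es <- eigen(Delta, symmetric = TRUE)
  psi <- pmax(es$values, 0)
  total <- sum(psi)
  if (total <= M * .Machine$double.eps * max(abs(Delta))) {
    abort("degenerate prior: all quality differences have zero prior variance")
  }
  q <- as.vector((es$vectors^2) %*% psi) / total
  new_schedule(q / sum(q), N, method = "standard")
}

#' Standard (exact) scheduling distribution
#'
#' The full-matrix route: build `Delta = E C E'` and apply
#' [spectral_scheduling()]. Exact but `O(N^4)` in memory and roughly
#' `O(N^6)` in time; [rbd_scheduling()] reproduces it at a fraction of the
#' cost.
#'
#' @inheritParams build_delta
#' @return A `bt_schedule`.
#' @export
#' @examples
#' standard_scheduling(toeplitz_covariance(3, 0.5))
standard_scheduling <- function(C, max_n = 300) {
  spectral_scheduling(build_delta(C, max_n = max_n))
}
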