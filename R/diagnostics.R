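#' Kullback-Leibler divergence between two scheduling distributions
#'
#' `KL(S || S~) = sum_r S_r log(S_r / S~_r)` in nats, over the shared pair
#' index. Terms with `S_r = 0` contribute zero; a pair with `S_r > 0` but
#' `S~_r = 0` makes the divergence infinite (reported, not an error). Used
#' to quantify how well the reduced-basis design approximates the exact
#' one.
#'
#' @param S,Stilde Two `bt_schedule` objects (or plain `i, j, q` data
#'   frames) over the same number of objects, or two bare probability
#'   vectors of equal length.
#' @return A one-row tibble with columns `kl` (nats), `max_abs_diff`,
#'   `n_pairs`.
#' @export
#' @examples
#' S <- standard_scheduling(toeplitz_covariance(5))
#' St <- rbd_scheduling(toeplitz_covariance(5))
#' kl_divergence(S, St)
kl_divergence <- function(S, Stilde) {
  p <- if (is.numeric(S)) S else S$q
  q <- if (is.numeric(Stilde)) Stilde else Stilde$q
  if (is.null(p) || is.null(q)) abort("inputs must be schedules or probability vectors")
  if (length(p) != length(q)) abort("schedules are over different numbers of pairs")
  if (abs(sum(p) - 1) > 1e-8 || abs(sum(q) - 1) > 1e-8 || any(p < 0) || any(q < 0)) {
    abort("inputs must be probability distributions")
  }
  pos <- p > 0
  kl <- if (any(pos & q == 0)) {
    Inf
  } else {
    # clip round-off negatives: the divergence is nonnegative by Gibbs
    max(sum(p[pos] * log(p[pos] / q[pos])), 0)
  }
  tibble::tibble(
    kl = kl,
    max_abs_diff = max(abs(p - q)),
    n_pairs = length(p)
  )
}

#' Predicted rank of the pairs-of-pairs covariance
#'
#' The rank of `Delta = E C E'` is determined by `C` alone: it equals
#' `rank(C) - 1` when the all-ones vector lies in `range(C)` (the constant
#' direction is the null space of `E`), and `rank(C)` otherwise. In
#' particular a full-rank `C` always gives `rank(Delta) = N - 1`.
#' Numerical rank counts eigenvalues above
#' `N * eps_machine * max(eigenvalue)`; membership of the ones vector in
#' `range(C)` is decided by the relative residual of its projection onto
#' the retained eigenvectors.
#'
#' @param C A symmetric positive semidefinite matrix.
#' @param tol Relative residual threshold for range membership (default
#'   `1e-8`).
#' @return Integer: the predicted rank of `Delta`.
#' @export
delta_rank <- function(C, tol = 1e-8) {
  C <- as.matrix(C)
  N <- nrow(C)
  # SVD rather than a symmetric eigensolver: its trailing singular values
  # carry less noise, which matters right at the rank threshold
  sv <- svd((C + t(C)) / 2)
  thresh <- N * .Machine$double.eps * max(sv$d, 0)
  keep <- sv$d > thresh
  rank_C <- sum(keep)
  if (rank_C == 0L) return(0L)
  ones <- rep(1, N)
  U <- sv$u[, keep, drop = FALSE]
  resid <- ones - U %*% crossprod(U, ones)
  ones_in_range <- sqrt(sum(resid^2)) / sqrt(N) <= tol
  as.integer(if (ones_in_range) rank_C - 1L else rank_C)
}

#' Check eigenvalue interlacing of the reduced design
#'
#' Verifies the interlacing guarantee
#' `alpha[i + N - d] <= sigma[i] <= alpha[i]` (for `i = 1..d`) relating the
#' `d` reduced-model eigenvalues `sigma` to the exact eigenvalues `alpha`
#' of `Delta`, within an absolute slack.
#'
#' @param alpha Exact eigenvalues of `Delta`, sorted non-increasing, length
#'   `M`.
#' @param sigma Reduced eigenvalues, sorted non-increasing, length `d`.
#' @param N Number of objects.
#' @param d Reduced dimension (defaults to `length(sigma)`).
#' @param slack Absolute tolerance (default `1e-10`).
#' @return A one-row tibble with `pass` (logical), `worst_upper` and
#'   `worst_lower` (most negative margins of `alpha_i - sigma_i` and
#'   `sigma_i - alpha_{i+N-d}`), `n_checked`.
#' @export
check_interlacing <- function(alpha, sigma, N, d = length(sigma), slack = 1e-10) {
  if (is.unsorted(rev(alpha), strictly = FALSE)) abort("alpha must be sorted non-increasing")
  if (is.unsorted(rev(sigma), strictly = FALSE)) abort("sigma must be sorted non-increasing")
  M <- length(alpha)
  if (M != N * (N - 1) / 2) abort("alpha must contain all M = N(N-1)/2 eigenvalues")
  i <- seq_len(d)
  upper <- alpha[i] - sigma            # must be >= -slack
  low_idx <- i + N - d
  lower <- sigma - ifelse(low_idx <= M, alpha[low_idx], 0)  # must be >= -slack
  tibble::tibble(
    pass = all(upper >= -slack) && all(lower >= -slack),
    worst_upper = min(upper),
    worst_lower = min(lower),
    n_checked = d
  )
}
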