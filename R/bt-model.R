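#' Bradley-Terry win probability
#'
#' The probability that object `i` (quality `lambda_i`) is judged better
#' than object `j`: `p_ij = exp(l_i) / (exp(l_i) + exp(l_j))`, evaluated as
#' the logistic of the difference for overflow safety.
#'
#' @param lambda_i,lambda_j Quality parameters (log scale); vectorised.
#' @return Probabilities in `(0, 1)` with `p_ij + p_ji = 1`.
#' @export
#' @examples
#' bt_probability(1, 0) # ~ 0.731
bt_probability <- function(lambda_i, lambda_j) {
  plogis(lambda_i - lambda_j)
}

#' Aggregated comparison data
#'
#' Comparison outcomes aggregated per unordered pair: `wins_i` of the
#' `total` comparisons of pair `(i, j)` were won by object `i`.
#'
#' @param data A data frame with columns `i`, `j`, `wins_i`, `total`
#'   (aggregated) or `left`, `right`, `winner` (long format, one row per
#'   judgement, aggregated on construction).
#' @param N Number of objects; defaults to the largest label seen.
#' @return A tibble of class `bt_comparisons` with columns `i`, `j`
#'   (`i < j`), `wins_i`, `total`, and attribute `N`.
#' @export
as_comparisons <- function(data, N = NULL) {
  data <- as.data.frame(data)
  if (all(c("left", "right", "winner") %in% names(data))) {
    if (!all(data$winner == data$left | data$winner == data$right)) {
      abort("each winner must be one of the two objects compared")
    }
    i <- pmin(data$left, data$right)
    j <- pmax(data$left, data$right)
    agg <- dplyr::summarise(
      dplyr::group_by(
        tibble::tibble(i = i, j = j, win_i = as.integer(data$winner == i)),
        .data$i, .data$j
      ),
      wins_i = sum(.data$win_i), total = dplyr::n(), .groups = "drop"
    )
    data <- as.data.frame(agg)
  }
  if (!all(c("i", "j", "wins_i", "total") %in% names(data))) {
    abort("expected columns i, j, wins_i, total (or long-format left, right, winner)")
  }
  if (any(data$i == data$j)) abort("a pair must contain two distinct objects")
  swap <- data$i > data$j
  if (any(swap)) {
    wins_j <- data$total[swap] - data$wins_i[swap]
    tmp <- data$i[swap]; data$i[swap] <- data$j[swap]; data$j[swap] <- tmp
    data$wins_i[swap] <- wins_j
  }
  data <- dplyr::summarise(
    dplyr::group_by(tibble::as_tibble(data), .data$i, .data$j),
    wins_i = sum(.data$wins_i), total = sum(.data$total), .groups = "drop"
  )
  if (any(data$wins_i < 0 | data$wins_i > data$total)) {
    abort("wins_i must lie in 0..total for every pair")
  }
  N <- as.integer(N %||% max(data$j, 2L))
  if (nrow(data) && max(data$j) > N) abort("object label exceeds N")
  data <- dplyr::arrange(data, .data$i, .data$j)
  tibble::new_tibble(data, N = N, class = "bt_comparisons")
}

#' Empty comparison data
#'
#' @param N Number of objects.
#' @return A `bt_comparisons` tibble with zero rows.
#' @export
empty_comparisons <- function(N) {
  tibble::new_tibble(
    tibble::tibble(
      i = integer(0), j = integer(0),
      wins_i = integer(0), total = integer(0)
    ),
    N = check_n_objects(N), class = "bt_comparisons"
  )
}

#' Bradley-Terry log posterior
#'
#' Binomial log likelihood of the aggregated comparisons plus the
#' multivariate normal log prior density `MVN(mu, C)`, up to an additive
#' constant in `lambda`. Binomial coefficients (constant in `lambda`) are
#' included when `include_const = TRUE`.
#'
#' @param lambda Length-`N` quality vector.
#' @param D A `bt_comparisons` object.
#' @param mu Length-`N` prior mean (default zero).
#' @param C `N x N` positive definite prior covariance.
#' @param include_const Include the binomial coefficients and MVN
#'   normalising constant (default `FALSE`; they do not affect the mode).
#' @return A scalar log density (up to a constant when
#'   `include_const = FALSE`).
#' @export
log_posterior <- function(lambda, D, mu = NULL, C, include_const = FALSE) {
  N <- attr(D, "N")
  if (length(lambda) != N) abort("lambda length must equal the object count")
  C <- as.matrix(C)
  if (nrow(C) != N) abort("prior covariance dimension must equal the object count")
  mu <- mu %||% rep(0, N)
  ll <- 0
  if (nrow(D)) {
    eta <- lambda[D$i] - lambda[D$j]
    ll <- sum(D$wins_i * plogis(eta, log.p = TRUE) +
                (D$total - D$wins_i) * plogis(-eta, log.p = TRUE))
    if (include_const) ll <- ll + sum(lchoose(D$total, D$wins_i))
  }
  ch <- tryCatch(chol(C), error = function(e) abort("prior covariance is not positive definite"))
  z <- backsolve(ch, lambda - mu, transpose = TRUE)
  lp <- -0.5 * sum(z^2)
  if (include_const) {
    lp <- lp - sum(log(diag(ch))) - N / 2 * log(2 * pi)
  }
  ll + lp
}

bt_gradient_hessian <- function(lambda, D, mu, Cinv) {
  N <- length(lambda)
  g <- -Cinv %*% (lambda - mu)
  H <- -Cinv
  if (nrow(D)) {
    eta <- lambda[D$i] - lambda[D$j]
    p <- plogis(eta)
    resid <- D$wins_i - D$total * p
    w <- D$total * p * (1 - p)
    g_lik <- numeric(N)
    g_lik[seq_len(N)] <- 0
    for (k in seq_len(nrow(D))) {
      ik <- D$i[k]; jk <- D$j[k]
      g_lik[ik] <- g_lik[ik] + resid[k]
      g_lik[jk] <- g_lik[jk] - resid[k]
      H[ik, ik] <- H[ik, ik] - w[k]
      H[jk, jk] <- H[jk, jk] - w[k]
      H[ik, jk] <- H[ik, jk] + w[k]
      H[jk, ik] <- H[jk, ik] + w[k]
    }
    g <- g + g_lik
  }
  list(g = as.numeric(g), H = H)
}

#' Bayesian MAP fit of the Bradley-Terry model
#'
#' Newton ascent to the mode of the posterior formed by the binomial
#' Bradley-Terry likelihood and a `MVN(mu, C)` prior. The log posterior is
#' strictly concave for a positive definite prior, so the mode is unique;
#' the returned covariance is the Laplace approximation, i.e. the inverse
#' negative Hessian at the mode. The likelihood itself is invariant to
#' adding a constant to every quality — identifiability comes entirely from
#' the prior. With no data the fit returns the prior (`lambda_hat = mu`,
#' `post_cov = C`) exactly.
#'
#' @param D A `bt_comparisons` object (possibly empty).
#' @param mu Length-`N` prior mean (default zero).
#' @param C `N x N` positive definite prior covariance.
#' @param tol Convergence tolerance on the gradient max-norm (default
#'   `1e-8`).
#' @param max_iter Newton iteration cap (default 100). Non-convergence is
#'   flagged, not an error.
#' @return An object of class `bt_fit`: list with `lambda_hat`, `post_cov`
#'   (Laplace posterior covariance, ready to serve as the next-phase design
#'   prior), `converged`, `iterations`, `gradient_norm`, `log_posterior`,
#'   `N`, `mu`, `prior_cov`.
#' @export
fit_bt_map <- function(D, mu = NULL, C, tol = 1e-8, max_iter = 100) {
  N <- attr(D, "N")
  C <- as.matrix(C)
  if (nrow(C) != N) abort("prior covariance dimension must equal the object count")
  mu <- mu %||% rep(0, N)
  if (nrow(D) == 0L) {
    return(structure(
      list(
        lambda_hat = mu, post_cov = C, converged = TRUE, iterations = 0L,
        gradient_norm = 0, log_posterior = log_posterior(mu, D, mu, C),
        N = N, mu = mu, prior_cov = C
      ),
      class = "bt_fit"
    ))
  }
  Cinv <- chol2inv(chol(C))
  lambda <- mu
  converged <- FALSE
  it <- 0L
  gnorm <- Inf
  while (it < max_iter) {
    it <- it + 1L
    gh <- bt_gradient_hessian(lambda, D, mu, Cinv)
    gnorm <- max(abs(gh$g))
    if (gnorm <= tol) {
      converged <- TRUE
      break
    }
    step <- solve(-gh$H, gh$g)
    # halve the step until the posterior does not decrease
    f0 <- log_posterior(lambda, D, mu, C)
    alpha <- 1
    repeat {
      cand <- lambda + alpha * step
      if (log_posterior(cand, D, mu, C) >= f0 - 1e-12 || alpha < 1e-8) break
      alpha <- alpha / 2
    }
    lambda <- cand
  }
  gh <- bt_gradient_hessian(lambda, D, mu, Cinv)
  gnorm <- max(abs(gh$g))
  if (gnorm <= tol) converged <- TRUE
  post_cov <- chol2inv(chol(-gh$H))
  structure(
    list(
      lambda_hat = as.numeric(lambda), post_cov = (post_cov + t(post_cov)) / 2,
      converged = converged, iterations = it, gradient_norm = gnorm,
      log_posterior = log_posterior(lambda, D, mu, C, include_const = TRUE),
      N = N, mu = mu, prior_cov = C
    ),
    class = "bt_fit"
  )
}

#' @export
print.bt_fit <- function(x, ...) {
  cat(sprintf(
    "<bt_fit> %d objects, %s in %d Newton iteration(s), |grad| = %.2g\n",
    x$N, if (x$converged) "converged" else "NOT converged", x$iterations,
    x$gradient_norm
  ))
  invisible(x)
}

#' Tidy a Bradley-Terry MAP fit
#'
#' @param x A `bt_fit`.
#' @param ... Unused.
#' @return A tibble with one row per object: `object`, `estimate` (posterior
#'   mode of the quality), `std_error` (Laplace posterior sd), `rank`
#'   (1 = highest estimated quality).
#' @method tidy bt_fit
#' @export
tidy.bt_fit <- function(x, ...) {
  tibble::tibble(
    object = seq_len(x$N),
    estimate = x$lambda_hat,
    std_error = sqrt(diag(x$post_cov)),
    rank = rank(-x$lambda_hat, ties.method = "min")
  )
}

#' One-row summary of a Bradley-Terry MAP fit
#'
#' @param x A `bt_fit`.
#' @param ... Unused.
#' @return A one-row tibble: `n_objects`, `converged`, `iterations`,
#'   `gradient_norm`, `log_posterior`.
#' @method glance bt_fit
#' @export
glance.bt_fit <- function(x, ...) {
  tibble::tibble(
    n_objects = x$N,
    converged = x$converged,
    iterations = x$iterations,
    gradient_norm = x$gradient_norm,
    log_posterior = x$log_posterior
  )
}

#' Simulate comparisons under a scheduling distribution
#'
#' Draws `n_total` comparisons: pairs are sampled i.i.d. from the
#' scheduling distribution, and each comparison of pair `(i, j)` is won by
#' `i` with Bradley-Terry probability `plogis(lambda_i - lambda_j)`. Pairs
#' with zero scheduling probability never appear.
#'
#' @param lambda_true Length-`N` vector of true qualities.
#' @param S A `bt_schedule`.
#' @param n_total Total number of comparisons.
#' @param seed Optional integer seed.
#' @return A `bt_comparisons` tibble with `sum(total) == n_total`.
#' @export
simulate_comparisons <- function(lambda_true, S, n_total, seed = NULL) {
  N <- schedule_n_objects(S)
  if (length(lambda_true) != N) abort("lambda_true length must match the schedule")
  if (n_total < 0) abort("n_total must be nonnegative")
  if (!is.null(seed)) set.seed(seed)
  if (n_total == 0) return(empty_comparisons(N))
  counts <- as.integer(rmultinom(1, n_total, S$q))
  used <- which(counts > 0)
  p_win <- bt_probability(lambda_true[S$i[used]], lambda_true[S$j[used]])
  wins <- rbinom(length(used), counts[used], p_win)
  as_comparisons(
    tibble::tibble(
      i = S$i[used], j = S$j[used],
      wins_i = wins, total = counts[used]
    ),
    N = N
  )
}

#' Two-phase design update
#'
#' The sequential workflow: fit the Bradley-Terry model to first-phase
#' comparisons under a `MVN(mu, C0)` prior, take the Laplace posterior
#' covariance as the prior covariance for the second phase, and build the
#' second-phase scheduling distribution from it with the reduced-basis
#' method. Pairs whose ordering the first phase already resolved receive
#' relatively less probability than under the prior design.
#'
#' @param D_phase1 First-phase `bt_comparisons` (may be empty, in which
#'   case the design is built from `C0` itself).
#' @param mu Prior mean (default zero).
#' @param C0 First-phase prior covariance.
#' @param eps_R,d_max Passed to [rbd_scheduling()].
#' @return A `bt_schedule` for the second phase; the fitted `bt_fit` is
#'   attached as attribute `fit`.
#' @export
two_phase_schedule <- function(D_phase1, mu = NULL, C0, eps_R = 1e-6,
                               d_max = NULL) {
  fit <- fit_bt_map(D_phase1, mu = mu, C = C0)
  S2 <- rbd_scheduling(fit$post_cov, eps_R = eps_R, d_max = d_max)
  attr(S2, "fit") <- fit
  S2
}
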