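test_that("win probabilities follow the logistic of the quality difference", {
  expect_equal(bt_probability(0, 0), 0.5)
  expect_equal(bt_probability(1, 0), exp(1) / (1 + exp(1)), tolerance = 1e-12)
  expect_equal(bt_probability(0, 1), 1 - bt_probability(1, 0), tolerance = 1e-12)
  # overflow safety at extreme qualities
  expect_equal(bt_probability(1000, 0), 1)
  expect_equal(bt_probability(-1000, 0), 0)
})

test_that("comparison data aggregates long-format judgements per unordered pair", {
  long <- data.frame(
    left = c(1, 2, 1, 3, 2),
    right = c(2, 1, 2, 1, 3),
    winner = c(1, 2, 2, 3, 2)
  )
  D <- as_comparisons(long)
  expect_equal(nrow(D), 3L) # pairs (1,2), (1,3), (2,3)
  r12 <- D[D$i == 1 & D$j == 2, ]
  expect_equal(r12$total, 3L)
  expect_equal(r12$wins_i, 1L) # object 1 won once of three
  r13 <- D[D$i == 1 & D$j == 3, ]
  expect_equal(r13$wins_i, 0L) # object 3 won their only meeting
  expect_error(as_comparisons(data.frame(left = 1, right = 2, winner = 3)), "winner")
  expect_error(
    as_comparisons(data.frame(i = 1, j = 1, wins_i = 0, total = 1)),
    "distinct"
  )
})

test_that("the log posterior reduces to its pieces in edge cases", {
  N <- 3
  C <- diag(N)
  D0 <- empty_comparisons(N)
  # empty data: pure MVN log density, maximised at mu
  mu <- c(0.3, -0.2, 0.1)
  expect_gt(
    log_posterior(mu, D0, mu, C),
    log_posterior(mu + c(0.1, 0, 0), D0, mu, C)
  )
  expect_equal(log_posterior(rep(0, N), D0, rep(0, N), C), 0)
  # one comparison between equal qualities: likelihood term log(1/2)
  D1 <- as_comparisons(data.frame(i = 1, j = 2, wins_i = 1, total = 1), N = N)
  expect_equal(
    log_posterior(rep(0, N), D1, rep(0, N), C) -
      log_posterior(rep(0, N), D0, rep(0, N), C),
    log(0.5),
    tolerance = 1e-12
  )
})

test_that("the log posterior matches a naive term-by-term oracle", {
  set.seed(99)
  N <- 3
  D <- as_comparisons(data.frame(
    i = c(1, 1, 2), j = c(2, 3, 3),
    wins_i = c(3, 1, 0), total = c(5, 2, 4)
  ), N = N)
  C <- random_psd(N) + diag(N)
  mu <- rnorm(N)
  lambda <- rnorm(N)
  # naive: binomial pmf per pair plus MVN density, all via dbinom/chol
  naive <- sum(mapply(function(i, j, y, n) {
    p <- exp(lambda[i]) / (exp(lambda[i]) + exp(lambda[j]))
    stats::dbinom(y, n, p, log = TRUE)
  }, D$i, D$j, D$wins_i, D$total)) +
    as.numeric(-0.5 * t(lambda - mu) %*% solve(C, lambda - mu)) -
    0.5 * log(det(2 * pi * C))
  expect_equal(log_posterior(lambda, D, mu, C, include_const = TRUE), naive,
    tolerance = 1e-10
  )
})

test_that("the likelihood is invariant to a constant quality shift", {
  D <- as_comparisons(data.frame(
    i = c(1, 2), j = c(2, 3), wins_i = c(2, 1), total = c(3, 2)
  ), N = 3)
  C <- diag(3)
  lambda <- c(0.5, -0.3, 0.2)
  # difference of two log posteriors with a flat-ish prior isolates the likelihood
  big <- as_covariance_model(1e6 * diag(3))
  expect_equal(
    log_posterior(lambda, D, rep(0, 3), big),
    log_posterior(lambda + 5, D, rep(5, 3), big),
    tolerance = 1e-8
  )
})

test_that("MAP fitting recovers symmetry, the prior, and a small gradient", {
  N <- 4
  C <- diag(N)
  # perfectly balanced data: mode at zero
  pg <- pair_grid(N)
  Dbal <- as_comparisons(
    data.frame(i = pg$i, j = pg$j, wins_i = 2, total = 4),
    N = N
  )
  fit <- fit_bt_map(Dbal, C = C)
  expect_true(fit$converged)
  expect_equal(fit$lambda_hat, rep(0, N), tolerance = 1e-8)
  expect_lte(fit$gradient_norm, 1e-8)
  expect_equal(fit$post_cov, t(fit$post_cov))
  expect_true(all(eigen(fit$post_cov, symmetric = TRUE, only.values = TRUE)$values > 0))

  # no data: exact prior recovery
  fit0 <- fit_bt_map(empty_comparisons(N), mu = c(1, 2, 3, 4), C = 2 * diag(N))
  expect_identical(fit0$lambda_hat, c(1, 2, 3, 4))
  expect_identical(fit0$post_cov, 2 * diag(N))
  expect_equal(fit0$iterations, 0L)
})

test_that("tidy and glance summarise a fit", {
  D <- as_comparisons(data.frame(
    i = c(1, 1, 2), j = c(2, 3, 3),
    wins_i = c(5, 4, 3), total = c(5, 5, 5)
  ), N = 3)
  fit <- fit_bt_map(D, C = 25 * diag(3))
  td <- tidy(fit)
  expect_named(td, c("object", "estimate", "std_error", "rank"))
  expect_equal(td$rank[1], 1L) # object 1 won everything
  gl <- glance(fit)
  expect_true(gl$converged)
  expect_equal(gl$n_objects, 3)
})

test_that("simulated comparisons respect the schedule and the truth", {
  N <- 5
  S <- standard_scheduling(as_covariance_model(diag(N)))
  expect_equal(nrow(simulate_comparisons(rep(0, N), S, 0)), 0L)

  # all scheduling mass on one pair
  q <- rep(0, n_pairs(N)); q[3] <- 1
  Sdeg <- new_schedule(q, N)
  Ddeg <- simulate_comparisons(rep(0, N), Sdeg, 50, seed = 1)
  expect_equal(nrow(Ddeg), 1L)
  expect_equal(Ddeg$total, 50L)
  expect_equal(c(Ddeg$i, Ddeg$j), c(index_to_pair(3, N)$i, index_to_pair(3, N)$j))

  # equal qualities: pooled win rate near 1/2 by the CLT
  D <- simulate_comparisons(rep(0, N), S, 1e4, seed = 42)
  expect_equal(sum(D$total), 1e4)
  frac <- sum(D$wins_i) / sum(D$total)
  expect_lt(abs(frac - 0.5), 3 * sqrt(0.25 / 1e4))
  # reproducible under the seed
  D2 <- simulate_comparisons(rep(0, N), S, 1e4, seed = 42)
  expect_identical(as.data.frame(D), as.data.frame(D2))
})

test_that("quality recovery improves with the number of comparisons", {
  set.seed(1234)
  N <- 12
  C <- toeplitz_covariance(N, 0.5)
  S <- rbd_scheduling(C)
  cors <- function(n_total, reps) {
    vapply(seq_len(reps), function(r) {
      lambda <- as.vector(t(chol(as.matrix(C))) %*% rnorm(N))
      D <- simulate_comparisons(lambda, S, n_total)
      fit <- fit_bt_map(D, C = as.matrix(C))
      cor(fit$lambda_hat, lambda)
    }, numeric(1))
  }
  lo <- mean(cors(5 * N, 15))
  hi <- mean(cors(50 * N, 15))
  expect_gt(hi, lo)
})

test_that("two-phase scheduling downweights pairs the first phase resolved", {
  N <- 5
  C0 <- as_covariance_model(25 * diag(N))
  # no phase-1 data: the design is the prior design (uniform for identity pattern)
  S0 <- two_phase_schedule(empty_comparisons(N), C0 = C0)
  expect_equal(S0$q, rep(1 / n_pairs(N), n_pairs(N)), tolerance = 1e-10)

  # heavy comparison of pair (1,2) shrinks its posterior difference variance
  D <- as_comparisons(
    data.frame(i = 1, j = 2, wins_i = 25, total = 50),
    N = N
  )
  S2 <- two_phase_schedule(D, C0 = C0)
  expect_lt(S2$q[1], S0$q[1])
  expect_equal(sum(S2$q), 1, tolerance = 1e-12)
  fit <- attr(S2, "fit")
  expect_s3_class(fit, "bt_fit")
  expect_true(fit$converged)
})
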