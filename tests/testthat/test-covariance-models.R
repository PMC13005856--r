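test_that("Erdos-Renyi graphs hit the degenerate and complete extremes", {
  g0 <- erdos_renyi_adjacency(5, 0, seed = 1)
  expect_equal(g0$A, matrix(0, 5, 5))
  g1 <- erdos_renyi_adjacency(5, 1, seed = 1)
  expect_equal(g1$A, matrix(1, 5, 5) - diag(5))
  expect_equal(diag(g1$D), rowSums(g1$A))
  expect_error(erdos_renyi_adjacency(5, 1.2), "\\[0, 1\\]")
})

test_that("Erdos-Renyi edge count matches the binomial mean", {
  edges <- vapply(
    1:1000,
    function(s) sum(erdos_renyi_adjacency(8, 0.5, seed = s)$A) / 2,
    numeric(1)
  )
  se <- sqrt(28 * 0.25 / 1000)
  expect_lt(abs(mean(edges) - 14), 3 * se)
})

test_that("graph generation is reproducible under a fixed seed", {
  expect_identical(
    erdos_renyi_adjacency(12, 0.4, seed = 7)$A,
    erdos_renyi_adjacency(12, 0.4, seed = 7)$A
  )
  C1 <- inverse_wishart_covariance(6, seed = 11)
  C2 <- inverse_wishart_covariance(6, seed = 11)
  expect_identical(unclass(C1), unclass(C2))
})

test_that("Laplacian covariance inverts D - A + I", {
  # empty graph: identity
  g <- erdos_renyi_adjacency(4, 0, seed = 1)
  expect_equal(unclass(laplacian_covariance(g))[, ], diag(4),
    tolerance = 1e-12, ignore_attr = TRUE
  )
  # two nodes, one edge: invert [[2,-1],[-1,2]] by hand
  g2 <- list(N = 2, A = matrix(c(0, 1, 1, 0), 2), D = diag(c(1, 1)), p = 1, seed = NULL)
  expect_equal(as.matrix(laplacian_covariance(g2)),
    matrix(c(2, 1, 1, 2), 2) / 3,
    tolerance = 1e-12, ignore_attr = TRUE
  )
  # D - A + I >= I so the smallest eigenvalue of C^{-1} is at least 1
  for (s in 1:5) {
    C <- laplacian_covariance(erdos_renyi_adjacency(8, 0.5, seed = s))
    ev <- eigen(solve(as.matrix(C)), symmetric = TRUE, only.values = TRUE)$values
    expect_gte(min(ev), 1 - 1e-10)
  }
})

test_that("Laplacian covariance exists for disconnected graphs", {
  g <- erdos_renyi_adjacency(10, 0.05, seed = 3) # very sparse, likely disconnected
  C <- laplacian_covariance(g)
  ev <- eigen(as.matrix(C), symmetric = TRUE, only.values = TRUE)$values
  expect_true(all(ev > 0))
})

test_that("Toeplitz covariance matches rho^|i-j| and its AR(1) determinant", {
  C <- toeplitz_covariance(3, 0.5)
  expect_equal(as.matrix(C),
    rbind(c(1, .5, .25), c(.5, 1, .5), c(.25, .5, 1)),
    ignore_attr = TRUE
  )
  expect_equal(as.matrix(toeplitz_covariance(4, 0)), diag(4), ignore_attr = TRUE)
  expect_equal(det(as.matrix(toeplitz_covariance(6, 0.5))), (1 - 0.25)^5,
    tolerance = 1e-12
  )
  expect_error(toeplitz_covariance(4, 1), "rho")
})

test_that("inverse-Wishart draws are unit-diagonal, PD, and concentrate at large df", {
  C <- inverse_wishart_covariance(5, seed = 2)
  expect_equal(diag(as.matrix(C)), rep(1, 5), tolerance = 1e-12)
  ev <- eigen(as.matrix(C), symmetric = TRUE, only.values = TRUE)$values
  expect_true(all(ev > 0))
  expect_error(inverse_wishart_covariance(5, df = 6), "df")

  offs <- vapply(1:500, function(s) {
    M <- as.matrix(inverse_wishart_covariance(4, df = 100, seed = s))
    mean(abs(M[upper.tri(M)]))
  }, numeric(1))
  expect_lt(mean(offs), 0.2)
})

test_that("matrix-exponential adjacency covariance is a correlation kernel", {
  g0 <- erdos_renyi_adjacency(5, 0, seed = 1)
  expect_equal(as.matrix(exp_adjacency_covariance(g0)), diag(5),
    tolerance = 1e-12, ignore_attr = TRUE
  )
  g2 <- list(N = 2, A = matrix(c(0, 1, 1, 0), 2), D = diag(c(1, 1)), p = 1, seed = NULL)
  expect_equal(exp_adjacency_covariance(g2)[1, 2], tanh(1), tolerance = 1e-12)

  C <- exp_adjacency_covariance(erdos_renyi_adjacency(10, 0.4, seed = 5))
  expect_equal(diag(as.matrix(C)), rep(1, 10), tolerance = 1e-12)
  expect_true(all(abs(as.matrix(C)) <= 1 + 1e-12))
})

test_that("correlation normalisation is idempotent and rescales off-diagonals", {
  C <- matrix(c(4, 3, 3, 9), 2)
  Cn <- normalize_to_correlation(C)
  expect_equal(Cn[1, 2], 0.5)
  expect_equal(diag(as.matrix(Cn)), c(1, 1))
  expect_equal(as.matrix(normalize_to_correlation(Cn)), as.matrix(Cn),
    ignore_attr = TRUE
  )
  expect_equal(as.matrix(normalize_to_correlation(diag(3))), diag(3),
    ignore_attr = TRUE
  )
  expect_error(normalize_to_correlation(matrix(c(0, 0, 0, 1), 2)), "diagonal")
})

test_that("every generated covariance satisfies the model invariants", {
  models <- list(
    laplacian_covariance(erdos_renyi_adjacency(12, 0.5, seed = 1)),
    toeplitz_covariance(12, 0.5),
    inverse_wishart_covariance(12, seed = 1),
    exp_adjacency_covariance(erdos_renyi_adjacency(12, 0.5, seed = 2))
  )
  for (C in models) {
    M <- as.matrix(C)
    expect_equal(M, t(M), tolerance = 1e-12)
    ev <- eigen(M, symmetric = TRUE, only.values = TRUE)$values
    expect_gte(min(ev), -1e-10 * max(ev))
  }
})

test_that("gross asymmetry is rejected by the constructor", {
  M <- diag(3)
  M[1, 2] <- 0.5
  expect_error(as_covariance_model(M), "symmetric")
})
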