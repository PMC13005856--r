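test_that("the greedy basis is orthonormal with T = Y'E", {
  for (N in c(4, 9, 16)) {
    E <- build_difference_operator(N)
    B <- rbd(E, eps_R = 1e-6)
    expect_equal(crossprod(B$Y), diag(B$d), tolerance = 1e-10, ignore_attr = TRUE)
    expect_equal(B$T, as.matrix(Matrix::crossprod(E, B$Y)) |> t(),
      tolerance = 1e-10, ignore_attr = TRUE
    )
    # residual history must be non-increasing
    expect_true(all(diff(B$residual_history) <= 1e-12))
  }
})

test_that("two columns span the N = 3 operator exactly", {
  # the three columns of E sum to zero, so any two span all of them
  E <- build_difference_operator(3)
  B <- rbd(E, eps_R = 1e-6, d_max = 2)
  expect_equal(B$d, 2L)
  unselected <- setdiff(1:3, B$selected)
  expect_lt(compression_error(E, B)[unselected], 1e-10)
})

test_that("full-depth runs terminate at d = N-1 with zero residual", {
  for (N in c(5, 8, 12)) {
    E <- build_difference_operator(N)
    B <- rbd(E, eps_R = 1e-12, d_max = N - 1)
    expect_equal(B$d, N - 1L)
    expect_lte(max(compression_error(E, B)), 1e-12)
    expect_lte(tail(B$residual_history, 1), 1e-12)
    # eps_R = 0: stops at exactly d = N - 1, never selecting a redundant column
    B0 <- rbd(E, eps_R = 0, d_max = N - 1)
    expect_equal(B0$d, N - 1L)
    expect_equal(sort(unique(B0$selected)), sort(B0$selected))
    expect_lte(max(compression_error(E, B0)), 1e-10)
  }
})

test_that("the fast residual estimator agrees with dense projection", {
  set.seed(31)
  for (rep in 1:20) {
    N <- sample(4:16, 1)
    d <- sample(seq_len(N - 1), 1)
    E <- build_difference_operator(N)
    B <- rbd(E, eps_R = 0, d_max = d)
    fast <- compression_error(E, B)
    dense <- dense_column_residuals(E, B$Y)
    expect_equal(fast, dense, tolerance = 1e-8)
    # squared-residual agreement of the raw estimator, relative to ||col||^2
    raw_sq <- (N - 1) - colSums(B$T^2)
    dense_sq <- dense^2 * (N - 1)
    expect_lt(max(abs(raw_sq - dense_sq)) / (N - 1), 1e-9)
  }
})

test_that("rbd with d = 1 on N = 4 matches the dense oracle residuals", {
  E <- build_difference_operator(4)
  B <- rbd(E, eps_R = 0, d_max = 1)
  expect_equal(
    max(compression_error(E, B)),
    max(dense_column_residuals(E, B$Y)),
    tolerance = 1e-10
  )
  # selected columns represent themselves exactly
  expect_lt(compression_error(E, B)[B$selected], 1e-12)
})

test_that("rbd runs are deterministic and tie-break at the lowest index", {
  E <- build_difference_operator(10)
  B1 <- rbd(E, eps_R = 1e-6)
  B2 <- rbd(E, eps_R = 1e-6)
  expect_identical(B1$selected, B2$selected)
  expect_equal(B1$Y, B2$Y)
  expect_equal(B1$selected[1], 1L) # auto init takes the first column
  B3 <- rbd(E, eps_R = 1e-6, init = 4)
  expect_equal(B3$selected[1], 4L)
})

test_that("invalid inputs are rejected and tiny tolerances warned about", {
  E <- build_difference_operator(6)
  expect_error(rbd(E, d_max = 6), "rank")
  expect_error(rbd(E, eps_R = -1), "nonnegative")
  expect_warning(rbd(E, eps_R = 1e-14), "precision")
  expect_error(
    compression_error(build_difference_operator(5), rbd(E)),
    "disagree"
  )
})

test_that("convergence history tidies to one row per iteration", {
  E <- build_difference_operator(7)
  B <- rbd(E, eps_R = 0)
  td <- tidy(B)
  expect_equal(nrow(td), B$d)
  expect_named(td, c("iteration", "selected_column", "max_residual"))
  expect_s3_class(autoplot(B), "ggplot")
})
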