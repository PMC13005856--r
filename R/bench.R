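#' Simulation study comparing the exact and reduced-basis designs
#'
#' For each covariance structure, study size and replicate: draw a prior
#' covariance, compute the exact scheduling distribution (full `Delta` +
#' spectral decomposition) and the reduced-basis one, and record their
#' Kullback-Leibler divergence plus wall-clock times. Per-replicate seeds
#' are derived deterministically from the master seed by a counter scheme,
#' so the full table is reproducible and any single cell can be re-run in
#' isolation. Timings are reported for interest only; they are
#' hardware-dependent and gate nothing.
#'
#' @param structures Character subset of
#'   `c("laplacian", "toeplitz", "inverse_wishart")`.
#' @param N_list Study sizes (each within the dense-`Delta` guard).
#' @param reps Replicates per cell (default 10).
#' @param eps_R RBD tolerance (default `1e-6`).
#' @param seed Master seed.
#' @param p Edge probability for the Laplacian structure (default 0.5).
#' @param rho Decay for the Toeplitz structure (default 0.5). Toeplitz is
#'   deterministic, so its replicates differ only in timing.
#' @param d_max RBD cap (default `N - 1` per size).
#' @return A tibble of class `bench_result`: one row per (structure, N,
#'   replicate) with columns `structure`, `N`, `param`, `replicate`,
#'   `seed`, `kl`, `max_abs_diff`, `d_achieved`, `degenerate`,
#'   `time_standard`, `time_rbd`, `error` (NA unless the replicate failed).
#' @export
run_study <- function(structures = c("laplacian", "toeplitz", "inverse_wishart"),
                      N_list = c(8, 16, 32, 64), reps = 10, eps_R = 1e-6,
                      seed = 1, p = 0.5, rho = 0.5, d_max = NULL) {
  structures <- match.arg(structures, several.ok = TRUE)
  grid <- expand.grid(
    structure = structures, N = N_list, replicate = seq_len(reps),
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )
  grid <- grid[order(grid$structure, grid$N, grid$replicate), ]
  rows <- purrr::pmap(grid, function(structure, N, replicate) {
    rep_seed <- derive_seed(seed, match(structure, c(
      "laplacian", "toeplitz", "inverse_wishart"
    )), N, replicate)
    run_one_cell(
      structure, N, replicate, rep_seed,
      eps_R = eps_R, p = p, rho = rho, d_max = d_max
    )
  })
  out <- dplyr::bind_rows(rows)
  tibble::new_tibble(out, class = "bench_result")
}

derive_seed <- function(master, ...) {
  parts <- c(master, ...)
  s <- 0
  for (x in parts) s <- (s * 1000003 + as.double(x)) %% 2147483629
  as.integer(s) + 1L
}

make_study_covariance <- function(structure, N, rep_seed, p, rho) {
  switch(structure,
    laplacian = laplacian_covariance(erdos_renyi_adjacency(N, p, seed = rep_seed)),
    toeplitz = toeplitz_covariance(N, rho),
    inverse_wishart = inverse_wishart_covariance(N, seed = rep_seed),
    abort(sprintf("unknown covariance structure '%s'", structure))
  )
}

run_one_cell <- function(structure, N, replicate, rep_seed, eps_R, p, rho,
                         d_max = NULL, max_n = 300) {
  param <- switch(structure,
    laplacian = p, toeplitz = rho, inverse_wishart = N + 2
  )
  base <- tibble::tibble(
    structure = structure, N = as.integer(N), param = param,
    replicate = as.integer(replicate), seed = as.integer(rep_seed),
    kl = NA_real_, max_abs_diff = NA_real_, d_achieved = NA_integer_,
    degenerate = NA, final_residual = NA_real_,
    time_standard = NA_real_, time_rbd = NA_real_,
    error = NA_character_
  )
  tryCatch({
    C <- make_study_covariance(structure, N, rep_seed, p, rho)
    t0 <- proc.time()[["elapsed"]]
    S <- standard_scheduling(C, max_n = max_n)
    t1 <- proc.time()[["elapsed"]]
    St <- rbd_scheduling(C, eps_R = eps_R, d_max = d_max)
    t2 <- proc.time()[["elapsed"]]
    cmp <- kl_divergence(S, St)
    meta <- attr(St, "meta")
    base$kl <- cmp$kl
    base$max_abs_diff <- cmp$max_abs_diff
    base$d_achieved <- as.integer(meta$d)
    base$degenerate <- isTRUE(meta$degenerate)
    base$final_residual <- meta$final_residual
    base$time_standard <- t1 - t0
    base$time_rbd <- t2 - t1
    base
  }, error = function(e) {
    base$error <- conditionMessage(e)
    base
  })
}

#' Sensitivity of the reduced-basis design to the sparsity of the prior
#'
#' Re-runs the Laplacian-covariance comparison over a grid of edge
#' probabilities, mirroring the connectivity sweep of the benchmark study.
#'
#' @param p_grid Edge probabilities (default `seq(0.1, 0.8, by = 0.1)`).
#' @param N_list Study sizes.
#' @inheritParams run_study
#' @return A `bench_result` tibble with `param` holding the edge
#'   probability.
#' @export
sparsity_sweep <- function(p_grid = seq(0.1, 0.8, by = 0.1),
                           N_list = c(8, 16, 32, 64), reps = 5,
                           eps_R = 1e-6, seed = 1) {
  rows <- list()
  k <- 0L
  for (p in p_grid) {
    for (N in N_list) {
      for (r in seq_len(reps)) {
        k <- k + 1L
        rep_seed <- derive_seed(seed, round(1000 * p), N, r)
        rows[[k]] <- run_one_cell(
          "laplacian", N, r, rep_seed,
          eps_R = eps_R, p = p, rho = 0.5
        )
      }
    }
  }
  tibble::new_tibble(dplyr::bind_rows(rows), class = "bench_result")
}

#' Sensitivity of the reduced-basis design to the residual tolerance
#'
#' Varies the RBD tolerance `eps_R` over a grid (canonically `1e-6` down to
#' `1e-16`) at fixed study size and connectivity, recording the KL
#' divergence against the exact design and whether the greedy basis
#' stopped on numerical degeneracy. Tolerances below double precision
#' (~`1e-13`) are flagged as degenerate rather than failing.
#'
#' @param eps_list Tolerances to sweep.
#' @param N Study size (default 32).
#' @param p Edge probability of the Laplacian prior (default 0.5).
#' @param reps Replicates per tolerance (default 5).
#' @param seed Master seed.
#' @return A `bench_result` tibble with an extra `eps_R` column.
#' @export
tolerance_sweep <- function(eps_list = 10^-c(6, 8, 10, 12, 14, 16), N = 32,
                            p = 0.5, reps = 5, seed = 1) {
  rows <- list()
  k <- 0L
  for (eps in eps_list) {
    for (r in seq_len(reps)) {
      k <- k + 1L
      rep_seed <- derive_seed(seed, N, r)  # same draws across tolerances
      row <- withCallingHandlers(
        run_one_cell("laplacian", N, r, rep_seed, eps_R = eps, p = p, rho = 0.5),
        warning = function(w) invokeRestart("muffleWarning")
      )
      row$eps_R <- eps
      rows[[k]] <- row
    }
  }
  tibble::new_tibble(dplyr::bind_rows(rows), class = "bench_result")
}

#' Summarise a benchmark table
#'
#' @param x A `bench_result`.
#' @param ... Unused.
#' @return One row per (structure, N, param[, eps_R]) with mean/min/max KL,
#'   mean times and the mean speedup.
#' @method glance bench_result
#' @export
glance.bench_result <- function(x, ...) {
  keys <- intersect(c("structure", "N", "param", "eps_R"), names(x))
  dplyr::summarise(
    dplyr::group_by(tibble::as_tibble(x), dplyr::across(dplyr::all_of(keys))),
    reps = dplyr::n(),
    mean_kl = mean(.data$kl),
    min_kl = min(.data$kl),
    max_kl = max(.data$kl),
    mean_time_standard = mean(.data$time_standard),
    mean_time_rbd = mean(.data$time_rbd),
    speedup = mean(.data$time_standard) / mean(.data$time_rbd),
    any_degenerate = any(.data$degenerate),
    .groups = "drop"
  )
}

#' Benchmark summary as a Markdown table
#'
#' @param x A `bench_result`.
#' @return A character vector of Markdown lines (invisibly printed with
#'   `cat`).
#' @export
bench_markdown <- function(x) {
  g <- glance(x)
  hdr <- c(
    "| Structure | N | param | RBD (s) | Standard (s) | Speedup | mean KL |",
    "|---|---|---|---|---|---|---|"
  )
  body <- sprintf(
    "| %s | %d | %s | %.4f | %.4f | %.1f | %.3g |",
    g$structure, g$N, format(g$param, digits = 3),
    g$mean_time_rbd, g$mean_time_standard, g$speedup, g$mean_kl
  )
  lines <- c(hdr, body)
  cat(lines, sep = "\n")
  invisible(lines)
}

#' Plot benchmark accuracy
#'
#' @param object A `bench_result`.
#' @param ... Unused.
#' @return A ggplot of KL divergence by study size and structure (log y
#'   axis).
#' @method autoplot bench_result
#' @export
autoplot.bench_result <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$kl <- pmax(df$kl, 1e-18)
  ggplot2::ggplot(df, ggplot2::aes(
    x = factor(.data$N), y = .data$kl,
    colour = .data$structure
  )) +
    ggplot2::geom_boxplot() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(
      x = "number of objects N",
      y = "KL divergence (exact || reduced-basis)",
      colour = "prior structure",
      title = "Accuracy of the reduced-basis design"
    )
}
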