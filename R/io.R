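#' Read a prior covariance matrix
#'
#' Accepts a dense CSV (N numeric columns, no row labels, optional header)
#' or a Matrix Market file (`%%MatrixMarket` header; both `array` and
#' `coordinate` formats, `general` or `symmetric`). Mild asymmetry (at most
#' `1e-8` relative) is symmetrised by averaging with the transpose; larger
#' asymmetry is an error. A matrix that is slightly indefinite is clipped
#' to the positive semidefinite cone with a warning.
#'
#' @param path File path.
#' @return A `covariance_model`.
#' @export
read_covariance <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  first <- readLines(path, n = 1L)
  C <- if (grepl("^%%MatrixMarket", first)) {
    read_matrix_market(path)
  } else {
    read_dense_csv(path)
  }
  if (nrow(C) != ncol(C)) {
    abort(sprintf("covariance must be square; got %d x %d", nrow(C), ncol(C)))
  }
  out <- as_covariance_model(C)
  ev_min <- min(eigen(unclass_cov(out), symmetric = TRUE, only.values = TRUE)$values)
  ev_max <- max(abs(eigen(unclass_cov(out), symmetric = TRUE, only.values = TRUE)$values))
  if (ev_min < -1e-10 * max(ev_max, 1)) {
    warn(sprintf(
      "matrix is not positive semidefinite (min eigenvalue %.3g); clipping negative eigenvalues to 0",
      ev_min
    ))
    es <- eigen(unclass_cov(out), symmetric = TRUE)
    Cc <- es$vectors %*% (pmax(es$values, 0) * t(es$vectors))
    out <- as_covariance_model((Cc + t(Cc)) / 2)
  }
  out
}

read_dense_csv <- function(path) {
  first <- readLines(path, n = 1L)
  has_header <- !all(grepl(
    "^\\s*[-+0-9.eE]+\\s*$",
    strsplit(first, ",")[[1]]
  ))
  M <- utils::read.csv(path, header = has_header)
  M <- as.matrix(M)
  if (!is.numeric(M)) abort("covariance file contains non-numeric entries")
  dimnames(M) <- NULL
  M
}

read_matrix_market <- function(path) {
  header <- tolower(readLines(path, n = 1L))
  if (grepl("coordinate", header)) {
    as.matrix(Matrix::readMM(path))
  } else {
    lines <- readLines(path)
    lines <- lines[!grepl("^%", lines)]
    lines <- lines[nzchar(trimws(lines))]
    dims <- as.integer(strsplit(trimws(lines[1]), "\\s+")[[1]])
    vals <- as.numeric(unlist(strsplit(trimws(lines[-1]), "\\s+")))
    if (length(vals) == dims[1] * dims[2]) {
      matrix(vals, dims[1], dims[2])  # column-major, general
    } else if (grepl("symmetric", header) &&
               length(vals) == dims[1] * (dims[1] + 1) / 2) {
      M <- matrix(0, dims[1], dims[2])
      M[lower.tri(M, diag = TRUE)] <- vals
      M <- M + t(M) - diag(diag(M))
      M
    } else {
      abort("Matrix Market array file has the wrong number of entries")
    }
  }
}

#' Write a covariance matrix
#'
#' @param C A matrix or `covariance_model`.
#' @param path Output path; `.mtx`/`.mm` extensions select Matrix Market
#'   (array, general), anything else dense CSV without header.
#' @export
write_covariance <- function(C, path) {
  C <- as.matrix(C)
  dimnames(C) <- NULL
  if (grepl("\\.(mtx|mm)$", path, ignore.case = TRUE)) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("%%MatrixMarket matrix array real general", con)
    writeLines(sprintf("%d %d", nrow(C), ncol(C)), con)
    writeLines(format(as.vector(C), digits = 17, scientific = TRUE, trim = TRUE), con)
  } else {
    utils::write.table(C, path,
      sep = ",", row.names = FALSE,
      col.names = FALSE
    )
  }
  invisible(path)
}

#' Write / read a scheduling distribution
#'
#' Schedules are stored as CSV with header `i,j,q`, rows sorted by linear
#' pair index, probabilities printed with 17 significant digits so the
#' round trip is exact in double precision. Reading validates the
#' distribution (nonnegative, sums to 1).
#'
#' @param S A `bt_schedule`.
#' @param path File path.
#' @return `write_schedule` returns `path` invisibly; `read_schedule`
#'   returns a `bt_schedule`.
#' @export
write_schedule <- function(S, path) {
  N <- schedule_n_objects(S)
  df <- data.frame(
    i = S$i, j = S$j,
    q = vapply(S$q, format, "", digits = 17, trim = TRUE)
  )
  utils::write.table(df, path,
    sep = ",", row.names = FALSE, col.names = TRUE,
    quote = FALSE
  )
  invisible(path)
}

#' @rdname write_schedule
#' @export
read_schedule <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  df <- utils::read.csv(path)
  if (!all(c("i", "j", "q") %in% names(df))) {
    abort("schedule file must have columns i, j, q")
  }
  N <- max(df$j)
  r <- pair_to_index(df$i, df$j, N)
  q <- numeric(N * (N - 1) / 2)
  if (anyDuplicated(r) || length(r) != length(q)) {
    abort("schedule file must contain each pair exactly once")
  }
  q[r] <- df$q
  new_schedule(q, N, method = "file")
}

#' Read an adjacency edge list
#'
#' Whitespace- or tab-separated, one undirected edge per line, 1-based
#' node labels. Duplicate and reversed edges collapse to one; self-loops
#' are rejected.
#'
#' @param path File path.
#' @param N Node count (default: largest label seen).
#' @return A `graph_model`.
#' @export
read_adjacency <- function(path, N = NULL) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  df <- utils::read.table(path, header = FALSE)
  if (ncol(df) < 2) abort("edge list must have two columns")
  a <- as.integer(df[[1]])
  b <- as.integer(df[[2]])
  if (any(a == b)) abort("self-loops are not allowed")
  N <- as.integer(N %||% max(a, b))
  if (any(a < 1 | b < 1 | a > N | b > N)) abort("node labels out of range")
  A <- matrix(0, N, N)
  A[cbind(pmin(a, b), pmax(a, b))] <- 1
  A[lower.tri(A)] <- 0
  A <- A + t(A)
  structure(
    list(N = N, A = A, D = diag(rowSums(A), N), p = NA_real_, seed = NULL),
    class = "graph_model"
  )
}

#' Read comparison data
#'
#' Accepts the aggregated format (header `i,j,wins_i,total`) or the long
#' format (header `left,right,winner`, one row per judgement, aggregated
#' on load).
#'
#' @param path CSV file path.
#' @param N Object count (default: largest label seen).
#' @return A `bt_comparisons`.
#' @export
read_comparisons <- function(path, N = NULL) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  as_comparisons(utils::read.csv(path), N = N)
}

#' Write a Bradley-Terry fit
#'
#' Writes the posterior summary (`object, estimate, posterior_sd`) as CSV
#' and, optionally, the Laplace posterior covariance in the same dense-CSV
#' dialect as [read_covariance()], ready to feed back into
#' [rbd_scheduling()] as a next-phase prior.
#'
#' @param fit A `bt_fit`.
#' @param path Summary CSV path.
#' @param cov_path Optional path for the posterior covariance.
#' @export
write_bt_fit <- function(fit, path, cov_path = NULL) {
  df <- tidy(fit)
  utils::write.table(
    data.frame(
      object = df$object,
      estimate = format(df$estimate, digits = 17, trim = TRUE),
      posterior_sd = format(df$std_error, digits = 17, trim = TRUE)
    ),
    path,
    sep = ",", row.names = FALSE, col.names = TRUE, quote = FALSE
  )
  if (!is.null(cov_path)) write_covariance(fit$post_cov, cov_path)
  invisible(path)
}

#' Heatmap of a scheduling distribution
#'
#' @param object A `bt_schedule`.
#' @param ... Unused.
#' @return A ggplot tile plot of pair probabilities.
#' @method autoplot bt_schedule
#' @export
autoplot.bt_schedule <- function(object, ...) {
  ggplot2::ggplot(
    tibble::as_tibble(object),
    ggplot2::aes(x = .data$j, y = .data$i, fill = .data$q)
  ) +
    ggplot2::geom_tile() +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(
      x = "object j", y = "object i", fill = "q",
      title = sprintf(
        "Scheduling distribution (%s method)",
        attr(object, "method") %||% "?"
      )
    )
}
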