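#' Number of unordered pairs among N objects
#'
#' @param N Integer number of objects, at least 2.
#' @return `M = N(N-1)/2`, the number of unordered pairs.
#' @export
#' @examples
#' n_pairs(4) # 6
n_pairs <- function(N) {
  N <- check_n_objects(N)
  N * (N - 1L) / 2L
}

#' Linear index of an unordered pair
#'
#' Maps a pair `(i, j)` with `i < j` to its linear index
#' `r = M - (N - i + 1)(N - i)/2 + j - i`, i.e. the position of the pair in
#' the lexicographic ordering (1,2), (1,3), ..., (1,N), (2,3), ..., (N-1,N).
#' This ordering indexes the rows of the pairwise difference operator and
#' the entries of every scheduling distribution in the package.
#'
#' @param i,j Object labels in `1..N` with `i != j`; vectors are recycled.
#'   Pairs must be supplied with `i < j` (callers holding `i > j` must swap).
#' @param N Number of objects.
#' @return Integer vector of linear indices in `1..M`.
#' @seealso [index_to_pair()] for the inverse.
#' @export
#' @examples
#' pair_to_index(2, 3, N = 4) # 4
pair_to_index <- function(i, j, N) {
  N <- check_n_objects(N)
  if (length(i) != length(j)) {
    lab <- vctrs_recycle(i, j)
    i <- lab[[1]]; j <- lab[[2]]
  }
  if (any(i == j)) {
    abort("a pair must contain two distinct objects (i == j supplied)")
  }
  if (any(i < 1L | i > N | j < 1L | j > N)) {
    abort(sprintf("object labels must lie in 1..%d", N))
  }
  if (any(i > j)) {
    abort("pairs must be supplied with i < j; swap the labels first")
  }
  M <- N * (N - 1) / 2
  as.integer(M - (N - i + 1) * (N - i) / 2 + j - i)
}

#' Pair corresponding to a linear index
#'
#' Inverts [pair_to_index()]: recovers the unordered pair `(i, j)` at
#' position `r` of the lexicographic pair ordering.
#'
#' @param r Linear index in `1..M` (vectorised).
#' @param N Number of objects.
#' @return A tibble with integer columns `i` and `j` (`i < j`), one row per
#'   element of `r`.
#' @export
#' @examples
#' index_to_pair(4, N = 4) # pair (2, 3)
index_to_pair <- function(r, N) {
  N <- check_n_objects(N)
  M <- N * (N - 1) / 2
  if (any(r < 1 | r > M) || any(r != floor(r))) {
    abort(sprintf("linear index must be an integer in 1..%d", M))
  }
  # pairs with first element i occupy a contiguous block of N - i indices;
  # locate the block, then the offset within it
  ends <- cumsum(seq(N - 1L, 1L))
  i <- findInterval(r - 1L, ends) + 1L
  starts <- c(0L, ends)[i]
  j <- i + (r - starts)
  tibble::tibble(i = as.integer(i), j = as.integer(j))
}

#' All unordered pairs in linear-index order
#'
#' @param N Number of objects.
#' @return A tibble with columns `i`, `j`, ordered by linear index `r`.
#' @export
pair_grid <- function(N) {
  N <- check_n_objects(N)
  i <- rep.int(seq_len(N - 1L), times = seq(N - 1L, 1L))
  j <- sequence(seq(N - 1L, 1L)) + i
  tibble::tibble(i = as.integer(i), j = as.integer(j))
}

#' Sparse pairwise difference operator
#'
#' Builds the `M x N` sparse matrix `E` whose row for pair `(i, j)` is
#' `e_i - e_j` (+1 in column `i`, -1 in column `j`). `E` maps a vector of
#' object qualities to the vector of all pairwise quality differences; the
#' pairs-of-pairs covariance of a prior `C` is `E C E'`. Its rank is `N - 1`
#' and its null space is spanned by the constant vector.
#'
#' @param N Number of objects, at least 2.
#' @return A `dgCMatrix` with `2M` structural nonzeros; rows follow
#'   [pair_to_index()] ordering.
#' @export
#' @examples
#' build_difference_operator(3)
build_difference_operator <- function(N) {
  N <- check_n_objects(N)
  pg <- pair_grid(N)
  M <- nrow(pg)
  Matrix::sparseMatrix(
    i = c(seq_len(M), seq_len(M)),
    j = c(pg$i, pg$j),
    x = c(rep(1, M), rep(-1, M)),
    dims = c(M, N)
  )
}

check_n_objects <- function(N) {
  if (length(N) != 1L || !is.finite(N) || N != floor(N) || N < 2) {
    abort("N must be a single integer >= 2")
  }
  as.integer(N)
}

vctrs_recycle <- function(i, j) {
  n <- max(length(i), length(j))
  list(rep_len(i, n), rep_len(j, n))
}
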