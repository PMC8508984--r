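#' Bipartite adjacency of an association dataset
#'
#' Assembles the symmetric (m + n) x (m + n) adjacency
#' \deqn{A = \begin{pmatrix} 0 & R \\ R^\top & 0 \end{pmatrix}}
#' of the bipartite graph whose only edges join ncRNAs (node indices
#' 1..m) to drugs (node indices m+1..m+n). There are no intra-domain
#' edges: the ncRNA-ncRNA and drug-drug diagonal blocks are zero. The
#' matrix is held sparse (`Matrix::sparseMatrix`); it has exactly
#' 2 * n_pairs(ds) nonzeros.
#'
#' @param ds an [association_dataset].
#' @return A symmetric sparse 0/1 Matrix of size (m + n) x (m + n).
#' @export
build_adjacency <- function(ds) {
  stopifnot(inherits(ds, "association_dataset"))
  m <- n_ncrnas(ds); n <- n_drugs(ds)
  i <- ds$pairs[, 1L]
  j <- m + ds$pairs[, 2L]
  Matrix::sparseMatrix(
    i = c(i, j), j = c(j, i), x = 1,
    dims = c(m + n, m + n)
  )
}

#' Symmetric spectral normalization of a self-looped adjacency
#'
#' Computes the propagation operator
#' \deqn{P = \tilde D^{-1/2} \tilde A \tilde D^{-1/2}, \quad \tilde A = A + I,}
#' where \eqn{\tilde D} is the diagonal degree matrix of \eqn{\tilde A}.
#' The spectral rule weights each edge by the degrees of both endpoints,
#' \eqn{P_{ij} = \tilde A_{ij} / \sqrt{\tilde d_i \tilde d_j}}. Because the
#' self-loop guarantees \eqn{\tilde d_i \ge 1}, the operator is defined even
#' for isolated nodes (whose row is the unit self-loop). P is symmetric with
#' spectral radius at most 1.
#'
#' @param adj square symmetric adjacency, typically from [build_adjacency()].
#' @return A symmetric sparse Matrix P of the same size.
#' @export
normalize_adjacency <- function(adj) {
  N <- nrow(adj)
  stopifnot(ncol(adj) == N)
  A_tilde <- adj + Matrix::Diagonal(N)
  d_tilde <- Matrix::rowSums(A_tilde)
  inv_sqrt <- Matrix::Diagonal(N, 1 / sqrt(d_tilde))
  P <- inv_sqrt %*% A_tilde %*% inv_sqrt
  methods::as(Matrix::forceSymmetric(P), "generalMatrix")
}

#' Export adjacency operators in MatrixMarket coordinate format
#'
#' @param mat a sparse Matrix (e.g. from [build_adjacency()] or
#'   [normalize_adjacency()]).
#' @param path output `.mtx` path.
#' @return `path`, invisibly.
#' @export
write_operator_mtx <- function(mat, path) {
  Matrix::writeMM(methods::as(mat, "CsparseMatrix"), path)
  invisible(path)
}
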