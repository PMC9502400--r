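# Tanimoto kernel.
#
# On binary vectors the Tanimoto (Jaccard) similarity
# T(x, y) = |x & y| / (|x| + |y| - |x & y|) is a valid positive-semidefinite
# kernel, so it can drive a support vector machine directly. The Gram matrix
# is computed with one matrix product rather than a pairwise loop.

#' Tanimoto kernel (Gram) matrix between two fingerprint sets
#'
#' @param X,Y binary matrices with molecules in rows and the same number of
#'   columns. `Y` defaults to `X` (the square training Gram matrix).
#' @return `nrow(X) x nrow(Y)` matrix of Tanimoto similarities. A pair of
#'   all-zero rows has similarity 1 (identical empty fingerprints).
#' @export
tanimoto_kernel_matrix <- function(X, Y = X) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (ncol(X) != ncol(Y)) {
    .stopf("fingerprint lengths differ (%d vs %d columns)", ncol(X), ncol(Y))
  }
  storage.mode(X) <- "double"; storage.mode(Y) <- "double"
  common <- X %*% t(Y)
  denom <- outer(rowSums(X), rowSums(Y), "+") - common
  K <- ifelse(denom == 0, 1, common / pmax(denom, .Machine$double.eps))
  dimnames(K) <- NULL
  K
}
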