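#' Group-factor correlation matrix from unconstrained parameters
#'
#' Maps any finite vector `beta` of length `G(G-1)/2` to a valid `G x G`
#' correlation matrix via a row-normalized Cholesky construction: row `i`
#' of a lower-triangular matrix `L` is `(beta_{i,1}, ..., beta_{i,i-1}, 1)`
#' scaled to unit Euclidean norm, and the correlation matrix is `L L'`.
#' The map is smooth and surjective onto the set of (strictly positive
#' definite) correlation matrices, which keeps the optimization over the
#' factor correlations unconstrained.
#'
#' @param beta numeric vector of length `G(G-1)/2`.
#' @param G number of group factors.
#' @return `G x G` correlation matrix.
#' @examples
#' build_group_correlation(1, G = 2)   # off-diagonal 1/sqrt(2)
#' @export
build_group_correlation <- function(beta, G) {
  G <- as.integer(G)
  nb <- G * (G - 1L) / 2L
  beta <- as.numeric(beta)
  if (length(beta) != nb) stop_dim("beta", nb, length(beta))
  if (G == 0L) return(matrix(numeric(0), 0, 0))
  L <- matrix(0, G, G)
  pos <- 0L
  for (i in seq_len(G)) {
    v <- c(if (i > 1) beta[pos + seq_len(i - 1L)], 1)
    pos <- pos + i - 1L
    L[i, seq_len(i)] <- v / sqrt(sum(v^2))
  }
  tcrossprod(L)
}

#' Full factor correlation matrix of the extended bi-factor model
#'
#' The general factor (index 1) is uncorrelated with every group factor;
#' the `G x G` group block comes from [build_group_correlation()]. The zero
#' correlations between the general and the group factors are required for
#' identifiability of the oblique bi-factor model.
#'
#' @inheritParams build_group_correlation
#' @return `(G+1) x (G+1)` correlation matrix.
#' @export
build_phi <- function(beta, G) {
  G <- as.integer(G)
  Phi <- diag(G + 1L)
  Phi[-1, -1] <- build_group_correlation(beta, G)
  Phi
}
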