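#' Bi-factor model parameters
#'
#' Bundles the three parameter blocks of the extended (oblique) bi-factor
#' model: the `J x (G+1)` loading matrix (column 1 is the general factor,
#' columns `2..G+1` the group factors), the unconstrained correlation
#' parameters `beta` of length `G(G-1)/2` that map to the group-factor
#' correlation block (see [build_group_correlation()]), and the strictly
#' positive uniquenesses `psi`.
#'
#' @param loadings numeric `J x (G+1)` matrix of factor loadings.
#' @param beta numeric vector of length `G(G-1)/2` of unconstrained
#'   group-correlation parameters.
#' @param psi numeric vector of length `J` of positive unique variances.
#' @return An object of class `bifactor_params`.
#' @examples
#' p <- bifactor_params(cbind(rep(1, 4), c(1, 1, 0, 0), c(0, 0, 1, 1)),
#'                      beta = 0.5, psi = rep(1, 4))
#' model_covariance(p)
#' @export
bifactor_params <- function(loadings, beta = numeric(0), psi) {
  loadings <- as.matrix(loadings)
  storage.mode(loadings) <- "double"
  J <- nrow(loadings)
  G <- ncol(loadings) - 1L
  if (G < 1) stop("loadings must have at least 2 columns (general + 1 group)")
  nb <- G * (G - 1L) / 2L
  beta <- as.numeric(beta)
  if (length(beta) != nb) stop_dim("beta", nb, length(beta))
  psi <- as.numeric(psi)
  if (length(psi) != J) stop_dim("psi", J, length(psi))
  if (any(!is.finite(loadings)) || any(!is.finite(beta)) || any(!is.finite(psi)))
    stop("bifactor_params: all parameters must be finite")
  if (any(psi <= 0)) stop("psi must be strictly positive")
  if (J < G + 1)
    warning("fewer variables (J = ", J, ") than factors (G + 1 = ", G + 1, ")")
  structure(list(loadings = loadings, beta = beta, psi = psi, J = J, G = G),
            class = "bifactor_params")
}

#' @export
print.bifactor_params <- function(x, ...) {
  cat("Bi-factor parameters: J =", x$J, "variables, G =", x$G,
      "group factors\n")
  cat("  loadings: ", x$J, "x", x$G + 1L,
      " | beta: ", length(x$beta), " | psi range: [",
      signif(min(x$psi), 4), ", ", signif(max(x$psi), 4), "]\n", sep = "")
  invisible(x)
}

# Flatten parameters to the unconstrained optimization vector
# (vec(Lambda), beta, omega = log psi) and back.
pack_params <- function(params) {
  c(as.numeric(params$loadings), params$beta, log(params$psi))
}

unpack_params <- function(theta, J, G) {
  nL <- J * (G + 1L)
  nb <- G * (G - 1L) / 2L
  loadings <- matrix(theta[seq_len(nL)], J, G + 1L)
  beta <- if (nb > 0) theta[nL + seq_len(nb)] else numeric(0)
  omega <- theta[nL + nb + seq_len(J)]
  # floor guards against exp() underflow in degenerate (Heywood-type) runs
  bifactor_params(loadings, beta, pmax(exp(omega), 1e-100))
}

#' Wrap a sample covariance or correlation matrix
#'
#' Validates symmetry and positive semi-definiteness and records the sample
#' size `N` (needed for BIC) and whether the matrix is a correlation matrix.
#'
#' @param S numeric `J x J` symmetric positive semi-definite matrix.
#' @param N sample size used to form `S` (nominal when `S` is a population
#'   matrix).
#' @param is_correlation logical; `TRUE` when `S` is a correlation matrix.
#' @return An object of class `sample_cov`.
#' @export
sample_covariance <- function(S, N, is_correlation = FALSE) {
  S <- as.matrix(S)
  storage.mode(S) <- "double"
  J <- nrow(S)
  if (ncol(S) != J) stop("S must be square")
  if (max(abs(S - t(S))) > 1e-10) stop("S must be symmetric (tolerance 1e-10)")
  S <- (S + t(S)) / 2
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-10)
    stop("S must be positive semi-definite; min eigenvalue = ",
         format(min(ev)))
  structure(list(S = S, N = as.integer(N), J = J,
                 is_correlation = isTRUE(is_correlation),
                 logdetS = if (min(ev) > 0) sum(log(ev)) else -Inf,
                 min_eigen = min(ev)),
            class = "sample_cov")
}

#' Compute a sample covariance (or correlation) matrix from raw data
#'
#' @param x numeric matrix or data frame, one row per observation.
#' @param denominator `"N"` for the maximum-likelihood convention (default)
#'   or `"N-1"` for the unbiased one.
#' @param correlation standardize to a correlation matrix?
#' @return A [sample_covariance()] object.
#' @export
compute_sample_cov <- function(x, denominator = c("N", "N-1"),
                               correlation = FALSE) {
  denominator <- match.arg(denominator)
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  N <- nrow(x)
  xc <- sweep(x, 2, colMeans(x))
  S <- crossprod(xc) / if (denominator == "N") N else N - 1L
  if (correlation) S <- stats::cov2cor(S)
  sample_covariance(S, N, is_correlation = correlation)
}

as_sample_cov <- function(sample) {
  if (inherits(sample, "sample_cov")) sample
  else stop("expected a sample_covariance() object")
}
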