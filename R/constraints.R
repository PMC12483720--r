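#' Bi-factor equality-constraint residuals
#'
#' The exact bi-factor pattern — each variable loads on at most one group
#' factor — holds exactly when every product of two distinct group loadings
#' in the same row vanishes. Two equivalent encodings are offered:
#' `"pairwise"` returns the `J * G(G-1)/2` bilinear residuals
#' `lambda_{jg} lambda_{jg'}` (default; better-conditioned multipliers),
#' `"row_aggregate"` returns the `J` quartic sums
#' `sum_{g<g'} lambda_{jg}^2 lambda_{jg'}^2`. Both are the zero vector if
#' and only if the loading matrix has an exact bi-factor structure.
#'
#' @param loadings `J x (G+1)` loading matrix (column 1 = general factor).
#' @param form constraint encoding, `"pairwise"` or `"row_aggregate"`.
#' @return numeric vector of constraint residuals (empty when `G = 1`).
#' @export
constraint_values <- function(loadings, form = c("pairwise", "row_aggregate")) {
  form <- match.arg(form)
  loadings <- as.matrix(loadings)
  G <- ncol(loadings) - 1L
  J <- nrow(loadings)
  if (G < 2) return(numeric(0))
  B <- loadings[, -1, drop = FALSE]
  if (form == "pairwise") {
    out <- numeric(J * G * (G - 1L) / 2L)
    k <- 0L
    for (g in 1:(G - 1L)) for (gp in (g + 1L):G) {
      out[k + seq_len(J)] <- B[, g] * B[, gp]
      k <- k + J
    }
    out
  } else {
    out <- numeric(J)
    for (g in 1:(G - 1L)) for (gp in (g + 1L):G)
      out <- out + (B[, g] * B[, gp])^2
    out
  }
}

#' Second-largest value of a vector
#'
#' The screening function used when measuring how far a loading matrix is
#' from the bi-factor set: a row satisfies the structure when the
#' second-largest absolute group loading is (numerically) zero. Vectors of
#' length 0 or 1 return 0 by convention, so single-group models are always
#' feasible.
#'
#' @param v numeric vector.
#' @return scalar: the second-largest element of `v` as given.
#' @export
second_largest <- function(v) {
  if (length(v) < 2) return(0)
  sort(v, decreasing = TRUE)[2]
}

#' Distance from a loading matrix to the bi-factor set
#'
#' `max_j` of the second-largest absolute group loading in row `j`; zero
#' exactly on loading matrices with an exact bi-factor structure. Used as
#' the feasibility stopping criterion of the solver: when below the
#' threshold `eps_struct`, each variable has at most one group loading
#' above that threshold.
#'
#' @inheritParams constraint_values
#' @return non-negative scalar.
#' @export
bifactor_distance <- function(loadings) {
  loadings <- as.matrix(loadings)
  if (ncol(loadings) - 1L < 2) return(0)
  B <- abs(loadings[, -1, drop = FALSE])
  max(apply(B, 1, second_largest))
}

#' Extract the estimated bi-factor structure from a loading matrix
#'
#' Cluster `g` collects the variables whose absolute loading on group
#' factor `g` exceeds `eps_struct`; variables below the threshold on every
#' group factor are reported as unassigned (general-factor-only). When the
#' loading matrix is within `eps_struct` of the bi-factor set the clusters
#' are disjoint by construction. Extraction from a matrix farther away
#' raises a warning and resolves row ties toward the largest absolute
#' loading (lowest column index on exact ties).
#'
#' @inheritParams constraint_values
#' @param eps_struct positive threshold separating zero from nonzero group
#'   loadings.
#' @return A `bifactor_structure` object: list of `G` integer vectors of
#'   1-based variable indices plus the unassigned set.
#' @export
extract_structure <- function(loadings, eps_struct = 1e-3) {
  loadings <- as.matrix(loadings)
  J <- nrow(loadings)
  G <- ncol(loadings) - 1L
  B <- abs(loadings[, -1, drop = FALSE])
  if (bifactor_distance(loadings) >= eps_struct) {
    warning("extracting structure from a loading matrix at distance ",
            format(bifactor_distance(loadings)),
            " >= eps_struct = ", eps_struct,
            " from the bi-factor set; assigning rows to their largest loading")
    assign <- integer(J)
    for (j in seq_len(J)) {
      above <- which(B[j, ] > eps_struct)
      assign[j] <- if (length(above) == 0) 0L else which.max(B[j, ])[1]
    }
  } else {
    assign <- integer(J)
    for (j in seq_len(J)) {
      above <- which(B[j, ] > eps_struct)
      if (length(above) > 1)
        stop("internal inconsistency: row ", j,
             " exceeds eps_struct on several group factors despite being ",
             "within bifactor_distance tolerance")
      assign[j] <- if (length(above) == 0) 0L else above
    }
  }
  bifactor_structure(lapply(seq_len(G), function(g) which(assign == g)), J)
}

#' Bi-factor structure (variable clusters)
#'
#' @param clusters list of `G` integer vectors of 1-based variable indices;
#'   must be pairwise disjoint.
#' @param J total number of variables.
#' @return An object of class `bifactor_structure` with elements
#'   `clusters`, `J`, `G` and `unassigned`.
#' @export
bifactor_structure <- function(clusters, J) {
  clusters <- lapply(clusters, function(x) sort(as.integer(x)))
  all_idx <- unlist(clusters)
  if (anyDuplicated(all_idx))
    stop("clusters must be pairwise disjoint")
  if (length(all_idx) > 0 && (min(all_idx) < 1 || max(all_idx) > J))
    stop("cluster indices must lie in 1..J")
  structure(list(clusters = clusters, J = as.integer(J),
                 G = length(clusters),
                 unassigned = setdiff(seq_len(J), all_idx)),
            class = "bifactor_structure")
}

#' @export
print.bifactor_structure <- function(x, ...) {
  cat("Bi-factor structure: J =", x$J, ", G =", x$G, "\n")
  for (g in seq_len(x$G))
    cat(sprintf("  group %d: %s\n", g,
                if (length(x$clusters[[g]])) paste(x$clusters[[g]], collapse = " ")
                else "(empty)"))
  if (length(x$unassigned))
    cat("  unassigned:", paste(x$unassigned, collapse = " "), "\n")
  invisible(x)
}

#' Change in parameter values between consecutive iterates
#'
#' Sum of the Frobenius norm of the loading-matrix change, the Frobenius
#' norm of the factor-correlation change, and the Euclidean norm of the
#' uniqueness change. Used as the parameter-convergence stopping criterion.
#'
#' @param prev,curr [bifactor_params()] objects of matching dimensions.
#' @return non-negative scalar.
#' @export
parameter_change <- function(prev, curr) {
  if (prev$J != curr$J || prev$G != curr$G)
    stop("parameter_change: dimension mismatch")
  sqrt(sum((curr$loadings - prev$loadings)^2)) +
    sqrt(sum((build_phi(curr$beta, curr$G) - build_phi(prev$beta, prev$G))^2)) +
    sqrt(sum((curr$psi - prev$psi)^2))
}
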