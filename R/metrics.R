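# Solve the linear sum assignment problem (minimize total cost) for a
# square cost matrix via the Hungarian algorithm with potentials
# (shortest augmenting paths, O(n^3)). Returns the column assigned to
# each row.
solve_assignment <- function(cost) {
  n <- nrow(cost)
  stopifnot(ncol(cost) == n)
  a <- rbind(0, cbind(0, cost)) # 1-based padding: a[i+1, j+1] = cost[i, j]
  INF <- .Machine$double.xmax / 4
  u <- numeric(n + 1); v <- numeric(n + 1)
  p <- integer(n + 1); way <- integer(n + 1)
  for (i in seq_len(n)) {
    p[1] <- i
    j0 <- 0L
    minv <- rep(INF, n + 1)
    used <- rep(FALSE, n + 1)
    repeat {
      used[j0 + 1L] <- TRUE
      i0 <- p[j0 + 1L]
      delta <- INF; j1 <- 0L
      for (j in seq_len(n)) {
        if (!used[j + 1L]) {
          cur <- a[i0 + 1L, j + 1L] - u[i0 + 1L] - v[j + 1L]
          if (cur < minv[j + 1L]) { minv[j + 1L] <- cur; way[j + 1L] <- j0 }
          if (minv[j + 1L] < delta) { delta <- minv[j + 1L]; j1 <- j }
        }
      }
      for (j in 0:n) {
        if (used[j + 1L]) {
          u[p[j + 1L] + 1L] <- u[p[j + 1L] + 1L] + delta
          v[j + 1L] <- v[j + 1L] - delta
        } else {
          minv[j + 1L] <- minv[j + 1L] - delta
        }
      }
      j0 <- j1
      if (p[j0 + 1L] == 0L) break
    }
    repeat {
      j1 <- way[j0 + 1L]
      p[j0 + 1L] <- p[j1 + 1L]
      j0 <- j1
      if (j0 == 0L) break
    }
  }
  assignment <- integer(n)
  for (j in seq_len(n)) if (p[j + 1L] > 0L) assignment[p[j + 1L]] <- j
  assignment
}

#' Loading mean squared error up to permutation and sign indeterminacy
#'
#' `min ||Lambda_true - Lambda_est D P||_F^2 / (J(G+1))` over all sign-flip
#' diagonal matrices `D` and group-factor permutations `P` (the general
#' column is matched to itself, with its own optimal sign). The minimum is
#' computed exactly: for each (true, estimated) group-column pair the
#' sign-optimal squared distance is precomputed, and the optimal pairing is
#' found by the Hungarian assignment algorithm.
#'
#' @param true_loadings,est_loadings `J x (G+1)` loading matrices
#'   (column 1 = general factor).
#' @return non-negative scalar MSE.
#' @export
loading_mse <- function(true_loadings, est_loadings) {
  Tm <- as.matrix(true_loadings); Em <- as.matrix(est_loadings)
  if (!all(dim(Tm) == dim(Em)))
    stop("loading matrices must have identical dimensions")
  J <- nrow(Tm); G <- ncol(Tm) - 1L
  col_cost <- function(x, y) min(sum((x - y)^2), sum((x + y)^2))
  general <- col_cost(Tm[, 1], Em[, 1])
  if (G == 0) return(general / J)
  cost <- matrix(0, G, G)
  for (a in seq_len(G)) for (b in seq_len(G))
    cost[a, b] <- col_cost(Tm[, a + 1L], Em[, b + 1L])
  assignment <- solve_assignment(cost)
  group <- sum(cost[cbind(seq_len(G), assignment)])
  (general + group) / (J * (G + 1L))
}

#' Exact match criterion (EMC)
#'
#' Equals 1 when some relabeling of the estimated group factors makes every
#' estimated cluster identical to the corresponding true cluster, and 0
#' otherwise. Variables unassigned in one structure but clustered in the
#' other break the match.
#'
#' @param true_structure,est_structure [bifactor_structure()] objects with
#'   the same `J` and `G`.
#' @return 0 or 1.
#' @export
emc <- function(true_structure, est_structure) {
  if (true_structure$G != est_structure$G) {
    warning("structures have different numbers of group factors; EMC = 0")
    return(0)
  }
  m <- acc(true_structure, est_structure)
  as.numeric(all(m$per_factor_counts == true_structure$J))
}

#' Average correctness criterion (ACC)
#'
#' Best-permutation proportion of correctly identified zero and nonzero
#' group loadings:
#' `max_sigma (1/(J G)) sum_g (|I_g ∩ Î_sigma(g)| + |I_g^c ∩ Î_sigma(g)^c|)`.
#' For group factor `g` under a given relabeling, a variable counts as
#' correct when it is in both clusters or in neither. The optimum over
#' relabelings is found by the Hungarian assignment algorithm on the
#' per-pair correctness counts. Unassigned variables count as zero group
#' loadings everywhere.
#'
#' @inheritParams emc
#' @return list (`acc_match`) with `value` in `[0, 1]`,
#'   `best_permutation` (estimated label matched to each true group), and
#'   `per_factor_counts`.
#' @export
acc <- function(true_structure, est_structure) {
  if (true_structure$J != est_structure$J)
    stop("structures must cover the same number of variables")
  if (true_structure$G != est_structure$G)
    stop("structures must have the same number of group factors")
  J <- true_structure$J; G <- true_structure$G
  counts <- matrix(0, G, G)
  for (a in seq_len(G)) for (b in seq_len(G)) {
    Ia <- true_structure$clusters[[a]]
    Ib <- est_structure$clusters[[b]]
    counts[a, b] <- length(intersect(Ia, Ib)) +
      (J - length(union(Ia, Ib)))
  }
  assignment <- solve_assignment(-counts)
  per_factor <- counts[cbind(seq_len(G), assignment)]
  structure(list(value = sum(per_factor) / (J * G),
                 best_permutation = assignment,
                 per_factor_counts = per_factor),
            class = "acc_match")
}

#' Selection correctness (SC)
#'
#' Indicator that the selected number of group factors equals the truth;
#' its average over replications is the selection accuracy.
#'
#' @param chosen_G selected number of group factors.
#' @param true_G true number of group factors.
#' @return 0 or 1.
#' @export
selection_correctness <- function(chosen_G, true_G) {
  as.numeric(chosen_G == true_G)
}

#' Hard thresholding of group loadings
#'
#' Sets group-column entries with absolute value below `tau` to zero,
#' leaving the general column untouched. The result need not satisfy the
#' bi-factor structure — several group loadings in one row may survive —
#' which is precisely the shortcoming of thresholding rotated solutions
#' that the constrained estimator avoids.
#'
#' @param loadings `J x (G+1)` loading matrix.
#' @param tau non-negative threshold.
#' @return thresholded loading matrix.
#' @export
hard_threshold <- function(loadings, tau) {
  stopifnot(tau >= 0)
  L <- as.matrix(loadings)
  B <- L[, -1, drop = FALSE]
  B[abs(B) < tau] <- 0
  L[, -1] <- B
  L
}

#' Identifiability check on a population model
#'
#' Sufficient condition for recovering the bi-factor structure from the
#' population covariance: every cluster has at least three variables with
#' nonzero group loadings, and at least three clusters have group loadings
#' linearly independent of (not proportional to) the corresponding general
#' loadings, checked as numerical rank 2 of the `|I_g| x 2` matrix
#' `[lambda_{I_g, general}, lambda_{I_g, g}]` (singular-value tolerance
#' `1e-8`).
#'
#' @param truth a `ground_truth` object (or a list with `params` and
#'   `structure`).
#' @return list with `satisfied` flag, the per-group diagnostics, and the
#'   failing groups.
#' @export
check_condition3 <- function(truth) {
  L <- truth$params$loadings
  st <- truth$structure
  G <- st$G
  size_ok <- logical(G)
  indep <- logical(G)
  for (g in seq_len(G)) {
    idx <- st$clusters[[g]]
    nz <- idx[L[idx, g + 1L] != 0]
    size_ok[g] <- length(nz) >= 3
    if (length(nz) >= 2) {
      m <- cbind(L[nz, 1], L[nz, g + 1L])
      sv <- svd(m, nu = 0, nv = 0)$d
      indep[g] <- length(sv) >= 2 && sv[2] > 1e-8 * max(sv[1], 1)
    } else {
      indep[g] <- FALSE
    }
  }
  satisfied <- all(size_ok) && sum(indep) >= 3
  list(satisfied = satisfied, cluster_size_ok = size_ok,
       independent = indep,
       failing_groups = which(!size_ok | !(indep | sum(indep) >= 3)))
}
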