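#' Unconstrained exploratory factor analysis fit (ML, echelon identification)
#'
#' Minimizes the same normal-theory discrepancy over a `J x K` loading
#' matrix with orthogonal factors (`Phi = I`) and positive uniquenesses.
#' Rotational indeterminacy is removed by the echelon constraint
#' `lambda_{jk} = 0` for `k > j`, which fixes the rotation without
#' restricting the model-implied covariance. Serves as the unconstrained
#' baseline against which the bi-factor BIC selection is compared.
#'
#' @param sample a [sample_covariance()] object.
#' @param K number of factors.
#' @param config an [alm_config()] object; only `n_starts`, `seed`,
#'   `inner_tol` and `inner_maxit` are used.
#' @return list with elements `loadings` (`J x K`, echelon zeros exact),
#'   `psi`, `loss`, and `start_objectives`.
#' @export
fit_efa <- function(sample, K, config = alm_config()) {
  sample <- as_sample_cov(sample)
  check_pd_sample(sample)
  J <- sample$J
  K <- as.integer(K)
  stopifnot(K >= 1)
  n_free <- sum(J - seq_len(K) + 1L)
  S <- sample$S; logdetS <- sample$logdetS

  fn <- function(th) {
    v <- .cpp_efa_objective(th, S, J, K, logdetS, FALSE)$value
    if (!is.finite(v)) 1e12 else v
  }
  gr <- function(th) {
    r <- .cpp_efa_objective(th, S, J, K, logdetS, TRUE)
    if (!isTRUE(r$ok)) return(rep(0, length(th)))
    g <- as.numeric(r$gradient)
    if (any(!is.finite(g))) g[!is.finite(g)] <- 0
    g
  }

  run_one <- function(th0) {
    best <- th0; best_f <- fn(th0); used <- 0L
    while (used < config$inner_maxit) {
      res <- stats::optim(best, fn, gr, method = "L-BFGS-B",
                          control = list(maxit = 200L,
                                         pgtol = config$inner_tol,
                                         factr = 10))
      used <- used + 200L
      if (res$value <= best_f) { best <- res$par; best_f <- res$value }
      if (max(abs(gr(best))) <= config$inner_tol) break
      if (res$convergence == 0) break
    }
    list(theta = best, value = best_f)
  }

  runs <- vector("list", config$n_starts)
  for (s in seq_len(config$n_starts)) {
    th0 <- with_seed(child_seed(config$seed, 100000L + s), {
      c(stats::runif(n_free, -1, 1), log(0.5 * diag(S)))
    })
    runs[[s]] <- run_one(th0)
  }
  objectives <- vapply(runs, `[[`, numeric(1), "value")
  best <- runs[[which.min(objectives)]]

  loadings <- matrix(0, J, K)
  pos <- 0L
  for (k in seq_len(K)) {
    loadings[k:J, k] <- best$theta[pos + seq_len(J - k + 1L)]
    pos <- pos + J - k + 1L
  }
  psi <- exp(best$theta[pos + seq_len(J)])
  list(loadings = loadings, psi = psi, loss = best$value,
       start_objectives = objectives, K = K, N = sample$N)
}
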