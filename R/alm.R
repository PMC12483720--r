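#' Solver configuration for the augmented Lagrangian method
#'
#' Tuning constants of the outer loop and the multi-start policy. Defaults
#' follow standard augmented-Lagrangian practice: start with a moderate
#' penalty weight, multiply it by `rho` only when the maximal constraint
#' violation failed to drop by the factor `gamma`, and cap it to keep the
#' inner problems well conditioned.
#'
#' @param mu0 initial penalty weight.
#' @param rho penalty growth factor (`> 1`).
#' @param gamma required violation-reduction factor (`0 < gamma < 1`).
#' @param mu_max penalty cap.
#' @param max_outer outer-iteration cap per run.
#' @param max_restarts restart cap after a non-converged run.
#' @param n_starts number of random starting points.
#' @param seed base seed for the per-start random streams.
#' @param eps_param parameter-change stopping threshold.
#' @param eps_struct structure-distance stopping threshold (also used to
#'   read off the estimated clusters).
#' @param inner_tol gradient-norm (max-abs) tolerance of the inner solver.
#' @param inner_maxit iteration cap per inner solve.
#' @param constraint_form `"pairwise"` or `"row_aggregate"`.
#' @param profile convenience preset: `"simulation"` sets
#'   `eps_param = 1e-4, eps_struct = 1e-3`; `"accurate"` sets
#'   `eps_param = 1e-5, eps_struct = 1e-4`. Explicit `eps_*` arguments
#'   override the profile.
#' @param verbose 0 = silent, 1 = per-outer-iteration trace (outer index,
#'   loss, max violation, distance, penalty weight).
#' @return An `alm_config` list.
#' @export
alm_config <- function(mu0 = 1, rho = 10, gamma = 0.25, mu_max = 1e8,
                       max_outer = 100, max_restarts = 3, n_starts = 50,
                       seed = 1L, eps_param = NULL, eps_struct = NULL,
                       inner_tol = 1e-7, inner_maxit = 500,
                       constraint_form = c("pairwise", "row_aggregate"),
                       profile = c("simulation", "accurate"),
                       verbose = 0) {
  profile <- match.arg(profile)
  constraint_form <- match.arg(constraint_form)
  defaults <- if (profile == "simulation") c(1e-4, 1e-3) else c(1e-5, 1e-4)
  eps_param <- eps_param %||% defaults[1]
  eps_struct <- eps_struct %||% defaults[2]
  stopifnot(rho > 1, gamma > 0, gamma < 1, mu0 > 0, mu_max >= mu0,
            max_outer >= 1, max_restarts >= 0, n_starts >= 1,
            eps_param > 0, eps_struct > 0, inner_tol > 0)
  structure(list(mu0 = mu0, rho = rho, gamma = gamma, mu_max = mu_max,
                 max_outer = as.integer(max_outer),
                 max_restarts = as.integer(max_restarts),
                 n_starts = as.integer(n_starts), seed = as.integer(seed),
                 eps_param = eps_param, eps_struct = eps_struct,
                 inner_tol = inner_tol, inner_maxit = as.integer(inner_maxit),
                 constraint_form = constraint_form, profile = profile,
                 verbose = verbose),
            class = "alm_config")
}

constraint_form_code <- function(form) if (form == "pairwise") 0L else 1L

n_constraints <- function(J, G, form) {
  if (G < 2) return(0L)
  if (form == "pairwise") as.integer(J * G * (G - 1) / 2) else as.integer(J)
}

#' Augmented Lagrangian objective
#'
#' `l(Sigma(params), S) + sum_k multiplier_k c_k + (mu/2) sum_k c_k^2`,
#' where `c` are the bi-factor constraint residuals of
#' [constraint_values()]. With zero multipliers and a feasible point this
#' reduces to the plain discrepancy.
#'
#' @param params a [bifactor_params()] object.
#' @param sample a [sample_covariance()] object.
#' @param multipliers Lagrange-multiplier vector aligned with
#'   [constraint_values()].
#' @param mu penalty weight.
#' @param constraint_form `"pairwise"` or `"row_aggregate"`.
#' @return scalar objective value.
#' @export
augmented_lagrangian <- function(params, sample, multipliers, mu,
                                 constraint_form = "pairwise") {
  sample <- as_sample_cov(sample)
  nc <- n_constraints(params$J, params$G, constraint_form)
  if (length(multipliers) != nc) stop_dim("multipliers", nc, length(multipliers))
  r <- .cpp_al_objective(pack_params(params), sample$S, params$J, params$G,
                         sample$logdetS, as.numeric(multipliers), mu,
                         constraint_form_code(constraint_form), FALSE)
  r$value
}

# Inner solve: unconstrained quasi-Newton minimization of the augmented
# Lagrangian at fixed multipliers and penalty weight, using the analytic
# gradient, stopping on a max-abs gradient tolerance (with an iteration
# cap). Returns theta plus diagnostics.
inner_minimize_theta <- function(theta, sample, J, G, multipliers, mu,
                                 form_code, inner_tol, inner_maxit) {
  S <- sample$S; logdetS <- sample$logdetS
  fn <- function(th) {
    v <- .cpp_al_objective(th, S, J, G, logdetS, multipliers, mu,
                           form_code, FALSE)$value
    if (!is.finite(v)) 1e12 else v
  }
  gr <- function(th) {
    r <- .cpp_al_objective(th, S, J, G, logdetS, multipliers, mu,
                           form_code, TRUE)
    if (!isTRUE(r$ok)) return(rep(0, length(th)))
    g <- as.numeric(r$gradient)
    if (any(!is.finite(g))) g[!is.finite(g)] <- 0
    g
  }
  f0 <- fn(theta)
  if (!is.finite(f0) || f0 >= 1e12)
    stop("non-finite objective at the starting point of an inner solve")
  used <- 0L
  best <- theta; best_f <- f0
  gmax <- Inf
  while (used < inner_maxit) {
    step <- min(200L, inner_maxit - used)
    res <- stats::optim(best, fn, gr, method = "L-BFGS-B",
                        control = list(maxit = step, pgtol = inner_tol,
                                       factr = 10))
    used <- used + step
    if (res$value <= best_f) { best <- res$par; best_f <- res$value }
    gmax <- max(abs(gr(best)))
    if (gmax <= inner_tol) break
    # converged by the solver's own projected-gradient / function-change
    # rule at a slightly larger gradient norm: accept rather than cycle
    if (res$convergence == 0 && gmax <= 1e3 * inner_tol) break
  }
  list(theta = best, value = best_f, grad_max = gmax,
       met_tol = gmax <= inner_tol)
}

#' Inner minimization of the augmented Lagrangian
#'
#' Runs the unconstrained quasi-Newton inner solve from the parameters in
#' `params` at fixed multipliers and penalty weight, returning the
#' (approximately) stationary parameters.
#'
#' @inheritParams augmented_lagrangian
#' @param config an [alm_config()] object.
#' @return a [bifactor_params()] object at an approximate stationary point.
#' @export
inner_minimize <- function(params, sample, multipliers, mu,
                           config = alm_config()) {
  sample <- as_sample_cov(sample)
  r <- inner_minimize_theta(pack_params(params), sample, params$J, params$G,
                            as.numeric(multipliers), mu,
                            constraint_form_code(config$constraint_form),
                            config$inner_tol, config$inner_maxit)
  unpack_params(r$theta, params$J, params$G)
}

#' First-order multiplier update
#'
#' `multiplier_k <- multiplier_k + mu * c_k` at the freshly inner-minimized
#' parameters, the standard first-order augmented-Lagrangian update.
#'
#' @param multipliers current multiplier vector.
#' @param mu current penalty weight.
#' @param cvec constraint residuals at the current parameters.
#' @return updated multiplier vector.
#' @export
update_multipliers <- function(multipliers, mu, cvec) {
  if (length(multipliers) != length(cvec))
    stop_dim("cvec", length(multipliers), length(cvec))
  multipliers + mu * cvec
}

#' Penalty-weight update
#'
#' Grows `mu` by the factor `rho` (capped at `mu_max`) only when the
#' maximal constraint violation failed to fall below `gamma` times its
#' previous value; otherwise leaves it unchanged, preventing the inner
#' problems from becoming ill-conditioned.
#'
#' @param mu current penalty weight.
#' @param violation current `max |c|`.
#' @param prev_violation previous `max |c|`.
#' @param config an [alm_config()] object.
#' @return updated penalty weight.
#' @export
update_penalty <- function(mu, violation, prev_violation, config = alm_config()) {
  if (violation > config$gamma * prev_violation)
    min(config$rho * mu, config$mu_max)
  else mu
}

#' Fit the bi-factor model from a single starting point
#'
#' One full augmented-Lagrangian run: alternates inner minimization,
#' multiplier update and penalty update until both the parameter change
#' falls below `eps_param` and the distance to the bi-factor set falls
#' below `eps_struct`. A run that exhausts `max_outer` outer iterations is
#' restarted from its current parameters with multipliers and penalty
#' reset, up to `max_restarts` times.
#'
#' @param sample a [sample_covariance()] object.
#' @param G number of group factors.
#' @param config an [alm_config()] object.
#' @param start a [bifactor_params()] starting point.
#' @return A `bifactor_fit` object (see [fit_multistart()]).
#' @export
fit_single_start <- function(sample, G, config = alm_config(), start) {
  sample <- as_sample_cov(sample)
  check_pd_sample(sample)
  J <- sample$J
  form <- config$constraint_form
  form_code <- constraint_form_code(form)
  nc <- n_constraints(J, G, form)

  theta <- pack_params(start)
  multipliers <- numeric(nc)
  mu <- config$mu0
  history <- list()
  converged <- FALSE
  restarts_used <- 0L
  prev_params <- start
  prev_violation <- Inf
  total_outer <- 0L

  repeat {
    outer <- 0L
    while (outer < config$max_outer) {
      outer <- outer + 1L; total_outer <- total_outer + 1L
      inner <- inner_minimize_theta(theta, sample, J, G, multipliers, mu,
                                    form_code, config$inner_tol,
                                    config$inner_maxit)
      theta <- inner$theta
      params <- unpack_params(theta, J, G)
      cvec <- constraint_values(params$loadings, form)
      viol <- if (nc > 0) max(abs(cvec)) else 0
      dist <- bifactor_distance(params$loadings)
      delta <- parameter_change(prev_params, params)
      loss <- .cpp_al_objective(theta, sample$S, J, G, sample$logdetS,
                                numeric(0), 0, 0L, FALSE)$loss
      history[[length(history) + 1L]] <-
        c(outer = total_outer, loss = loss, max_violation = viol,
          distance = dist, param_change = delta, mu = mu,
          grad_max = inner$grad_max)
      if (isTRUE(config$verbose >= 1))
        message(sprintf(
          "outer %3d | loss %.6g | max|c| %.3g | dist %.3g | mu %.3g",
          total_outer, loss, viol, dist, mu))
      if (delta < config$eps_param && dist < config$eps_struct) {
        converged <- TRUE
        break
      }
      multipliers <- update_multipliers(multipliers, mu, cvec)
      mu <- update_penalty(mu, viol, prev_violation, config)
      prev_violation <- viol
      prev_params <- params
    }
    if (converged || restarts_used >= config$max_restarts) break
    # restart from the current parameters with fresh auxiliary coefficients
    restarts_used <- restarts_used + 1L
    multipliers <- numeric(nc)
    mu <- config$mu0
    prev_violation <- Inf
  }

  params <- unpack_params(theta, J, G)
  loss <- discrepancy_loss(params, sample)
  structure_est <- if (converged)
    extract_structure(params$loadings, config$eps_struct)
  else NULL
  hist_df <- as.data.frame(do.call(rbind, history))
  structure(list(params = params, structure = structure_est, loss = loss,
                 converged = converged, restarts_used = restarts_used,
                 history = hist_df, G = G, N = sample$N,
                 is_correlation = sample$is_correlation,
                 config = config),
            class = "bifactor_fit")
}

# Random starting point: loadings i.i.d. Uniform(-1, 1), beta i.i.d.
# Uniform(-0.5, 0.5), psi_j = 0.5 * S_jj. Draws come from the current RNG
# stream; callers seed it per start.
random_start <- function(sample, G) {
  J <- sample$J
  loadings <- matrix(stats::runif(J * (G + 1L), -1, 1), J, G + 1L)
  beta <- stats::runif(G * (G - 1L) / 2L, -0.5, 0.5)
  bifactor_params(loadings, beta, 0.5 * diag(sample$S))
}

#' Fit the bi-factor model with multiple random starting points
#'
#' Runs [fit_single_start()] from `n_starts` seeded random starting points
#' and returns the converged run with the smallest discrepancy (ties go to
#' the earliest start). The constrained problem is non-convex, so
#' multi-start is the safeguard against local minima. Deterministic given
#' `config$seed`.
#'
#' @inheritParams fit_single_start
#' @return A `bifactor_fit` object with additional fields
#'   `start_objectives` (final discrepancy per start), `start_converged`,
#'   and `n_starts_used`. The winning solution is canonicalized with
#'   [identify_solution()].
#' @export
fit_multistart <- function(sample, G, config = alm_config()) {
  sample <- as_sample_cov(sample)
  check_pd_sample(sample)
  t0 <- proc.time()[["elapsed"]]
  fits <- vector("list", config$n_starts)
  for (s in seq_len(config$n_starts)) {
    start <- with_seed(child_seed(config$seed, s), random_start(sample, G))
    fits[[s]] <- fit_single_start(sample, G, config, start)
  }
  objectives <- vapply(fits, `[[`, numeric(1), "loss")
  conv <- vapply(fits, `[[`, logical(1), "converged")
  pick <- if (any(conv)) which(conv)[which.min(objectives[conv])]
  else which.min(objectives)
  best <- fits[[pick]]
  best$params <- identify_solution(best$params, config$eps_struct)
  if (best$converged)
    best$structure <- extract_structure(best$params$loadings,
                                        config$eps_struct)
  best$start_objectives <- objectives
  best$start_converged <- conv
  best$n_starts_used <- config$n_starts
  best$winning_start <- pick
  best$elapsed <- proc.time()[["elapsed"]] - t0
  best
}

#' @export
print.bifactor_fit <- function(x, ...) {
  cat("Exact bi-factor fit: J =", x$params$J, ", G =", x$G, "\n")
  cat("  discrepancy:", format(x$loss), "| converged:", x$converged, "\n")
  if (!is.null(x$n_starts_used))
    cat("  starts:", x$n_starts_used, "(", sum(x$start_converged),
        "converged ), winner = start", x$winning_start, "\n")
  if (!is.null(x$structure)) print(x$structure)
  invisible(x)
}

#' Canonicalize a fitted solution
#'
#' Any bi-factor solution is only identified up to column sign flips and a
#' relabeling of the group factors, both of which leave the model
#' covariance unchanged. This canonical form flips each factor so its
#' largest-absolute loading is positive (propagating the flip into the
#' factor correlations) and orders the group factors by the smallest
#' variable index in their cluster.
#'
#' @param params a [bifactor_params()] object.
#' @param eps_struct threshold used to read the clusters for ordering.
#' @return a [bifactor_params()] object with identical model covariance.
#' @export
identify_solution <- function(params, eps_struct = 1e-3) {
  L <- params$loadings
  J <- params$J; G <- params$G
  Phi <- build_phi(params$beta, G)
  # sign flips
  d <- vapply(seq_len(G + 1L), function(k) {
    i <- which.max(abs(L[, k]))
    if (L[i, k] < 0) -1 else 1
  }, numeric(1))
  L <- sweep(L, 2, d, `*`)
  Phi <- diag(d) %*% Phi %*% diag(d)
  # order group factors by smallest member variable index
  first_idx <- vapply(seq_len(G), function(g) {
    members <- which(abs(L[, g + 1L]) > eps_struct)
    if (length(members) == 0) Inf else min(members)
  }, numeric(1))
  ord <- order(first_idx, seq_len(G))
  perm <- c(1L, 1L + ord)
  L <- L[, perm, drop = FALSE]
  Phi <- Phi[perm, perm, drop = FALSE]
  # recover beta for the permuted correlation block via Cholesky
  beta <- phi_to_beta(Phi[-1, -1, drop = FALSE])
  bifactor_params(L, beta, params$psi)
}

# Invert the row-normalized Cholesky map: given a PD correlation matrix,
# recover the beta vector reproducing it exactly.
phi_to_beta <- function(PhiG) {
  G <- nrow(PhiG)
  if (G < 2) return(numeric(0))
  Lc <- t(chol(PhiG))       # lower triangular with positive diagonal
  beta <- numeric(G * (G - 1) / 2)
  pos <- 0L
  for (i in 2:G) {
    beta[pos + seq_len(i - 1L)] <- Lc[i, seq_len(i - 1L)] / Lc[i, i]
    pos <- pos + i - 1L
  }
  beta
}
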