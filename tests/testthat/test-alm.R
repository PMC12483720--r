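test_that("augmented Lagrangian value decomposes as loss + multiplier + penalty", {
  p <- rand_params(4, 2, seed = 3)
  s <- rand_sample(4, 2, N = 300, seed = 4)
  nc <- ebifactor:::n_constraints(4, 2, "pairwise")
  # zero multipliers at an exactly feasible point: equals the loss
  truth <- generate_exact_model(simulation_design(J = 4, G = 2, seed = 5),
                                require_condition3 = FALSE)
  expect_equal(augmented_lagrangian(truth$params, s, numeric(nc), mu = 7),
               discrepancy_loss(truth$params, s))
  # arithmetic: single constraint c = 0.3 with multiplier 2 and mu = 4
  L <- cbind(c(1, 1), rbind(c(0.5, 0.6), c(0.4, 0)))
  pc <- suppressWarnings(bifactor_params(L, beta = 0, psi = c(1, 1)))
  s2 <- sample_covariance(matrix(c(2, 0.5, 0.5, 1.5), 2, 2), N = 100)
  cvec <- constraint_values(L, "pairwise")
  expect_equal(cvec, c(0.3, 0))
  expect_equal(augmented_lagrangian(pc, s2, c(2, 0), mu = 4),
               discrepancy_loss(pc, s2) + 2 * 0.3 + (4 / 2) * 0.09)
  # quadratic penalty dominates as mu grows at an infeasible point
  v1 <- augmented_lagrangian(pc, s2, c(0, 0), mu = 1e2)
  v2 <- augmented_lagrangian(pc, s2, c(0, 0), mu = 1e6)
  expect_gt(v2, v1)
  expect_equal(v2 - v1, (1e6 - 1e2) / 2 * sum(cvec^2))
})

test_that("augmented Lagrangian gradient matches finite differences", {
  worst <- 0
  for (i in 1:25) {
    J <- sample(4:6, 1); G <- 2
    p <- rand_params(J, G, seed = 600 + i)
    s <- rand_sample(J, G, N = 300, seed = 700 + i)
    form <- if (i %% 2 == 0) 0L else 1L
    nc <- if (form == 0L) J * G * (G - 1) / 2 else J
    set.seed(800 + i)
    mult <- runif(nc, -1, 1); mu <- runif(1, 0.5, 20)
    th <- ebifactor:::pack_params(p)
    obj <- function(t) ebifactor:::.cpp_al_objective(
      t, s$S, J, G, s$logdetS, mult, mu, form, FALSE)$value
    g <- as.numeric(ebifactor:::.cpp_al_objective(
      th, s$S, J, G, s$logdetS, mult, mu, form, TRUE)$gradient)
    fd <- fd_gradient(obj, th)
    worst <- max(worst, max(abs(g - fd) / pmax(abs(fd), 1e-4)))
  }
  expect_lt(worst, 1e-5)
})

test_that("multiplier and penalty updates follow the first-order rules", {
  expect_equal(update_multipliers(0, mu = 2, cvec = 0.3), 0.6)
  expect_equal(update_multipliers(c(1, -1), 2, c(0, 0)), c(1, -1))
  expect_equal(update_multipliers(c(1, 2), 10, c(0.1, -0.2)), c(2, 0))

  cfg <- alm_config(rho = 10, gamma = 0.25, mu_max = 50)
  expect_equal(update_penalty(1, violation = 0.2, prev_violation = 1, cfg), 1)
  expect_equal(update_penalty(1, violation = 0.9, prev_violation = 1, cfg), 10)
  expect_equal(update_penalty(50, violation = 0.9, prev_violation = 1, cfg), 50)
})

test_that("inner solver is a descent method reaching its gradient tolerance", {
  truth <- generate_exact_model(simulation_design(J = 6, G = 2, seed = 21),
                                require_condition3 = FALSE)
  pop <- population_input(truth)
  cfg <- alm_config()
  nc <- ebifactor:::n_constraints(6, 2, "pairwise")
  # starting at the population solution with zero multipliers: stays there
  out <- inner_minimize(truth$params, pop, numeric(nc), mu = 1, cfg)
  expect_equal(out$loadings, truth$params$loadings, tolerance = 1e-4)

  # from a random start, the final objective cannot exceed the initial one
  # and the gradient meets the tolerance on this well-behaved instance
  p0 <- rand_params(6, 2, seed = 22)
  s <- rand_sample(6, 2, N = 500, seed = 23)
  set.seed(24); mult <- runif(nc, -0.1, 0.1)
  v0 <- augmented_lagrangian(p0, s, mult, mu = 2)
  p1 <- inner_minimize(p0, s, mult, mu = 2, cfg)
  v1 <- augmented_lagrangian(p1, s, mult, mu = 2)
  expect_lte(v1, v0)
  g <- ebifactor:::.cpp_al_objective(
    ebifactor:::pack_params(p1), s$S, 6L, 2L, s$logdetS, mult, 2, 0L, TRUE)
  expect_lt(max(abs(as.numeric(g$gradient))), cfg$inner_tol * 10)
})

test_that("a single run recovers the structure from the population covariance", {
  truth <- generate_exact_model(simulation_design(J = 15, G = 3, seed = 31))
  pop <- population_input(truth)
  start <- with(list(), {
    set.seed(32); ebifactor:::random_start(pop, 3)
  })
  fit <- fit_single_start(pop, 3, alm_config(), start)
  expect_true(fit$converged)
  expect_lt(bifactor_distance(fit$params$loadings), alm_config()$eps_struct)
  # run log shows the violation driven to feasibility
  expect_lt(tail(fit$history$max_violation, 1), alm_config()$eps_struct)
  if (emc(truth$structure, fit$structure) == 1) {
    expect_lt(loading_mse(truth$params$loadings, fit$params$loadings), 1e-4)
  }
})

test_that("G = 1 degenerates to an unconstrained fit with empty constraints", {
  truth <- generate_exact_model(simulation_design(J = 6, G = 1, seed = 41),
                                require_condition3 = FALSE)
  fit <- fit_multistart(population_input(truth), 1,
                        alm_config(n_starts = 3, seed = 1))
  expect_true(fit$converged)
  expect_equal(fit$loss, 0, tolerance = 1e-6)
  expect_length(constraint_values(fit$params$loadings), 0)
})

test_that("multistart is deterministic and returns the best converged run", {
  truth <- generate_exact_model(simulation_design(J = 9, G = 3, seed = 51))
  s <- sample_dataset(truth, N = 300, seed = 52)$sample
  cfg <- alm_config(n_starts = 4, seed = 99)
  f1 <- fit_multistart(s, 3, cfg)
  f2 <- fit_multistart(s, 3, cfg)
  expect_identical(f1$params$loadings, f2$params$loadings)
  expect_identical(f1$start_objectives, f2$start_objectives)
  expect_equal(f1$loss, min(f1$start_objectives[f1$start_converged]))
  expect_true(all(f1$loss <= f1$start_objectives[f1$start_converged] + 1e-12))
})

test_that("converged fits are feasible in distance and raw violation", {
  cfg <- alm_config(n_starts = 3, seed = 7)
  for (seed in c(61, 62, 63)) {
    truth <- generate_exact_model(simulation_design(J = 12, G = 3, seed = seed))
    s <- sample_dataset(truth, N = 400, seed = seed + 100)$sample
    fit <- fit_multistart(s, 3, cfg)
    expect_true(fit$converged)
    expect_lt(bifactor_distance(fit$params$loadings), cfg$eps_struct)
    cvec <- constraint_values(fit$params$loadings, cfg$constraint_form)
    expect_lt(max(abs(cvec)), 10 * cfg$eps_struct^2)
  }
})

test_that("canonicalization fixes signs and ordering without changing the model", {
  truth <- generate_exact_model(simulation_design(J = 12, G = 3, seed = 71))
  p <- truth$params
  # scramble: flip two columns, swap group factors
  perm <- c(1, 3, 4, 2); d <- c(-1, 1, -1, 1)
  Phi <- build_phi(p$beta, 3)
  L2 <- sweep(p$loadings[, perm], 2, d, `*`)
  Phi2 <- diag(d) %*% Phi[perm, perm] %*% diag(d)
  p2 <- bifactor_params(L2, ebifactor:::phi_to_beta(Phi2[-1, -1]), p$psi)
  expect_equal(model_covariance(p2), model_covariance(p), tolerance = 1e-12)

  canon <- identify_solution(p2)
  expect_equal(model_covariance(canon), model_covariance(p), tolerance = 1e-12)
  canon_p <- identify_solution(p)
  expect_equal(canon$loadings, canon_p$loadings, tolerance = 1e-12)
  # idempotent
  expect_equal(identify_solution(canon)$loadings, canon$loadings)
  # canonical signs: largest-absolute loading per column positive
  for (k in 1:4) {
    col <- canon$loadings[, k]
    expect_gte(col[which.max(abs(col))], 0)
  }
})

test_that("penalty weight stays bounded when the run converges", {
  truth <- generate_exact_model(simulation_design(J = 12, G = 3, seed = 81))
  s <- sample_dataset(truth, N = 500, seed = 82)$sample
  fit <- fit_multistart(s, 3, alm_config(n_starts = 2, seed = 3))
  expect_true(fit$converged)
  expect_lt(max(fit$history$mu), alm_config()$mu_max)
})
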