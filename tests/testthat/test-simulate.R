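test_that("exact models have one group loading per row within the stated ranges", {
  d <- simulation_design(J = 15, G = 3, seed = 7)
  truth <- generate_exact_model(d)
  B <- truth$params$loadings[, -1]
  expect_true(all(rowSums(B != 0) == 1))
  expect_equal(bifactor_distance(truth$params$loadings), 0)
  expect_true(all(abs(B[B != 0]) >= d$group_range[1] &
                    abs(B[B != 0]) <= d$group_range[2]))
  g0 <- truth$params$loadings[, 1]
  expect_true(all(g0 >= d$general_range[1] & g0 <= d$general_range[2]))
  expect_equal(truth$params$psi, rep(d$psi_value, 15))

  # seeded reproducibility
  truth2 <- generate_exact_model(d)
  expect_identical(truth$params$loadings, truth2$params$loadings)
})

test_that("approximate models perturb only off-cluster loadings, boundedly", {
  d <- simulation_design(J = 15, G = 3, seed = 8, perturb_range = c(0, 0.1))
  truth <- generate_approx_model(d)
  expect_false(truth$is_exact)
  expect_gt(bifactor_distance(truth$params$loadings), 0)
  B <- truth$params$loadings[, -1]
  for (g in 1:3) {
    off <- setdiff(1:15, truth$structure$clusters[[g]])
    expect_true(all(abs(B[off, g]) <= 0.1))
    expect_true(all(abs(B[truth$structure$clusters[[g]], g]) >= 0.5))
  }
  # zero-width perturbation degenerates to the exact generator
  d0 <- simulation_design(J = 15, G = 3, seed = 8, perturb_range = c(0, 0))
  expect_equal(bifactor_distance(generate_approx_model(d0)$params$loadings), 0)
})

test_that("sampled datasets are reproducible with consistent covariances", {
  truth <- generate_exact_model(simulation_design(J = 6, G = 2, seed = 9),
                                require_condition3 = FALSE)
  ds1 <- sample_dataset(truth, N = 100, seed = 5)
  ds2 <- sample_dataset(truth, N = 100, seed = 5)
  expect_identical(ds1$data, ds2$data)
  S <- ds1$sample$S
  expect_equal(S, t(S))
  expect_gte(min(eigen(S, only.values = TRUE)$values), 0)

  # Monte-Carlo consistency: the sample covariance approaches the truth
  e3 <- max(abs(sample_dataset(truth, N = 1e3, seed = 6)$sample$S -
                  truth$population_cov))
  e5 <- max(abs(sample_dataset(truth, N = 1e5, seed = 6)$sample$S -
                  truth$population_cov))
  expect_lt(e5, e3)
  expect_lt(e5, 0.05)
})

test_that("population input wraps a low-rank-plus-diagonal matrix", {
  truth <- generate_exact_model(simulation_design(J = 12, G = 3, seed = 10))
  pop <- population_input(truth, N = 750)
  expect_false(pop$is_correlation)
  expect_equal(pop$N, 750L)
  low_rank <- pop$S - diag(truth$params$psi)
  expect_lte(qr(low_rank)$rank, 4)
})

test_that("generated designs with blocks of three or more satisfy the identifiability check", {
  for (i in 1:100) {
    truth <- generate_exact_model(simulation_design(J = 9, G = 3,
                                                    seed = 2000 + i))
    expect_true(check_condition3(truth)$satisfied)
  }
})

test_that("generator draws follow the configured uniform distributions", {
  # pool general loadings across many seeded models: Uniform(0.5, 1.5)
  draws <- unlist(lapply(1:300, function(i)
    generate_exact_model(simulation_design(J = 12, G = 3, seed = 4000 + i),
                         require_condition3 = FALSE)$params$loadings[, 1]))
  n <- length(draws)
  se_mean <- sqrt(1 / 12) / sqrt(n)
  expect_lt(abs(mean(draws) - 1), 3 * se_mean)
  expect_lt(abs(var(draws) - 1 / 12), 3 * sqrt(1 / 180) / sqrt(n))
})

test_that("invalid designs are rejected", {
  expect_error(simulation_design(J = 10, G = 3), "divisible")
  expect_error(simulation_design(J = 6, G = 2,
                                 clusters = list(1:3, 3:6)), "partition")
})
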