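test_that("constraint residuals vanish exactly on bi-factor rows", {
  L <- cbind(1, rbind(c(0.8, 0, 0), c(0, -0.5, 0), c(0, 0, 0.3)))
  expect_equal(constraint_values(L, "pairwise"), rep(0, 9))
  expect_equal(constraint_values(L, "row_aggregate"), rep(0, 3))

  L2 <- cbind(1, matrix(c(1, 2, 0), 1))
  expect_equal(sort(constraint_values(L2, "pairwise")), c(0, 0, 2))

  L3 <- cbind(1, matrix(c(1, 2, 3), 1))
  expect_equal(constraint_values(L3, "row_aggregate"), 4 + 9 + 36)

  # G = 1: no constraints
  expect_length(constraint_values(cbind(1, 1:3)), 0)
})

test_that("second_largest follows the screening convention", {
  expect_equal(second_largest(c(3, 0.5, 0.1)), 0.5)
  expect_equal(second_largest(c(0.2, 0.2)), 0.2)
  expect_equal(second_largest(0.7), 0)
  expect_equal(second_largest(numeric(0)), 0)
})

test_that("bifactor distance is zero exactly on the bi-factor set", {
  truth <- generate_exact_model(simulation_design(J = 12, G = 3, seed = 5))
  expect_equal(bifactor_distance(truth$params$loadings), 0)

  L <- cbind(1, rbind(c(0.5, 0.1), c(0.05, 0.02)))
  expect_equal(bifactor_distance(L), 0.1)

  # monotone: zeroing an entry never increases the distance
  set.seed(6)
  for (i in 1:50) {
    L <- cbind(1, matrix(runif(12, -1, 1), 4, 3))
    d0 <- bifactor_distance(L)
    j <- sample(4, 1); g <- sample(2:4, 1)
    L[j, g] <- 0
    expect_lte(bifactor_distance(L), d0 + 1e-15)
  }
})

test_that("zero constraints, zero distance and row sparsity coincide", {
  set.seed(9)
  for (i in 1:500) {
    J <- sample(3:8, 1); G <- sample(2:4, 1)
    B <- matrix(runif(J * G, -1, 1), J, G)
    if (i %% 2 == 0) {
      # make it exactly bi-factor
      keep <- sample(G, J, replace = TRUE)
      B <- B * outer(seq_len(J), seq_len(G),
                     function(j, g) as.numeric(keep[j] == g))
    }
    L <- cbind(1, B)
    c_zero <- all(constraint_values(L, "pairwise") == 0)
    d_zero <- bifactor_distance(L) == 0
    sparse <- all(rowSums(B != 0) <= 1)
    expect_equal(c_zero, sparse)
    expect_equal(d_zero, sparse)
    expect_equal(all(constraint_values(L, "row_aggregate") == 0), sparse)
  }
})

test_that("structure extraction assigns, leaves unassigned, and stays disjoint", {
  L <- cbind(1, rbind(c(0.9, 0.001), c(0.004, 0.002), c(0.0005, 0.8)))
  st <- extract_structure(L, eps_struct = 0.01)
  expect_equal(st$clusters[[1]], 1L)
  expect_equal(st$clusters[[2]], 3L)
  expect_equal(st$unassigned, 2L)

  # disjointness whenever the precondition holds
  set.seed(10)
  for (i in 1:100) {
    truth <- generate_exact_model(
      simulation_design(J = 12, G = 3, seed = 1000 + i),
      require_condition3 = FALSE)
    st <- extract_structure(truth$params$loadings, 1e-3)
    expect_equal(anyDuplicated(unlist(st$clusters)), 0)
  }
})

test_that("extraction is invariant to column permutation and sign flips", {
  truth <- generate_exact_model(simulation_design(J = 12, G = 3, seed = 42))
  L <- truth$params$loadings
  st <- extract_structure(L, 1e-3)
  perm <- c(1, 4, 2, 3)
  L2 <- sweep(L[, perm], 2, c(1, -1, 1, -1), `*`)
  st2 <- extract_structure(L2, 1e-3)
  expect_equal(st2$clusters[[match(2, perm) - 1L]], st$clusters[[1]])
  expect_equal(st2$clusters[[match(3, perm) - 1L]], st$clusters[[2]])
  expect_equal(st2$clusters[[match(4, perm) - 1L]], st$clusters[[3]])
})

test_that("extraction from a far-from-feasible matrix warns", {
  L <- cbind(1, rbind(c(0.5, 0.4), c(0.3, 0.3)))
  expect_warning(extract_structure(L, eps_struct = 0.01), "distance")
})

test_that("parameter change is a norm-like divergence of iterates", {
  p <- rand_params(5, 2, seed = 1)
  expect_equal(parameter_change(p, p), 0)

  q <- p
  q$loadings[2, 2] <- q$loadings[2, 2] + 0.37
  expect_equal(parameter_change(p, q), 0.37)

  r <- rand_params(5, 2, seed = 2)
  expect_lte(parameter_change(p, r),
             parameter_change(p, q) + parameter_change(q, r) + 1e-12)
})
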