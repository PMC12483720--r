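test_that("loading MSE is invariant to sign flips and relabeling", {
  truth <- generate_exact_model(simulation_design(J = 12, G = 3, seed = 14))
  Tm <- truth$params$loadings
  expect_equal(loading_mse(Tm, Tm), 0)

  Em <- sweep(Tm[, c(1, 3, 2, 4)], 2, c(1, -1, 1, -1), `*`)
  expect_equal(loading_mse(Tm, Em), 0)

  Em2 <- Tm; Em2[4, 2] <- Em2[4, 2] + 0.2
  expect_equal(loading_mse(Tm, Em2), 0.04 / (12 * 4))
})

test_that("assignment-based MSE equals the exhaustive permutation/sign search", {
  set.seed(15)
  for (i in 1:100) {
    J <- sample(4:8, 1); G <- sample(2:5, 1)
    Tm <- matrix(runif(J * (G + 1), -1, 1), J, G + 1)
    Em <- Tm + matrix(rnorm(J * (G + 1), 0, 0.3), J, G + 1)
    expect_equal(loading_mse(Tm, Em), brute_mse(Tm, Em), tolerance = 1e-12)
  }
})

test_that("EMC detects exact recovery up to relabeling and nothing weaker", {
  ts <- bifactor_structure(list(1:5, 6:10, 11:15), 15)
  relab <- bifactor_structure(list(11:15, 1:5, 6:10), 15)
  expect_equal(emc(ts, relab), 1)

  moved <- bifactor_structure(list(c(1:4, 6), c(5, 7:10), 11:15), 15)
  expect_equal(emc(ts, moved), 0)
  expect_warning(
    out <- emc(ts, bifactor_structure(list(1:5, 6:15), 15)),
    "different numbers")
  expect_equal(out, 0)
})

test_that("the per-factor correctness count matches the 15-item illustration", {
  # true cluster of the first group factor: items 1-5 of 15
  ts <- bifactor_structure(list(1:5, 6:10, 11:15), 15)
  perfect <- acc(ts, ts)
  expect_equal(perfect$per_factor_counts[1], 15)
  expect_equal(perfect$value, 1)

  # imperfect estimate: item 5 missed, item 6 wrongly included
  es <- bifactor_structure(list(c(1, 2, 3, 4, 6), c(5, 7, 8, 9, 10), 11:15),
                           15)
  m <- acc(ts, es)
  expect_equal(m$per_factor_counts[1], 13)
})

test_that("assignment-based ACC equals brute force and dominates EMC", {
  set.seed(16)
  for (i in 1:100) {
    J <- sample(8:15, 1); G <- sample(2:5, 1)
    ts <- rand_structure(J, G, seed = 3000 + i)
    es <- rand_structure(J, G, seed = 6000 + i)
    m <- acc(ts, es)
    expect_equal(m$value, brute_acc(ts, es), tolerance = 1e-12)
    expect_gte(m$value, 0); expect_lte(m$value, 1)
    e <- suppressWarnings(emc(ts, es))
    if (e == 1) expect_equal(m$value, 1)
    if (m$value == 1) expect_equal(e, 1)
  }
})

test_that("ACC and EMC are invariant to simultaneous relabeling", {
  ts <- rand_structure(12, 3, seed = 17)
  es <- rand_structure(12, 3, seed = 18)
  perm <- c(3, 1, 2)
  tsp <- bifactor_structure(ts$clusters[perm], 12)
  esp <- bifactor_structure(es$clusters[perm], 12)
  expect_equal(acc(ts, es)$value, acc(tsp, esp)$value)
  expect_equal(emc(ts, es), emc(tsp, esp))
})

test_that("selection correctness is the equality indicator", {
  expect_equal(selection_correctness(3, 3), 1)
  expect_equal(selection_correctness(2, 3), 0)
  expect_equal(mean(selection_correctness(c(3, 3, 2, 4), 3)), 0.5)
})

test_that("hard thresholding zeroes small group loadings only", {
  L <- cbind(c(1, 1), rbind(c(0.3, 0.25), c(0.1, -0.05)))
  expect_equal(hard_threshold(L, 0), L)
  out <- hard_threshold(L, 0.2)
  expect_equal(out[1, 2:3], c(0.3, 0.25))  # both survive: not bi-factor
  expect_equal(out[2, 2:3], c(0, 0))
  expect_equal(out[, 1], c(1, 1))
  expect_equal(hard_threshold(L, 10)[, 2:3], matrix(0, 2, 2))
})

test_that("the identifiability checker counts cluster sizes and independence", {
  truth <- generate_exact_model(simulation_design(J = 9, G = 3, seed = 19))
  expect_true(check_condition3(truth)$satisfied)

  # a cluster of two variables fails
  small <- list(params = truth$params,
                structure = bifactor_structure(list(1:2, 3:6, 7:9), 9))
  expect_false(check_condition3(small)$satisfied)

  # proportional group loadings do not count toward the three
  p <- truth$params
  idx <- truth$structure$clusters[[2]]
  p$loadings[idx, 3] <- 2 * p$loadings[idx, 1]  # exact scalar multiple
  prop <- list(params = p, structure = truth$structure)
  res <- check_condition3(prop)
  expect_false(res$independent[2])
  expect_false(res$satisfied)
})
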