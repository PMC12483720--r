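# Shared fixtures and independent oracles for the test suite.

# random parameters with psi bounded away from zero
rand_params <- function(J, G, seed) {
  set.seed(seed)
  bifactor_params(matrix(runif(J * (G + 1), -1, 1), J, G + 1),
                  beta = runif(G * (G - 1) / 2, -1, 1),
                  psi = runif(J, 0.5, 2))
}

rand_sample <- function(J, G, N = 500, seed = 1) {
  clusters <- split(seq_len(J), rep(seq_len(G), length.out = J))
  truth <- generate_exact_model(
    simulation_design(J = J, G = G, clusters = unname(clusters), seed = seed),
    require_condition3 = FALSE)
  sample_dataset(truth, N = N, seed = seed + 1)$sample
}

# central finite-difference gradient of an arbitrary scalar function of theta
fd_gradient <- function(f, theta, h = 1e-6) {
  vapply(seq_along(theta), function(i) {
    e <- numeric(length(theta)); e[i] <- h
    (f(theta + e) - f(theta - e)) / (2 * h)
  }, numeric(1))
}

# all permutations of 1..n (n small)
all_perms <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in all_perms(n - 1L))
    for (k in seq_len(n))
      out[[length(out) + 1L]] <- append(p, n, after = k - 1L)
  out
}

# exhaustive minimum of ||T - E D P||_F^2 / (J(G+1)) over group-column
# permutations P and all 2^(G+1) sign flips D
brute_mse <- function(Tm, Em) {
  J <- nrow(Tm); G <- ncol(Tm) - 1L
  best <- Inf
  signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), G + 1L)))
  for (p in all_perms(G)) {
    E2 <- Em[, c(1L, 1L + unlist(p)), drop = FALSE]
    for (r in seq_len(nrow(signs))) {
      E3 <- sweep(E2, 2, signs[r, ], `*`)
      best <- min(best, sum((Tm - E3)^2))
    }
  }
  best / (J * (G + 1L))
}

# exhaustive ACC over all label permutations
brute_acc <- function(ts, es) {
  J <- ts$J; G <- ts$G
  best <- -Inf
  for (p in all_perms(G)) {
    tot <- sum(vapply(seq_len(G), function(g) {
      Ia <- ts$clusters[[g]]; Ib <- es$clusters[[unlist(p)[g]]]
      length(intersect(Ia, Ib)) + (J - length(union(Ia, Ib)))
    }, numeric(1)))
    best <- max(best, tot)
  }
  best / (J * G)
}

# random structure: each variable assigned to a group (or unassigned with
# probability p0)
rand_structure <- function(J, G, seed, p0 = 0.1) {
  set.seed(seed)
  assign <- sample(0:G, J, replace = TRUE,
                   prob = c(p0, rep((1 - p0) / G, G)))
  bifactor_structure(lapply(seq_len(G), function(g) which(assign == g)), J)
}
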