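#' Simulation design for bi-factor population models
#'
#' Defines the data-generating conditions for the recovery and selection
#' studies: cluster layout, the Uniform ranges of the general and group
#' loading magnitudes, the Bernoulli sign probability of group loadings,
#' the Uniform range of the off-cluster perturbations (zero width gives an
#' exact bi-factor model), the Uniform range of the unconstrained
#' correlation parameters, and a common uniqueness value.
#'
#' @param J number of variables.
#' @param G number of group factors.
#' @param N sample size for generated datasets.
#' @param clusters `"equal_blocks"` (contiguous blocks of `J/G` variables)
#'   or an explicit list of `G` disjoint index vectors covering `1..J`.
#' @param general_range Uniform range of general-factor loadings.
#' @param group_range Uniform range of group-loading magnitudes.
#' @param sign_prob probability that a group loading is positive.
#' @param perturb_range Uniform range of off-cluster loading magnitudes in
#'   the approximate model (width 0 recovers the exact model).
#' @param beta_range Uniform range of the correlation parameters `beta`.
#' @param psi_value common uniqueness value.
#' @param seed seed of the model-generating stream.
#' @return A `simulation_design` list.
#' @export
simulation_design <- function(J = 15, G = 3, N = 200,
                              clusters = "equal_blocks",
                              general_range = c(0.5, 1.5),
                              group_range = c(0.5, 1.5),
                              sign_prob = 0.5,
                              perturb_range = c(0, 0.1),
                              beta_range = c(-1, 1),
                              psi_value = 1,
                              seed = 1L) {
  stopifnot(J >= 2, G >= 1, N >= 1,
            length(general_range) == 2, diff(general_range) >= 0,
            length(group_range) == 2, diff(group_range) >= 0,
            sign_prob >= 0, sign_prob <= 1,
            length(perturb_range) == 2, diff(perturb_range) >= 0,
            perturb_range[1] >= 0,
            length(beta_range) == 2, diff(beta_range) >= 0,
            psi_value > 0)
  if (identical(clusters, "equal_blocks")) {
    if (J %% G != 0)
      stop("J must be divisible by G for equal_blocks clusters")
    size <- J %/% G
    clusters <- lapply(seq_len(G), function(g) ((g - 1L) * size + 1L):(g * size))
  } else {
    clusters <- lapply(clusters, as.integer)
    if (length(clusters) != G) stop("clusters must list G index sets")
    if (!setequal(unlist(clusters), seq_len(J)) ||
        anyDuplicated(unlist(clusters)))
      stop("clusters must partition 1..J")
  }
  structure(list(J = as.integer(J), G = as.integer(G), N = as.integer(N),
                 clusters = clusters, general_range = general_range,
                 group_range = group_range, sign_prob = sign_prob,
                 perturb_range = perturb_range, beta_range = beta_range,
                 psi_value = psi_value, seed = as.integer(seed)),
            class = "simulation_design")
}

draw_model <- function(design, exact) {
  J <- design$J; G <- design$G
  loadings <- matrix(0, J, G + 1L)
  loadings[, 1] <- stats::runif(J, design$general_range[1],
                                design$general_range[2])
  sgn <- function(n) ifelse(stats::runif(n) < design$sign_prob, 1, -1)
  for (g in seq_len(G)) {
    idx <- design$clusters[[g]]
    loadings[idx, g + 1L] <- sgn(length(idx)) *
      stats::runif(length(idx), design$group_range[1], design$group_range[2])
  }
  if (!exact) {
    for (g in seq_len(G)) {
      off <- setdiff(seq_len(J), design$clusters[[g]])
      loadings[off, g + 1L] <- sgn(length(off)) *
        stats::runif(length(off), design$perturb_range[1],
                     design$perturb_range[2])
    }
  }
  beta <- stats::runif(G * (G - 1L) / 2L, design$beta_range[1],
                       design$beta_range[2])
  bifactor_params(loadings, beta, rep(design$psi_value, J))
}

finish_truth <- function(params, design, exact) {
  structure(list(params = params,
                 structure = bifactor_structure(design$clusters, design$J),
                 population_cov = model_covariance(params),
                 is_exact = exact, design = design),
            class = "ground_truth")
}

#' Generate an exact bi-factor population model
#'
#' General loadings are i.i.d. Uniform on `general_range`; each variable's
#' single group loading has magnitude i.i.d. Uniform on `group_range` with
#' a Bernoulli(`sign_prob`) sign; all other group loadings are exactly
#' zero; the correlation parameters are i.i.d. Uniform on `beta_range`;
#' all uniquenesses equal `psi_value`. Models failing the identifiability
#' check of [check_condition3()] are redrawn (with the retry count
#' reported), which for generic draws essentially never triggers when every
#' cluster has at least three variables.
#'
#' @param design a [simulation_design()] with zero-width `perturb_range`
#'   (the perturbation range is ignored here).
#' @param require_condition3 redraw until [check_condition3()] passes?
#'   Defaults to `TRUE` when `G >= 3` (the condition cannot hold with fewer
#'   groups).
#' @return A `ground_truth` object: true parameters, true structure, the
#'   population covariance, and the design.
#' @export
generate_exact_model <- function(design, require_condition3 = design$G >= 3) {
  with_seed(design$seed, {
    for (try in 1:100) {
      params <- draw_model(design, exact = TRUE)
      truth <- finish_truth(params, design, exact = TRUE)
      if (!require_condition3 || check_condition3(truth)$satisfied) {
        if (try > 1)
          message("condition-3 resampling: ", try - 1L, " redraw(s)")
        return(truth)
      }
    }
    stop("could not generate a model satisfying the identifiability check")
  })
}

#' Generate an approximate bi-factor population model
#'
#' As [generate_exact_model()], but every off-cluster group loading gets a
#' small perturbation with magnitude i.i.d. Uniform on `perturb_range` and
#' random sign, so the true loading matrix violates the exact bi-factor
#' structure. The recorded true structure is the pre-perturbation one.
#'
#' @param design a [simulation_design()] with positive-width
#'   `perturb_range`.
#' @inheritParams generate_exact_model
#' @return A `ground_truth` object with `is_exact = FALSE`.
#' @export
generate_approx_model <- function(design, require_condition3 = design$G >= 3) {
  if (diff(design$perturb_range) <= 0 && design$perturb_range[2] == 0)
    return(generate_exact_model(design, require_condition3))
  with_seed(design$seed, {
    for (try in 1:100) {
      params <- draw_model(design, exact = FALSE)
      truth <- finish_truth(params, design, exact = FALSE)
      exact_part <- params
      exact_part$loadings[, -1][abs(exact_part$loadings[, -1]) <=
                                  design$perturb_range[2]] <- 0
      cond <- !require_condition3 ||
        check_condition3(finish_truth(exact_part, design, TRUE))$satisfied
      if (cond) {
        if (try > 1)
          message("condition-3 resampling: ", try - 1L, " redraw(s)")
        return(truth)
      }
    }
    stop("could not generate a model satisfying the identifiability check")
  })
}

#' Sample a multivariate-normal dataset from a population model
#'
#' Draws `N` i.i.d. mean-zero multivariate normal observations with the
#' model's population covariance and forms the sample covariance with the
#' maximum-likelihood (`1/N`) denominator by default.
#'
#' @param truth a `ground_truth` object.
#' @param N number of observations (defaults to the design's `N`).
#' @param seed seed of the data stream (distinct replications of the same
#'   population model vary only this seed).
#' @param denominator `"N"` or `"N-1"`.
#' @return list with `data` (`N x J` matrix) and `sample`
#'   (a [sample_covariance()] object).
#' @export
sample_dataset <- function(truth, N = truth$design$N, seed = 1L,
                           denominator = c("N", "N-1")) {
  denominator <- match.arg(denominator)
  J <- truth$design$J
  if (N < J) warning("N < J: the sample covariance will be singular")
  x <- with_seed(seed,
                 MASS::mvrnorm(N, mu = rep(0, J),
                               Sigma = truth$population_cov))
  list(data = x, sample = compute_sample_cov(x, denominator))
}

#' Use the population covariance itself as input
#'
#' Wraps the true covariance `Sigma_0` as the input matrix, enabling
#' population-recovery checks: at the population, the global solutions of
#' the constrained problem recover the true structure exactly (up to sign
#' flips and relabeling). `N` is only needed nominally for BIC.
#'
#' @param truth a `ground_truth` object.
#' @param N nominal sample size.
#' @return a [sample_covariance()] object.
#' @export
population_input <- function(truth, N = 1000L) {
  sample_covariance(truth$population_cov, N, is_correlation = FALSE)
}
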