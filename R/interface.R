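#' Exact exploratory bi-factor analysis
#'
#' High-level entry point. Takes either raw observations (data frame or
#' matrix, one row per observation) or a covariance/correlation matrix,
#' fits the extended bi-factor model with `G` group factors by
#' constrained maximum likelihood (augmented Lagrangian with multiple
#' random starts), and returns the canonicalized solution with its
#' extracted structure. Works with pipes; inspect results with
#' [generics::tidy()], [generics::glance()] and [ggplot2::autoplot()].
#'
#' @param x data frame or numeric matrix of observations, or a `J x J`
#'   covariance/correlation matrix when `input` is not `"data"`.
#' @param G number of group factors.
#' @param input `"data"`, `"covariance"` or `"correlation"`.
#' @param N sample size; required for covariance/correlation input.
#' @param n_starts number of random starting points.
#' @param seed base seed.
#' @param profile `"simulation"` or `"accurate"` tolerance preset.
#' @param config optional full [alm_config()]; overrides the shortcut
#'   arguments.
#' @param denominator covariance denominator for raw-data input.
#' @return a `bifactor_fit` object.
#' @examples
#' \donttest{
#' truth <- generate_exact_model(simulation_design(J = 12, G = 3, seed = 7))
#' fit <- ebifa(population_input(truth), G = 3, input = "covariance",
#'              N = 500, n_starts = 3)
#' glance(fit)
#' }
#' @export
ebifa <- function(x, G, input = c("data", "covariance", "correlation"),
                  N = NULL, n_starts = 50, seed = 1L,
                  profile = c("simulation", "accurate"), config = NULL,
                  denominator = "N") {
  input <- match.arg(input)
  profile <- match.arg(profile)
  config <- config %||% alm_config(n_starts = n_starts, seed = seed,
                                   profile = profile)
  sample <- if (inherits(x, "sample_cov")) x
  else load_sample(as.matrix(x), if (input == "data") "data" else input,
                   N, denominator)
  fit_multistart(sample, G, config)
}

#' Select the number of group factors from data
#'
#' Convenience wrapper around [select_num_groups()] with the same input
#' handling as [ebifa()].
#'
#' @inheritParams ebifa
#' @param candidates integer vector of candidate numbers of group factors.
#' @return an `ebifa_selection` object.
#' @export
ebifa_select <- function(x, candidates,
                         input = c("data", "covariance", "correlation"),
                         N = NULL, n_starts = 50, seed = 1L,
                         profile = c("simulation", "accurate"),
                         config = NULL, denominator = "N") {
  input <- match.arg(input)
  profile <- match.arg(profile)
  config <- config %||% alm_config(n_starts = n_starts, seed = seed,
                                   profile = profile)
  sample <- if (inherits(x, "sample_cov")) x
  else load_sample(as.matrix(x), if (input == "data") "data" else input,
                   N, denominator)
  select_num_groups(sample, candidates, config)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a bi-factor fit into a long tibble of loadings
#'
#' One row per variable-factor pair: variable index, factor label
#' (`general` or `group_g`), estimated loading, and whether the variable
#' belongs to that factor's cluster.
#'
#' @param x a `bifactor_fit` object.
#' @param ... unused.
#' @return a tibble.
#' @export
tidy.bifactor_fit <- function(x, ...) {
  L <- x$params$loadings
  J <- nrow(L); G <- ncol(L) - 1L
  st <- x$structure
  labels <- c("general", paste0("group_", seq_len(G)))
  out <- tibble::tibble(
    variable = rep(seq_len(J), G + 1L),
    factor = rep(labels, each = J),
    loading = as.numeric(L))
  member <- matrix(FALSE, J, G + 1L)
  member[, 1] <- TRUE
  if (!is.null(st))
    for (g in seq_len(G)) member[st$clusters[[g]], g + 1L] <- TRUE
  out$in_cluster <- as.logical(member)
  out
}

#' One-row summary of a bi-factor fit
#'
#' @param x a `bifactor_fit` object.
#' @param ... unused.
#' @return a tibble with the discrepancy, BIC, convergence flag, numbers
#'   of starts and converged starts, and the distance to the bi-factor
#'   set.
#' @export
glance.bifactor_fit <- function(x, ...) {
  tibble::tibble(
    J = x$params$J, G = x$G, N = x$N,
    loss = x$loss,
    bic = bic_bifactor(x$loss, x$N, x$G),
    converged = x$converged,
    n_starts = x$n_starts_used %||% 1L,
    n_converged_starts = sum(x$start_converged %||% x$converged),
    bifactor_distance = bifactor_distance(x$params$loadings))
}

#' Tidy a BIC selection table
#'
#' @param x an `ebifa_selection` object.
#' @param ... unused.
#' @return a tibble with one row per candidate `G`.
#' @export
tidy.ebifa_selection <- function(x, ...) {
  tibble::tibble(
    G = x$candidate_G,
    loss = x$loss_values,
    penalty = (x$candidate_G * (x$candidate_G - 1) / 2) * log(x$N),
    bic = x$bic_values,
    chosen = x$candidate_G == x$chosen_G)
}

#' Loading heat map of a bi-factor fit
#'
#' Variables on the vertical axis, factors on the horizontal, fill mapped
#' to the signed loading; cluster membership outlined.
#'
#' @param object a `bifactor_fit` object.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.bifactor_fit <- function(object, ...) {
  d <- tidy(object)
  d$factor <- factor(d$factor, levels = unique(d$factor))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$factor,
                                  y = factor(.data$variable,
                                             levels = rev(seq_len(object$params$J))),
                                  fill = .data$loading)) +
    ggplot2::geom_tile(color = "grey70") +
    ggplot2::geom_tile(data = d[d$in_cluster, ], fill = NA,
                       color = "black", linewidth = 0.4) +
    ggplot2::scale_fill_gradient2(low = "#2166AC", mid = "white",
                                  high = "#B2182B", midpoint = 0) +
    ggplot2::labs(x = NULL, y = "variable", fill = "loading") +
    ggplot2::theme_minimal()
}

#' BIC curve of a selection sweep
#'
#' @param object an `ebifa_selection` object.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.ebifa_selection <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$G, y = .data$bic)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(ggplot2::aes(color = .data$chosen), size = 3) +
    ggplot2::scale_color_manual(values = c(`FALSE` = "grey40",
                                           `TRUE` = "#B2182B"),
                                guide = "none") +
    ggplot2::labs(x = "number of group factors G", y = "BIC") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 .data
NULL
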