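#' BIC of a fitted bi-factor model
#'
#' `N * loss + (G(G-1)/2) * log N`. Since `N * loss` differs from twice the
#' negative log-likelihood by a constant not depending on the parameters,
#' and the counts of nonzero loadings (`2J`) and uniquenesses (`J`) are the
#' same for every number of group factors, the only parameter count that
#' varies with `G` is the `G(G-1)/2` free correlations; all constant terms
#' cancel in BIC comparisons and are dropped.
#'
#' @param fit a `bifactor_fit` object (or any list with a `loss` element).
#' @param N sample size.
#' @param G number of group factors.
#' @return scalar BIC value (up to a `G`-independent additive constant).
#' @export
bic_bifactor <- function(fit, N, G) {
  if (is.list(fit) && !is.null(fit$converged) && !isTRUE(fit$converged))
    warning("computing BIC from a non-converged fit")
  loss <- if (is.list(fit)) fit$loss else as.numeric(fit)
  N * loss + (G * (G - 1) / 2) * log(N)
}

#' Select the number of group factors by BIC
#'
#' Fits each candidate `G` by [fit_multistart()] and picks the candidate
#' with the smallest BIC (smallest `G` on ties). Candidates whose fit fails
#' entirely are excluded with a warning.
#'
#' @param sample a [sample_covariance()] object.
#' @param candidates integer vector of candidate numbers of group factors.
#' @param config an [alm_config()] object applied to every candidate.
#' @return An `ebifa_selection` object: `candidate_G`, `bic_values`,
#'   `loss_values`, `chosen_G`, and the per-candidate fits.
#' @export
select_num_groups <- function(sample, candidates, config = alm_config()) {
  sample <- as_sample_cov(sample)
  candidates <- sort(unique(as.integer(candidates)))
  stopifnot(length(candidates) >= 1, all(candidates >= 1))
  fits <- vector("list", length(candidates))
  ok <- logical(length(candidates))
  for (i in seq_along(candidates)) {
    fits[[i]] <- tryCatch(fit_multistart(sample, candidates[i], config),
                          error = function(e) e)
    ok[i] <- inherits(fits[[i]], "bifactor_fit")
    if (!ok[i])
      warning("fit failed for G = ", candidates[i], ": ",
              conditionMessage(fits[[i]]))
  }
  if (!any(ok)) stop("all candidate fits failed")
  loss_values <- ifelse(ok, vapply(fits, function(f)
    if (inherits(f, "bifactor_fit")) f$loss else NA_real_, numeric(1)), NA_real_)
  bic_values <- ifelse(ok, sample$N * loss_values +
                         (candidates * (candidates - 1) / 2) * log(sample$N),
                       NA_real_)
  chosen <- candidates[ok][which.min(bic_values[ok])]
  structure(list(candidate_G = candidates, bic_values = bic_values,
                 loss_values = loss_values, chosen_G = chosen,
                 fits = fits, ok = ok, N = sample$N),
            class = "ebifa_selection")
}

#' @export
print.ebifa_selection <- function(x, ...) {
  cat("BIC selection of the number of group factors\n")
  tab <- data.frame(G = x$candidate_G, loss = x$loss_values,
                    BIC = x$bic_values)
  print(tab, row.names = FALSE)
  cat("chosen G:", x$chosen_G, "\n")
  invisible(x)
}

#' BIC of an exploratory factor analysis fit
#'
#' `N * loss + (J*K - K(K-1)/2) * log N`: the free-loading count under the
#' echelon identification. The `J` uniquenesses appear in every candidate
#' and are dropped, as only BIC differences matter.
#'
#' @param loss discrepancy value of the `K`-factor EFA fit.
#' @param N sample size.
#' @param J number of variables.
#' @param K number of factors.
#' @return scalar BIC value (up to a `K`-independent additive constant).
#' @export
bic_efa <- function(loss, N, J, K) {
  N * loss + (J * K - K * (K - 1) / 2) * log(N)
}

#' Select the number of group factors via unconstrained EFA + BIC
#'
#' The baseline selector: fits ordinary (non-bi-factor) exploratory factor
#' models for each candidate factor count `K`, picks `K` by BIC, and
#' returns `K - 1` as the implied number of group factors (a bi-factor
#' model with `G` group factors spans `G + 1` factor dimensions). Unlike
#' the bi-factor BIC, this baseline pays a penalty proportional to `J` per
#' extra factor, which makes it prone to under-selection at small sample
#' sizes.
#'
#' @param sample a [sample_covariance()] object.
#' @param candidates_K integer vector of candidate numbers of EFA factors.
#' @param config an [alm_config()] object.
#' @return list with `candidate_K`, `bic_values`, `loss_values`,
#'   `chosen_K`, and `chosen_G = chosen_K - 1`.
#' @export
bic_efa_select <- function(sample, candidates_K, config = alm_config()) {
  sample <- as_sample_cov(sample)
  candidates_K <- sort(unique(as.integer(candidates_K)))
  stopifnot(length(candidates_K) >= 1, all(candidates_K >= 1))
  losses <- numeric(length(candidates_K))
  for (i in seq_along(candidates_K))
    losses[i] <- fit_efa(sample, candidates_K[i], config)$loss
  bic <- bic_efa(losses, sample$N, sample$J, candidates_K)
  chosen_K <- candidates_K[which.min(bic)]
  list(candidate_K = candidates_K, bic_values = bic, loss_values = losses,
       chosen_K = chosen_K, chosen_G = chosen_K - 1L, N = sample$N)
}
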