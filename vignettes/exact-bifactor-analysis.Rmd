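---
title: "Exact exploratory bi-factor analysis: model, algorithm, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Exact exploratory bi-factor analysis: model, algorithm, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ebifactor)
```

## The model

The extended (oblique) bi-factor model for `J` observed variables assumes
one general factor, loaded by every variable, and `G` group factors, each
loaded by a disjoint cluster of variables. With loading matrix
$\Lambda \in \mathbb{R}^{J \times (G+1)}$ (column 1 = general factor),
factor correlation matrix $\Phi$ and diagonal uniqueness matrix $\Psi$,
the population covariance is

$$\Sigma = \Lambda \Phi \Lambda^\top + \Psi.$$

Two structural restrictions define the model. First, the general factor is
uncorrelated with every group factor ($\Phi_{1,g} = 0$), which is needed
for identifiability of the oblique variant; the group factors themselves
may correlate freely. Second, each variable loads on **at most one** group
factor. In confirmatory bi-factor analysis the variable-to-group
assignment is specified in advance. The exploratory problem treated here
is to *learn* that assignment from data.

The key observation is that the combinatorial structure "at most one
nonzero group loading per row" is exactly the zero set of a family of
smooth equality constraints: for every variable $j$ and every pair of
group factors $g < g'$,

$$\lambda_{jg}\,\lambda_{jg'} = 0.$$

This converts a discrete model-search problem (the number of candidate
structures grows exponentially in `J`) into a continuous constrained
optimization problem:

$$\min_{\Lambda, \Phi, \Psi}\; l(\Sigma(\Lambda,\Phi,\Psi), S)
  \quad\text{s.t.}\quad \lambda_{jg}\lambda_{jg'} = 0 \;\;\forall j,\; g<g',$$

where $S$ is the sample covariance (or correlation) matrix and $l$ is the
normal-theory discrepancy

$$l(\Sigma, S) = \log\det\Sigma + \operatorname{tr}(S\Sigma^{-1})
  - \log\det S - J.$$

`N * l` differs from twice the negative log-likelihood by a constant that
does not depend on the parameters, so minimizing `l` is maximum-likelihood
estimation. The two subtracted constants are a normalization convention
that makes the minimum exactly zero when the model can reproduce `S`; all
constants cancel in optimization and in BIC comparisons (a property the
test suite verifies numerically).

### Unconstrained parameterization

The inner problems must be smooth and unconstrained, so the two
constrained blocks are reparameterized:

* **Factor correlations.** The group block of $\Phi$ is written as
  $L L^\top$, where row $i$ of the lower-triangular $L$ is
  $(\beta_{i,1}, \ldots, \beta_{i,i-1}, 1)$ rescaled to unit norm. Any
  finite $\beta \in \mathbb{R}^{G(G-1)/2}$ produces a valid (strictly
  positive definite) correlation matrix, and the map is smooth and
  surjective, with an exact inverse through the Cholesky factorization
  (used when canonicalizing solutions). Any smooth surjective
  parameterization of the correlation manifold would do; this
  row-normalized construction is the standard one and is what the package
  commits to.
* **Uniquenesses.** $\psi_j = e^{\omega_j}$ with $\omega_j$ free, which
  enforces positivity without box constraints. Degenerate (Heywood-type)
  runs can drive $\omega_j$ very low; reported values are floored at
  `1e-100` purely to avoid numerical underflow when unpacking.

Analytic gradients flow through both maps by the chain rule and are
implemented, together with the discrepancy itself, in compiled code
(RcppArmadillo). The test suite checks them against central finite
differences on dozens of random instances at `1e-5` relative accuracy.

## The augmented Lagrangian solver

Writing $c(\Lambda)$ for the vector of constraint residuals, outer
iteration `t` of the solver minimizes (quasi-Newton, analytic gradients)

$$l(\Sigma(\theta), S) + \sum_k \tilde\lambda_k c_k(\Lambda)
  + \frac{\mu}{2}\sum_k c_k(\Lambda)^2$$

over the unconstrained parameter vector $\theta$, then applies the
standard first-order updates: multipliers
$\tilde\lambda_k \leftarrow \tilde\lambda_k + \mu\, c_k$, and penalty
$\mu \leftarrow \min(\rho\mu, \mu_{\max})$ *only if* the maximal violation
failed to fall below $\gamma$ times its previous value. Growing $\mu$ only
on stalls keeps the inner problems well conditioned; the multiplier term
is what lets the iterates converge to a feasible point without $\mu \to
\infty$.

Two criteria stop the outer loop, both required simultaneously:

1. **parameter change** — the Frobenius norm of the loading change plus
   the Frobenius norm of the correlation change plus the Euclidean norm of
   the uniqueness change falls below `eps_param` (this unnormalized sum of
   block norms is the package's convention; thresholds are calibrated to
   it);
2. **structure distance** — `max_j` of the *second-largest* absolute group
   loading in row `j` falls below `eps_struct`. When this holds, each row
   has at most one group loading above `eps_struct`, so thresholding at
   `eps_struct` reads off a well-defined partition: cluster $\hat I_g$
   collects the variables whose loading on group factor `g` exceeds the
   threshold, and variables below it everywhere are general-factor-only.

A run that exhausts `max_outer` outer iterations restarts from its current
parameters with multipliers reset to zero and $\mu$ reset to $\mu_0$ (up
to `max_restarts` times). The constrained problem is non-convex, so
`fit_multistart()` runs the whole procedure from `n_starts` seeded random
starting points (loadings i.i.d. Uniform(−1, 1), $\beta$ i.i.d.
Uniform(−0.5, 0.5), $\psi_j = 0.5\,S_{jj}$) and keeps the converged run
with the smallest discrepancy. Solutions are reported in a canonical form:
each factor's sign is flipped so its largest-absolute loading is positive,
and group factors are ordered by the smallest variable index in their
cluster — both operations leave $\Sigma$ unchanged, which is exactly the
sign/label indeterminacy of the model.

### Tuning parameters

| parameter | default | meaning |
|---|---|---|
| `mu0` | 1 | initial penalty weight |
| `rho` | 10 | penalty growth factor on stalls |
| `gamma` | 0.25 | required violation-reduction factor |
| `mu_max` | 1e8 | penalty cap (conditioning guard) |
| `max_outer` | 100 | outer iterations per run |
| `max_restarts` | 3 | restarts after a non-converged run |
| `n_starts` | 50 | random starting points |
| `inner_tol` | 1e-7 | max-abs gradient tolerance of inner solves |
| `eps_param`, `eps_struct` | 1e-4, 1e-3 | stopping thresholds ("simulation" profile) |

These follow standard augmented-Lagrangian practice; performance is robust
to moderate changes. The `"accurate"` profile (`eps_param = 1e-5`,
`eps_struct = 1e-4`) is intended for real-data analyses where a more
reliable structure read-off is worth extra iterations. Both constraint
encodings are available: the default `"pairwise"` bilinear residuals give
one multiplier per (variable, factor-pair) and are better conditioned; the
`"row_aggregate"` quartic form ($c_j = \sum_{g<g'}
\lambda_{jg}^2\lambda_{jg'}^2$, one constraint per variable) is offered
for comparison. Both vanish exactly on the bi-factor set.

The inner solver is deliberately specified as a *contract* rather than a
named algorithm: any smooth unconstrained quasi-Newton scheme with
analytic gradients and a gradient-norm stopping rule qualifies. The
implementation uses L-BFGS-B (without active bounds) for its built-in
projected-gradient tolerance, re-invoked until the max-abs gradient falls
below `inner_tol` or the per-solve iteration cap (500) is reached.

## Selecting the number of group factors

For candidate `G`, the nonzero-loading count (`2J`) and uniqueness count
(`J`) do not depend on `G`; only the `G(G−1)/2` free factor correlations
do. Dropping all `G`-independent constants,

$$\mathrm{BIC}(G) = N\, l^*_G + \frac{G(G-1)}{2}\,\log N,$$

minimized over a candidate set (smallest `G` on ties — a parsimony
tie-break the package commits to, since exact ties are otherwise
undefined). The baseline selector fits ordinary exploratory factor
models with `K` orthogonal factors under the echelon identification
($\lambda_{jk} = 0$ for $k > j$, which removes rotational freedom without
restricting $\Sigma$), uses

$$\mathrm{BIC}_{\mathrm{EFA}}(K) = N\, l^*_K +
  \Big(JK - \frac{K(K-1)}{2}\Big) \log N,$$

and reports $\hat K - 1$ as the implied number of group factors (a
bi-factor model with `G` group factors spans `G+1` factor dimensions).
The uniqueness count, common to all `K`, is dropped. Because the EFA
penalty grows by roughly `J log N` per factor while the bi-factor penalty
grows only by `(G−1) log N` per group factor, the unconstrained baseline
under-selects at small sample sizes — the behaviour the selection
experiment verifies.

## The synthetic-data generator

`simulation_design()` + `generate_exact_model()` build population models:
contiguous equal blocks of `J/G` variables per group factor (arbitrary
partitions accepted); general loadings i.i.d. Uniform(0.5, 1.5); group
loadings with magnitude i.i.d. Uniform(0.5, 1.5) and Bernoulli(0.5) sign;
correlation parameters $\beta$ i.i.d. Uniform(−1, 1); all uniquenesses
equal to 1. `generate_approx_model()` additionally gives every off-cluster
group loading a magnitude i.i.d. Uniform(0, 0.1) with random sign, so the
true loading matrix is *near* but not *on* the bi-factor set — the
misspecified regime in which the estimator still always returns an exact
bi-factor structure. Datasets are i.i.d. mean-zero multivariate normal
draws from the population covariance; the sample covariance uses the
maximum-likelihood `1/N` denominator by default (`1/(N−1)` selectable).
Models with fewer than three variables per cluster, or without three
group factors whose loadings are linearly independent of the general
loadings, fail the identifiability check (`check_condition3()`) and are
redrawn; for generic Uniform draws with blocks of three or more this
essentially never triggers.

The recovery and selection experiments use two designs, `(J, G) = (15, 3)`
and `(30, 5)`, with sample sizes `N = 200` (small) and `N = 2000` (large),
generating the population model once per setting and varying only the
data seed across replications. The test suite runs desk-scale versions: 20
replications per setting with multistart budgets of 10–20 starts
(selection sweeps use 12 starts per candidate, the EFA baseline 8), and
checks the observed success counts against 95% binomial intervals around
the expected rates rather than point values. Full-scale runs (100
replications, 50 starts) are a matter of changing two arguments.

What the generator deliberately does **not** emulate: non-normal or
ordinal/dichotomous responses, unequal uniquenesses, unequal cluster
sizes, missing data, and structured rather than i.i.d. perturbations.
Passing tests therefore demonstrate correctness of the estimator and its
selection behaviour *under the stated sampling model*, not robustness to
real-data departures from it.

## Structure-recovery metrics

Estimated structures are only identified up to relabeling of the group
factors and sign flips of any factor, so all metrics optimize over these:

* **loading MSE** — $\min_{P, D} \|\Lambda^* - \hat\Lambda D P\|_F^2 /
  (J(G+1))$ over group-column permutations `P` and per-column sign flips
  `D`. The per-pair sign-optimal costs decouple, so the exact optimum is a
  linear assignment problem, solved with an in-package Hungarian
  algorithm; the tests assert exact agreement with exhaustive search over
  all $G!\,2^{G+1}$ combinations. Dividing by the number of loading
  entries is this package's normalization; constant factors do not affect
  method comparisons.
* **EMC** — 1 iff some relabeling makes every estimated cluster identical
  to the true one.
* **ACC** — best-relabeling proportion of correctly classified zero/nonzero
  group loadings, $\max_\sigma \frac{1}{JG}\sum_g |I_g \cap
  \hat I_{\sigma(g)}| + |I_g^c \cap \hat I_{\sigma(g)}^c|$, again solved
  by assignment with a brute-force oracle in the tests. Variables left
  unassigned by the structure read-off count as zero group loadings
  everywhere, which breaks EMC unless the truth leaves them unassigned
  too.
* **SC** — indicator that the selected `G` equals the truth.

`hard_threshold()` is provided for evaluating externally produced
(rotation-style) loading matrices: it zeroes small group loadings but —
unlike the constrained estimator — cannot guarantee the result is a
bi-factor structure.

## Numerical choices and edge cases

* `second_largest()` of a length-0 or length-1 vector is 0, so `G = 1`
  models are trivially feasible and the solver degenerates to an
  unconstrained two-column ML fit.
* Ties at structure read-off (two loadings above `eps_struct` in one row)
  can only occur when the feasibility criterion has not been met;
  extraction then warns and assigns to the largest absolute loading,
  lowest column index on exact ties.
* A singular sample covariance is rejected with its minimum eigenvalue
  reported (use correlation input or a ridge); model covariances are
  always positive definite by construction ($\psi > 0$).
* Non-finite inner objectives (overshooting line searches) are mapped to a
  large finite value so the quasi-Newton solver backtracks.
* All randomness is derived from explicit seeds: per-start streams are
  seeded from `config$seed` and the start index, and the package restores
  the caller's RNG state after every internal draw.

## A worked example

```{r example, eval = FALSE}
set.seed(1)
truth <- generate_exact_model(simulation_design(J = 15, G = 3, N = 500,
                                                seed = 7))
x <- sample_dataset(truth, seed = 8)
fit <- ebifa(x$data, G = 3, n_starts = 10, seed = 9)
glance(fit)
emc(truth$structure, fit$structure)
sel <- ebifa_select(x$data, candidates = 2:4, n_starts = 10, seed = 9)
tidy(sel)
```

## Known limitations

* The constrained problem is non-convex; multistart mitigates but cannot
  certify global optimality. Selection sweeps inherit this: a candidate
  whose multistart misses the global minimum can distort BIC comparisons,
  which is why the selection budget should not be cut too aggressively.
* Only the normal-theory discrepancy ships; the interface isolates the
  loss so a least-squares variant could be added, but none is provided.
* Inequality-relaxed constraints ($|\lambda_{jg}\lambda_{jg'}| \le c$) and
  hierarchical (higher-order) factor structures are out of scope.
* The BIC values are reported up to `G`-independent constants; they are
  comparable across candidates on the same sample, not across samples.
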