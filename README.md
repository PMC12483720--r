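# ebifactor

Exact exploratory bi-factor analysis by constrained maximum likelihood.

## The problem

Bi-factor models are a workhorse of psychological and educational
measurement (and of any multivariate setting with one dominant dimension
plus clustered residual structure): every observed variable loads on a
general factor, and each variable loads on at most one of *G* (possibly
correlated) group factors. Confirmatory bi-factor analysis requires the
variable-to-group assignment to be known in advance. When it is not, the
classical exploratory option — rotating an unconstrained factor solution
toward a bi-factor pattern and hard-thresholding small loadings — does
not in general produce an *exact* bi-factor structure: some variables
keep sizeable loadings on several group factors at once, and no threshold
can fix that.

`ebifactor` learns an exact structure directly. The bi-factor pattern is
characterized by bilinear equality constraints on the loading matrix
Λ ∈ ℝ^{J×(G+1)}:

> λ_{jg} · λ_{jg'} = 0 for every variable j and every pair g < g' of
> group factors,

which hold exactly iff each row of the group block has at most one
nonzero entry. The estimator solves

> min over (Λ, Φ, Ψ) of l(ΛΦΛᵀ + Ψ, S) subject to those constraints,

where S is the sample covariance (or correlation) matrix and
l(Σ, S) = log det Σ + tr(SΣ⁻¹) − log det S − J is the normal-theory
discrepancy (N·l = −2 log-likelihood up to a constant). The constrained
problem is solved with an augmented Lagrangian method: a sequence of
smooth unconstrained quasi-Newton minimizations (analytic gradients,
compiled hot path) with first-order multiplier updates and a guarded
penalty schedule, run from many random starting points. Group-factor
correlations are kept on the correlation manifold by a row-normalized
Cholesky parameterization and uniquenesses positive by a log
parameterization, so the inner problems are genuinely unconstrained. At
convergence each variable has at most one group loading above the
feasibility threshold, so the estimated structure is read off directly —
no post-hoc thresholding step.

The number of group factors is selected by BIC,
N·l\*\_G + (G(G−1)/2)·log N, with an unconstrained exploratory-factor-
analysis BIC as the reference baseline. The package also ships the full
simulation engine (exact and approximate bi-factor population models) and
the structure-recovery metrics — loading MSE up to column permutation and
sign flips (exact, via optimal assignment), the exact match criterion
(EMC), the average correctness criterion (ACC), and selection correctness
(SC).

## A worked example

```r
library(ebifactor)

truth <- generate_exact_model(simulation_design(J = 15, G = 3, N = 500,
                                                seed = 7))
x <- sample_dataset(truth, seed = 8)

fit <- ebifa(x$data, G = 3, n_starts = 10, seed = 9)
glance(fit)
#> # A tibble: 1 × 9
#>       J     G     N  loss   bic converged n_starts n_converged_starts
#>   <int> <dbl> <int> <dbl> <dbl> <lgl>        <int>              <int>
#> 1    15     3   500 0.115  76.1 TRUE            10                 10

fit$structure
#> Bi-factor structure: J = 15 , G = 3
#>   group 1: 1 2 3 4 5
#>   group 2: 6 7 8 9 10
#>   group 3: 11 12 13 14 15

emc(truth$structure, fit$structure)
#> [1] 1
```

The fitted discrepancy (0.115) is the normal-theory distance between the
model-implied and sample covariance — zero would mean a perfect
reproduction of S — and all 10 random starts converged to feasible
bi-factor solutions. The extracted clusters match the generating
partition exactly (EMC = 1). Selecting G instead of fixing it:

```r
sel <- ebifa_select(x$data, candidates = 2:4, n_starts = 10, seed = 9)
tidy(sel)
#> # A tibble: 3 × 5
#>       G  loss penalty   bic chosen
#>   <int> <dbl>   <dbl> <dbl> <lgl>
#> 1     2 0.597    6.21 305.  FALSE
#> 2     3 0.115   18.6   76.1 TRUE
#> 3     4 0.106   37.3   90.2 FALSE
```

G = 3 wins: going from 2 to 3 group factors buys a large drop in misfit,
while going to 4 buys almost nothing and pays a bigger penalty.
`autoplot(fit)` draws the loading heat map with the estimated clusters
outlined; `autoplot(sel)` draws the BIC curve. A thin command-line
wrapper with `fit`, `select`, `simulate` and `evaluate` verbs lives in
`inst/cli/ebifa.R`.

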