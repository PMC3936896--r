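# chainedimp

Chained-equations (fully conditional specification) and joint-model
multiple imputation for mixed binary/continuous data, with a diagnostic
for **order effects** — systematic dependence of the imputation
distribution on the sequence in which variables are updated.

## Why

Chained equations imputes each incomplete variable from its own
conditional regression, cycling through the variables; joint modelling
draws the missing data from the posterior predictive of a single
parametric model.  The two coincide when the conditionals are
compatible with the joint model **and** each variable's
conditional-model parameter is a priori independent of the parameter of
the remaining variables' margin (the *non-informative margins*
condition) — then chained equations is a genuine Gibbs sampler and the
visit order cannot matter.  The condition holds for the multivariate
normal model (via the Schur determinant identity
|Σ| = ω_j·|Σ̃_j|) and the saturated multinomial with Dirichlet prior,
but fails for the general location model — one binary Y and continuous
W with W | Y ~ N(μ₀ + μ₁Y, Σ) — because the margin of W is a normal
mixture that determines the logistic parameters of Y | W.  There,
chained equations with perfectly compatible logistic + linear
conditionals can impute from a distribution that depends on the visit
order.

This package implements both samplers for that design, an augmented
chain that fits the analysis model (OLS of W₂ on W₁ and Y) after every
single-variable update, batch-means Monte Carlo standard errors for the
resulting order-effect estimate β̄_b − β̄_c, executable checks of the
non-informative-margins identities, and a driver for the full
simulation study (500 datasets of n = 100, Y ~ Bern(3/10),
W₁ | Y ~ N(10 + βY, 9), W₂ | W₁, Y ~ N(9 + 8/9 + W₁/9 + βY, 8 + 8/9),
Y and W₁ missing completely at random in the first 50 rows).

## Worked example

One dataset from the study design at β = 3, imputed three ways:

```r
library(chainedimp)
d <- simulate_masked(sim_config(beta = 3, seed = 7))
d
#> md_dataset: 100 subjects x 3 variables
#>   Y        binary       50 missing
#>   W1       continuous   50 missing
#>   W2       continuous    0 missing

complete_case_estimate(d)            # OLS on the 50 complete rows
#> 2.096

completed <- run_data_augmentation(d, m = 100, burn_in = 100,
                                   thin = 100, seed = 8)
pool_estimates(completed)            # joint-model (gold standard)
#> 1.769

specs <- list(conditional_spec("Y",  c("W1", "W2"), "logistic_mvn"),
              conditional_spec("W1", c("Y", "W2"),  "normal_linear"))
tr <- run_chain(d, specs, chain_config(10010, 10, seed = 9))
order_effect_test(tr)
#> order effect: diff = -0.03145 (MCSE 0.00205), 95% CI [-0.03547, -0.02742] *
```

The single-dataset estimates scatter widely around β = 3 (their
sampling standard deviation is about 0.9 at n = 100; across 500
datasets the means line up with the truth).  The starred interval is
the point: the mean analysis-model estimate taken right after the Y
update differs systematically from the one taken right after the W₁
update, so this chained-equations sampler is not drawing from any
single joint model — an order effect, here resolved over 10000 retained
iterations of one chain.

`run_study(study_config())` runs the full four-arm design (complete
case, joint model, chained with logistic Y, chained with
linear-discriminant Y; β = 1 and 3) and tabulates per-arm means,
mean |β̄_b − β̄_c| and significance counts; reduced-scale
configurations finish in minutes (see the vignette).  A thin CLI over
the same functions lives in `exec/chainedimp`
(`simulate`, `impute-jm`, `impute-ce`, `diagnose`, `check-nim`,
`study`).

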