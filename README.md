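# mtmeval

Multi-trait multi-environment (MTME) genetic evaluation of segregating
progeny trials, for plant breeders and quantitative geneticists who need the
full path from plot-level phenotypes to a ranked selection list — in both
inferential frameworks used in practice.

Progeny trials repeated across locations are analyzed with the linear mixed
model

```
y = X b + Z g + W i + e
```

with fixed block-within-location effects `b`, random progeny effects
`g ~ N(0, Σg ⊗ I)`, random genotype-by-environment effects
`i ~ N(0, Σint ⊗ I)` and plot residuals `e` with within-plot trait
covariance `Σe`. Single-trait models use the scalar versions; multi-trait
models use unstructured trait×trait covariance matrices. The package fits
this model by

* **EM-REML / BLUP** — Henderson mixed-model equations, monotone EM with a
  safeguarded SQUAREM accelerator and balanced-ANOVA moment starts,
  prediction error variances, restricted likelihood, `AIC = −2logL + 2p`
  and likelihood-ratio tests; and
* **Bayesian Gibbs sampling** — conjugate blocked updates with
  inverse-Wishart / inverse-gamma priors, Geweke diagnostics, shortest
  (HPD) credible intervals, and DIC with random effects integrated out.

From fitted components it derives the plot-basis broad-sense heritability
`h² = σg² / (σg² + σint²/n + σe²/(nr))`, the GxE determination coefficient,
genotypic/residual coefficients of variation, two selection-accuracy
estimators (`√((σg²−PEV)/σg²)` and `1 − sd(g)/|ḡ|`), genetic correlations
(directly from multi-trait fits, or via the sum-of-traits covariance trick
`(var_sum − var_i − var_j)/2` with out-of-range correlations flagged), and
selection outputs: predicted gains, Spearman agreement with a bootstrap
interval, the coincidence index `(A − C)/(M − C)` with `C = bM`, and an
additive genetic index for simultaneous selection.

A balanced-trial simulator with known ground truth
(`simulate_trial()` / `soybean_trial_params()`) emulates the motivating
study — 203 soybean F2:4 progeny, 2 locations, 3 blocks, traits DM/SW/SY —
so every stage is testable without external data.

## Worked example

```r
library(mtmeval)

# a reduced soybean-like trial with known truth
params <- soybean_trial_params(n_progeny = 100)
sim <- simulate_trial(params, seed = 4)
validate_table(sim$table)
#> Trial validation report
#>   progeny: 100, locations: 2, blocks/location: 3, 3
#>   missing cells: 0, balanced: TRUE

# single-trait REML fit for days to maturity
d <- build_design(sim$table, "DM")
fit <- fit_reml(d)
fit
#> EM-REML fit: 1 traits, 2 iterations, converged: TRUE
#>   logL = -2229.7015, deviance = 4459.4029, AIC = 4465.4029 (p = 3)
#>   sigma_g diag: 137.026

# derived genetic parameters (n = 2 locations, r = 3 replicates)
derive_genetic_parameters(fit$components, grand_means = 143.45,
                          n_locations = 2, n_reps = 3)
#>   trait sigma_g2 sigma_int2 sigma_e2 sigma_phen2   h2_prog    c2_int       cv_g
#> 1    DM 137.0265   32.10501 52.66529    221.7968 0.8465922 0.1447497 0.08160217
#>         cv_e
#> 1 0.05058965
```

The generating heritability of the preset is 0.838; the fit above recovers
0.847 on one 100-progeny replicate (the two EM iterations reflect the
balanced-ANOVA moment start, which already solves the REML equations for
balanced data), and across 50 replicates the mean σg² estimates recover the
generating values within 10% (see the acceptance tests). The same
design object feeds the Bayesian sampler (`run_mcmc`), whose weak-prior
posterior means agree with the REML estimates within 5%.

An end-to-end run — all four model variants (FSTME/FMTME/BSTME/BMTME),
model comparison, parameters, selection, agreement and index tables plus a
manifest — is one call:

```r
out <- run_pipeline(pipeline_config(seed = 1, out_dir = "run1"))
```

The default configuration simulates and analyzes the full 203-progeny trial
(the multi-trait REML fit at that size takes a while because the near-unity
DM–SY genetic correlation puts the optimum at the edge of the parameter
space); pass `sim_params = soybean_trial_params(n_progeny = 50)` and a
shorter `mcmc` schedule for a quick exploratory run.

A thin command-line wrapper with `simulate`, `fit`, `params`, `select`,
`compare` and `run` subcommands is installed at
`inst/scripts/mtme.R`.

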