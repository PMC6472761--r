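---
title: "Multi-trait multi-environment genetic evaluation: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-trait multi-environment genetic evaluation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mtmeval)
```

## The problem

Plant-breeding programs evaluate segregating progeny (here, soybean F2:4
families) in replicated trials across several locations, and must decide
which families to advance. Two questions dominate: how much of the observed
variation is genetic, and which progeny have the best predicted genotypic
values. Because traits are correlated and genotypes interact with
environments, a joint multi-trait multi-environment (MTME) analysis can
recover more genetic signal than separate single-trait analyses — in
particular it borrows strength across correlated traits, shrinking the
apparent genotype-by-environment (GxE) variance and improving selection
accuracy for low-heritability traits.

`mtmeval` implements the complete evaluation pipeline in both inferential
frameworks used in practice: frequentist REML/BLUP and Bayesian Gibbs
sampling, for single-trait (STME) and multi-trait (MTME) versions of the
same linear mixed model.

## The model

For phenotypes `y` collected in a randomized complete block design repeated
at `n` locations with `r` blocks per location,

```
y = X b + Z g + W i + e
```

* `b` (fixed): overall mean, location effects, and block-within-location
  effects, under reference-level (treatment) coding. Any full-rank coding
  gives identical REML estimates and BLUPs; treatment coding keeps `X`
  small and interpretable (for 2 locations and 3 blocks: 6 columns per
  trait).
* `g` (random): one effect per progeny, `g ~ N(0, Sigma_g ⊗ I)`.
* `i` (random): one effect per progeny-by-location cell,
  `i ~ N(0, Sigma_int ⊗ I)`.
* `e` (random): plot residuals, with trait-by-trait covariance `Sigma_e`
  within a plot and independence across plots.

In the single-trait case the three covariance matrices collapse to the
scalars `sigma_g2`, `sigma_int2`, `sigma_e2`. In the multi-trait case all
three are unstructured trait-by-trait covariance matrices, the design is
stacked trait-major, and the random-effect covariances take Kronecker form.
Residual covariance is modeled within plot only — observations from
different plots are conditionally independent — which is the standard MTME
assumption when each plot yields one measurement per trait.

Missing trait cells are handled by row deletion (the observed-data
likelihood). Progeny with no observations are retained in the design and
receive fully shrunk BLUPs.

## Frequentist fitting: EM-REML with a safeguarded accelerator

Variance components are estimated by restricted maximum likelihood using an
EM algorithm on Henderson's mixed-model equations. Each iteration solves the
equations at the current components and replaces each covariance matrix by
the conditional expectation of its effects' cross-products (for the residual
matrix, a per-plot conditional expectation that also handles partially
observed plots exactly). EM guarantees a non-decreasing restricted
likelihood, which the package records (`logl_trace`) and the test suite
asserts on every fit.

Plain EM can be slow, especially near the boundary of the parameter space
(a nearly singular `Sigma_g` is common when two traits are genetically
correlated above 0.95, exactly the situation in the motivating soybean
data). Two measures keep fits fast without giving up the monotonicity
guarantee:

* **Moment starting values.** For complete balanced trials the ANOVA
  cross-product estimators of the three strata (progeny,
  progeny-by-location, residual) are computed in closed form, projected
  onto the PSD cone, and used as the starting point. For balanced data with
  an interior optimum these already solve the REML equations, and EM
  terminates in a couple of iterations; near the boundary they still start
  close.
* **SQUAREM extrapolation.** Every cycle performs two EM steps and one
  squared-extrapolation candidate; the candidate is accepted only if it
  does not decrease the restricted likelihood. Monotonicity therefore
  survives acceleration.

Convergence is declared when the relative change of the restricted
log-likelihood falls below `tol` (default 1e-9); the iteration cap is 5000.
Updated matrices that leave the PSD cone are projected back (eigenvalue
floor at 1e-8 of the mean diagonal, so the mixed-model equations stay
solvable) with a warning; a component pinned at the boundary still counts as
an estimated parameter in AIC.

The restricted log-likelihood convention includes the `-(n-p)/2 log(2*pi)`
constant. Absolute values are therefore not comparable with other software,
which embeds different constants; only differences (likelihood-ratio tests)
and the AIC identity `AIC = deviance + 2p` are meaningful across
implementations. `p` counts variance-covariance parameters only (3 for a
full single-trait model, 2 reduced, `3 t(t+1)/2` for a full `t`-trait
model); this counting is confirmed by the internal consistency of the
published model-comparison tables the test suite checks. Likelihood-ratio
tests use one degree of freedom for single-trait component tests; for
multi-trait comparisons the parameter-count difference is the default and a
`df` argument allows the single-degree convention.

## Bayesian fitting: blocked Gibbs sampling

The same models are fitted by a blocked Gibbs sampler with conjugate
conditionals:

1. all fixed and random effects jointly from their multivariate-normal
   conditional (Cholesky of the mixed-model coefficient matrix; fixed
   effects carry a `N(0, 1e8)` prior);
2. `Sigma_g`, `Sigma_int`, `Sigma_e` from inverse-Wishart conditionals
   (inverse-gamma in the single-trait case), in that fixed order.

Default priors are weak: IW scale `diag(1e-3)` with degrees of freedom equal
to the trait count, IG shape and scale 0.001, all overridable through
`prior_spec()`. With such priors the posterior means of the variance
components track the REML estimates on balanced data (asserted within 5% in
the tests), and doubling the IW scale moves posterior means by less than 2%
(asserted up to the Monte-Carlo resolution of the test chains).

The default schedule is desk-scale — 20,000 iterations, 10,000 burn-in,
thinning 5 — chosen so that a single-trait fit of a 100-progeny trial runs
in well under a minute; production analyses of the full 203-progeny trial
would use a longer schedule (e.g. 1,000,000 / 500,000 / 5), available by
passing the corresponding `mcmc_opts()`. Chain convergence is checked with
the Geweke diagnostic (first 10% vs last 50%, spectral variance estimates)
and interval summaries use shortest-interval HPDs. Posterior summaries of
derived quantities such as the heritability are computed **draw-wise** — the
transformation is applied to every stored draw and the transformed chain is
summarized — because the ratio of posterior means is not the posterior mean
of the ratio (the Jensen gap is demonstrated in the test suite); the
kernel-density mode uses Silverman's bandwidth.

The deviance stored for DIC is conditional on the fixed effects and the
covariance components with the random effects integrated out of the
Gaussian likelihood. This makes full and reduced models directly comparable
and gives `DIC = Dhat + 2 pD = Dbar + pD` (asserted to 1e-10). Samplers
that instead condition on the latent effects produce different absolute DIC
values, so published DIC numbers from such software are not reproduction
targets here; the model *ordering* (full model preferred when progeny
variance is real) is, and is verified on synthetic data.

Multi-trait Gibbs sampling requires every plot to have all traits observed,
because the conjugate residual update acts on complete plot residual
vectors. Single-trait sampling handles missing plots exactly. The motivating
trial is balanced, so this restriction does not bind there.

## Derived genetic parameters

With `n` locations and `r` replicates:

* plot-basis broad-sense heritability of progeny means
  `h2 = sigma_g2 / (sigma_g2 + sigma_int2/n + sigma_e2/(n r))`;
* GxE determination coefficient `c2_int = sigma_int2 / sigma_phen2`,
  `sigma_phen2 = sigma_g2 + sigma_int2 + sigma_e2`;
* genotypic and residual coefficients of variation `sqrt(sigma2)/mean`,
  reported as fractions, not percent;
* selection accuracy, by two estimators: frequentist
  `sqrt((sigma_g2 - PEV)/sigma_g2)` per progeny from the prediction error
  variance (the cited estimator is usually written with the radical; the
  square root is adopted here deliberately), and Bayesian
  `1 - sd(g)/|mean(g)|` per progeny from the posterior chains, truncated to
  [0, 1], with progeny of numerically zero posterior mean excluded from the
  reported average (their ratio is undefined; the exclusion count is
  logged).

Genetic covariances between traits come either directly from a multi-trait
fit or, for single-trait pipelines, from the sum-of-traits trick: analyze
the plot-wise sum of two traits and take
`cov = (var_sum - var_i - var_j)/2`. Correlations assembled this way need
not respect `|rho| <= 1`; out-of-range values are returned *unclipped* with
a flag, since that overflow is itself a diagnostic of single-trait bias
(multi-trait fits, being PSD-constrained, cannot produce it).

## Selection

Progeny are ranked by predicted genotypic value (`u+g`: the trait mean of
the fixed part plus the progeny BLUP); ties break by progeny identifier.
Predicted gain is the mean `u+g` of the selected set minus the overall
mean, and as a percentage of the overall mean. Agreement between two
methods' rankings combines the Spearman correlation of the full
breeding-value vectors (with a seeded percentile bootstrap over progeny
pairs for its confidence interval) and the chance-corrected coincidence
index `(A - C)/(M - C)` of the top-`m` sets, with `C = b M` kept
real-valued (at `m = 30`, `b = 0.15`, `C = 4.5`); negative values (worse
than chance) are reported unclipped.

For simultaneous selection the additive genetic index (AGI) aggregates
per-trait values with positive weights, by default after standardizing each
trait by its dispersion so the ranking is invariant to measurement units.
Weighting by the genotypic coefficients of variation reproduces the logic
of published index selections; the absolute scale of published AGI columns
depends on a proprietary aggregation that is not documented, so only the
ranking behaviour — not the printed index values — is treated as
reproducible, and both the standardized and raw variants are provided.

## The synthetic-trial generator

`simulate_trial()` produces balanced randomized-complete-block
multi-environment trials with known truth: progeny, GxE and residual
effect rows drawn from zero-mean multivariate normals, plus fixed location
and block effects. `soybean_trial_params()` encodes the motivating study's
conditions: 203 progeny from 3 populations, 2 locations, 3 blocks, traits
DM (days), SW (g), SY (g/plot), grand means (143.45, 18.43, 20.82),
published multi-trait progeny variances (130.947, 1.8084, 10.4882) and
genetic correlations (-0.1107, 0.9718, -0.0217), and published GxE and
residual variances. The GxE and residual *cross-trait* correlations were
never published; a moderate 0.3 is used for both, configurable, and the
choice is recorded in the returned object. Default fixed effects are small
— the second location +5% of the grand mean, blocks spread over ±0.5% — to
exercise the fixed part of the model without dominating the variance.

All draws come from one RNG stream in a fixed order (progeny effects, GxE
effects, residuals, missingness mask), so a seed fully determines the trial
and seeds are portable across parameter values of equal dimensions.

What the generator does *not* emulate: pedigree or population structure
(progeny effects are i.i.d., as in the evaluation model itself), spatial
field trends, epistasis, or heterogeneous residual variances per location.
Passing tests on this generator therefore validates the estimation
machinery under the stated model, not robustness to model misspecification
in real fields.

## Numerical choices and problem sizes

* Eigen-decomposition MVN sampler, so degenerate (exactly singular)
  covariance inputs are valid in simulations.
* PSD checks tolerate relative asymmetry/eigenvalue error of 1e-8;
  projections floor eigenvalues at 1e-8 of the mean diagonal.
* EM convergence `tol = 1e-9` relative log-likelihood, `max_iter = 5000`,
  SQUAREM acceleration on by default; all configurable.
* Ties in rankings break lexicographically by progeny identifier; the
  coincidence chance term is real-valued.
* The test suite runs everything at reduced sizes chosen to keep the full
  suite in a few minutes: oracle equalities on 5–120 progeny, parameter
  recovery on 50 replicates of 100-progeny trials, Gibbs/REML agreement on
  one 100-progeny trial at a 5,000-iteration schedule, DIC calibration on
  20 replicates of 40-progeny trials, and the sum-trick/multi-trait
  covariance comparison on 20 replicates of 80-progeny trials. These sizes
  are statements about where the properties are already decisive, not
  limits of the implementation.

## Known limitations

* No pedigree/kinship: progeny effects are exchangeable. Extending `Z`'s
  covariance to `Sigma_g ⊗ A` would be straightforward but is out of scope.
* No factor-analytic or heterogeneous-by-location structures for GxE.
* Multi-trait Gibbs requires trait-complete plots (see above).
* EM-REML near a singular component converges slowly by construction;
  the moment start and SQUAREM mitigate but do not eliminate this. For
  routine full-scale multi-trait fits an average-information algorithm
  would be faster; EM was chosen because its monotonicity is a testable
  invariant.
* Published absolute DIC/AIC constants and posterior summaries from other
  samplers are software-specific and are not reproduction targets; the
  arithmetic identities and model orderings are.
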