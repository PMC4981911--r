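---
title: "Missing bivariate outcomes in cluster randomised trials: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Missing bivariate outcomes in cluster randomised trials: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crtmi)
```

## The problem

Cluster randomised trials (CRTs) randomise intact groups — care homes,
schools, clinics — rather than individuals, so outcomes of individuals in the
same cluster are correlated. Health-economic evaluations alongside CRTs
analyse two outcomes jointly, typically a cost and a health effect (QALYs),
and both are usually incomplete. The *joint* complete cases are fewer than
either outcome's complete cases, so the handling of missing data matters more
for a bivariate analysis than for each endpoint alone.

`crtmi` implements and compares four strategies for missing-at-random (MAR)
bivariate continuous outcomes in two-arm CRTs:

* **CCA** — complete-case analysis: fit only records with *both* outcomes
  observed ([complete_cases()]);
* **SMI** — single-level multiple imputation, ignoring clustering beyond any
  cluster-level covariates in the imputation model ([impute_smi()]);
* **FMI** — multiple imputation with fixed cluster effects (one indicator
  per cluster) in the imputation model ([impute_fmi()]);
* **MMI** — multilevel multiple imputation from a joint bivariate
  random-intercept model, sampled with a Gibbs sampler ([impute_mmi()]).

## The substantive model

The analysis model is a bivariate linear mixed model with treatment as the
only covariate, fitted to both arms with common covariance:

$$Y_{\ell,ijk} = \beta_{\ell,0} + \beta_\ell k + u_{\ell,jk} + e_{\ell,ijk},
\qquad \ell \in \{1,2\},$$

with correlated cluster random intercepts
$(u_1, u_2) \sim N(0, \Phi)$, $\Phi = \begin{pmatrix} \tau_1^2 & \phi\tau_1\tau_2 \\ \phi\tau_1\tau_2 & \tau_2^2\end{pmatrix}$,
and correlated residuals $(e_1, e_2) \sim N(0, \Sigma)$ parameterised by
$(\sigma_1, \sigma_2, \rho)$. The treatment effects $(\beta_1, \beta_2)$ are
the estimands; for a cost-effectiveness reading, $\beta_1$ is the incremental
cost and $\beta_2$ the incremental effect, combined into the incremental net
benefit $\mathrm{INB}(\lambda) = \lambda\beta_2 - \beta_1$ ([inb()]).

`fit_bivariate_mixed()` maximises the restricted likelihood by default (a
plain-ML switch is provided). The fixed part is constant within cluster, so
the likelihood collapses exactly into (i) pooled within-cluster deviations
with covariance $\Sigma$ and (ii) per-cluster outcome-mean pairs with
covariance $\Sigma/n_j + \Phi$; the four fixed effects are profiled out by
GLS at each variance value and a Nelder–Mead search runs over the six
variance parameters as log-SDs and arctanh-correlations. This collapsed form
is verified in the test suite against direct $2n$-dimensional
multivariate-normal density evaluation to $10^{-6}$.

Numerical choices: convergence is declared when the simplex's function
spread falls below $10^{-9}$ relative; a tighter "polish" restart always
follows, and up to three deterministic jittered restarts are attempted on
non-convergence. Variance components live on the boundary-respecting
transformed scale ($\tau \ge 0$, $|\rho|, |\phi| < 1$); log-SDs are clamped
at $\pm 15$, so a collapsed component is reported as a tiny positive number
rather than an error. REML was chosen as the default because with few
clusters (5 per arm in one design) ML variance components are noticeably
downward biased and drag interval coverage further below nominal.

## The imputation engines

All engines are fitted **separately within each treatment arm** (allowing a
different covariance structure per arm), use both outcomes jointly, and
produce *proper* imputations: model parameters are drawn from a posterior
before the missing values are drawn, so between-imputation variance reflects
estimation uncertainty. Observed values are never altered. Since both
outcomes are Gaussian and linear, chained-equation cycling and joint-normal
sampling coincide; SMI and FMI therefore use the exact conjugate joint form
(a `cycles` argument is retained for interface familiarity, with no effect).

**SMI** regresses $(Y_1, Y_2)$ on an intercept and the auxiliary covariates
(`x`, `w` by default). The posterior is the standard
normal-inverse-Wishart form under a Jeffreys-style prior
(`draw_regression_posterior()`): $\Sigma \mid y \sim IW(n-p, S)$ and the
coefficient matrix is matrix-normal given $\Sigma$. Records with one
observed outcome are completed from the conditional normal given the
co-outcome. The posterior is formed from rows with both outcomes observed;
partially observed rows are then imputed from conditionals. This keeps the
conjugate draw exact; a monotone-sweep refinement would use the partial rows
in estimation as well, at the cost of the closed form.

**FMI** adds one indicator column per cluster, except a *reference cluster*
absorbed by the intercept. Cluster-level covariates cannot enter (they are
collinear with the indicators), so FMI uses only `x`. A cluster whose
outcomes are entirely missing has no estimable indicator and is imputed from
the reference cluster's predictive distribution — the reference is therefore
chosen as the cluster whose observed mean is nearest the arm mean
(`choose_reference_cluster()`, standardised distances summed over the two
outcomes, ties to the first-appearing cluster).

**MMI** replaces the indicators with correlated cluster random intercepts
(the same family as the analysis model, making imputation and analysis
models compatible) and samples the joint posterior by data augmentation:
cluster effects, $\Phi$, $\Sigma$, coefficients, then missing outcomes, each
from its full conditional. Priors are flat on coefficients and
inverse-Wishart with 2 degrees of freedom (the dimension — the most diffuse
proper choice) and identity scale on both covariance matrices; the identity
scale is negligible against residual scales of order $10^2$–$10^3$ and adds
mild regularisation for the smallest designs. The first completed dataset is
taken after `burn_in` iterations and later ones every `thin` iterations
(defaults 1000/1000). With 5 clusters per arm and appreciable clustering the
$\Phi$ chain mixes slowly; a burn-in of 5000 is recommended there, and the
simulation harness exposes this as a control. SMI and FMI draw one child
random stream per (arm, imputation), so a stack can be extended without
replaying earlier imputations; MMI is one sequential chain per arm, so
extending `M` replays the chain deterministically.

## Rubin's rules and intervals

`rubin_pool()` combines per-imputation fits: pooled estimate
$\bar{Q} = M^{-1}\sum_m \hat\beta^{(m)}$, within-variance $W$ (mean of
squared SEs), between-variance $B$ (sample variance of estimates), total
$T = W + (1 + 1/M)B$. Confidence intervals are normal-based
($\bar{Q} \pm z_{0.975}\sqrt{T}$); small-sample MI degrees of freedom are
deliberately not used, so that MI and CCA intervals are directly comparable.
The full pooled $2\times 2$ covariance of $(\hat\beta_1, \hat\beta_2)$ is
retained for the INB variance
$\lambda^2\,\mathrm{var}(\hat\beta_2) + \mathrm{var}(\hat\beta_1) -
2\lambda\,\mathrm{cov}$.

## What the generator emulates

`generate_trial()` draws two-arm trials shaped like the motivating
care-home CEA: $J$ clusters per arm (25 of 10, 5 of 50, or 15 with sizes
from a rounded Gamma with mean 20 and cv 0.5, floored at 2 — round-half-even
rounding, since the rounding rule is otherwise open), a standard-normal
individual covariate $X$ and cluster covariate $W$, and outcomes

$$Y_{1} = 100 + 120k + \beta_{w,1}W + \beta_{x,1}X + u_1 + e_1,\qquad
  Y_{2} = 50 + 10k + \beta_{w,2}W + \beta_{x,2}X + u_2 + e_2,$$

with $\sigma = (40, 20)$, $\rho = 0.1$, and $\tau_\ell$ set from the ICC via
$\tau = \sigma\sqrt{\mathrm{icc}/(1-\mathrm{icc})}$. The ICC here is the
*conditional* (residual-scale) one, excluding covariate-explained variance:
the covariance matrices $\Sigma$ and $\Phi$ are specified directly and the
ICC levels map onto $\Phi$'s diagonal. Two constants are genuinely open and
were fixed once as package defaults: the covariate effects and the
cluster-effect correlation $\phi = 0.1$ (set equal to the residual
correlation). For the covariates, $\beta_x = (20, 10)$ — half each residual
SD, so the individual-level auxiliary is strongly prognostic and
complete-case selection on it bites — and $\beta_w = (2, 1)$. The asymmetry
is deliberate: the analysis model excludes $X$ and $W$, so $\beta_w^2$ acts
as *additional cluster-level variance* in the analysis. A large $\beta_w$
would silently turn every nominally low-ICC scenario into a high-ICC one
and inflate all interval widths several-fold, out of keeping with interval
widths reported for trials of this size in the CRT literature; $\beta_w$ at 5% of
the residual SD keeps the cluster covariate relevant to the missingness
model while leaving the configured ICC levels meaningful in the analysis.

Missingness ([mar_mechanism()], [apply_missingness()]) is Bernoulli per
outcome with $\mathrm{logit}\,\pi = \alpha_0 + \eta_X X + \eta_W W$; four
kinds (individual, cluster, both, differential-by-treatment, where $\eta$
differs by arm: 1 vs 2 at the low level, 1.5 vs 3 at the high level).
$\alpha_0$ is calibrated so the *expected* rate hits the target, by 80-node
Gauss–Hermite quadrature of $E[\mathrm{expit}(\alpha_0 + sZ)]$,
$s^2 = \eta_X^2 + \eta_W^2$, inverted with `uniroot` to $10^{-9}$. For the
differential kind the intercept is calibrated in the control arm and shared,
so intervention-arm rates emerge from the stronger association (a per-arm
mode is available). Missingness depends only on fully observed quantities,
so it is MAR by construction — verified in tests by regressing the response
indicator on the outcomes given $(X, W, \mathrm{arm})$.

What the generator does *not* emulate: skewed costs (no transformation or
rounding of imputations either, which is also why the package declines
them), missing covariates, cluster-level unit non-response, informative
cluster size, MNAR mechanisms. Passing tests therefore speak to the
MAR-with-Gaussian-outcomes regime, not to robustness against skewness or
MNAR.

## The simulation harness

`expand_scenarios()` builds the full factorial grid (3 designs × 4 ICC
pairs × 2 association strengths × 2 non-response patterns × 4 mechanisms =
192 scenarios), each with a derived seed. `run_replicate()` executes
generate → mask → handle → fit → pool; all methods consume the *identical*
masked dataset per replicate (pairing, adopted for variance reduction in
method contrasts), and replicate $i$ runs from a child seed so any replicate
is reproducible in isolation. `run_scenario()` summarises coverage of the
true effects (120 and 10), empirical and percent bias, RMSE, and average CI
width, with the coverage Monte Carlo SE $\sqrt{p(1-p)/N}$; replicates whose
fit fails or does not converge are excluded for that method and counted, and
a method losing more than 10% of replicates is flagged. The 90–97% coverage
band drawn by `autoplot()` is an annotation for judging performance, not a
hard failure.

```{r grid, eval = FALSE}
grid <- expand_scenarios()
cell <- grid$scenario[[which(grid$mechanism == "differential" &
                             grid$design == "many_small" &
                             grid$icc == "low" & grid$eta_level == "low" &
                             grid$pattern == "equal")]]
perf <- run_scenario(cell, n_reps = 500, seed = cell$seed)
autoplot(perf)
```

## Problem sizes and numerical settings used for validation

A comparison at production scale runs all 192 scenarios at 1000 replicates
each; the package validates itself at desk scale. Reproduction runs
(`scripts/acceptance.R` and the acceptance tests) use N = 1000 replicates
per scenario cell in the script (500 for the burn-in comparison cells, and
250 or less for the auxiliary qualitative checks in the tests) and M = 10
imputations, and the Gibbs engine at burn-in 200 / thinning 200 — chosen
after checking that the retained-draw autocorrelation of the cluster-variance
chain at lag 200 is negligible for the designs involved (see the test
suite), with the single exception of the two cells whose point is the
burn-in itself (5000 vs 1000). At N = 500 a coverage estimate carries a
Monte Carlo SE of about 1 point, which is the right yardstick when comparing
against reference values computed at N = 1000.

## Known limitations

* Continuous bivariate outcomes only; no categorical imputation, random
  slopes, or predictive-mean matching.
* SMI/FMI form their posterior from joint complete rows; with very high
  missingness on one outcome this discards partially observed rows that a
  monotone sweep would use.
* FMI needs at least one cluster with complete rows per arm to anchor the
  design, and its known over-coverage with many small clusters is a property
  of the method, not of this implementation.
* The REML fit reports boundary solutions (e.g. $\hat\tau = 0$) as
  converged fits, which is the standard mixed-model convention; downstream
  pooling treats them like any other fit.
* With 5 clusters per arm, interval coverage of all methods is sensitive to
  the realised cluster configuration; the multilevel engine's default
  burn-in is too short there and the 5000-iteration setting should be used.
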