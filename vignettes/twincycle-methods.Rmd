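---
title: "Path-analysis methods for the twin-cycle models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Path-analysis methods for the twin-cycle models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(twincycle)
```

## The scientific question and the models

The twin-cycle hypothesis holds that two mutually reinforcing fat cycles —
hepatic (liver fat, triacylglycerol, insulin sensitivity, fasting insulin
secretion) and pancreatic (pancreatic fat, beta-cell glucose sensitivity) —
jointly impair glycaemic control. `twincycle` encodes this as a
manifest-variable path model over nine measured quantities (see
`?twincycle` for the node glossary) and tests it, together with an
extension in which objectively measured physical activity (`PA`) feeds
every metabolic node, against the covariance structure of cohort data.

Two model structures are built in (`builtinModel()`):

* **TC** — 8 endogenous nodes, 13 edges, including the directed feedback
  loop IS → FI → LF → IS. The system is therefore *non-recursive*: it
  cannot be evaluated by topological substitution and is handled in matrix
  form throughout.
* **TC-PA** — TC plus exogenous `PA` with an edge into each of the eight
  metabolic nodes (21 edges).

The node-symbol mapping (e.g. that `is1` is the LF → IS edge) is inferred
from the outcome/parent structure of the reported edge tables rather than
from an explicit legend, and should be read with that caveat.

## Preprocessing

All continuous variables are transformed by a stratified rank-based
inverse normal transform (`rankInverseNormal()`), by sex in cohort 1 and
by sex × treatment group in cohort 2, then residualised
(`residualize()`) on age, study centre, total energy intake and
carbohydrate, fat and protein intakes; the residuals are the variables the
models are fitted to. Choices the procedure leaves open, fixed here:

* **Rank offset.** The transform uses ranks via
  $\Phi^{-1}\!\big((r - c)/(n - 2c + 1)\big)$ with the Blom offset
  $c = 3/8$ as default — the most common convention; `offset` is exposed so
  alternatives are testable. Ties receive average ranks, which keeps the
  transform deterministic and order-preserving.
* **Stratification vs adjustment.** Sex enters only through
  stratification of the transform, not additionally as a residualisation
  covariate (the stratified transform already removes sex-level location
  and scale).
* **No re-standardisation.** Residuals are not rescaled after
  residualisation; the standardized SEM solution handles scale, and
  rescaling would alter raw-coefficient Wald SEs without changing the
  standardized estimates.
* **Missing data.** Complete-case analysis only: listwise deletion happens
  at `covarianceInput()`, after transformation; there is no imputation.

## Maximum-likelihood estimation

For parameter matrix $B$ (edge coefficients) and diagonal disturbance
covariance $\Psi$, the implied covariance of the simultaneous linear
system $y = By + \zeta$ is

$$\Sigma(\theta) = (I - B)^{-1} \Psi (I - B)^{-T},$$

valid for cyclic systems whenever $I - B$ is invertible. Estimation
minimises the ML discrepancy

$$F_{ML} = \ln|\Sigma| - \ln|S| + \mathrm{tr}(S\Sigma^{-1}) - p,$$

with $\chi^2 = (N-1)F_{ML}$ (the Wishart-likelihood convention;
`chisqScale = "N"` is available for sensitivity checks). Numerical
contract:

* L-BFGS-B with the analytic gradient
  ($\partial F/\partial B_{ij} = 2(\Sigma W A)_{ji}$,
  $\partial F/\partial \psi_{kk} = (A^T W A)_{kk}$, where
  $A = (I-B)^{-1}$ and $W = \Sigma^{-1} - \Sigma^{-1} S \Sigma^{-1}$),
  followed by Newton polishing until the projected gradient max-norm is
  below $10^{-10}$; the hot path is compiled (RcppArmadillo) because the
  randomised null refits the model thousands of times.
* Start values: zero coefficients, disturbance variances at half the
  sample variances; up to 10 seeded jittered restarts on non-convergence.
* Disturbance variances are bounded below at $10^{-6}$; a variance pinned
  at the bound raises a Heywood-case warning.
* A trial point with singular $I - B$ or non-positive-definite $\Sigma$
  returns a large objective value so the line search retreats.
* **Exogenous convention (fixed-x).** The variance of `PA` is fixed to its
  sample value rather than estimated, the dominant default for observed
  exogenous regressors; it reproduces the exogenous moment exactly, so
  model df are $p(p+1)/2$ minus free parameters minus one per fixed
  exogenous variance (15 for both TC and TC-PA). `fixedExogenous = FALSE`
  switches to free exogenous variances (identical df and fit).
* **Standard errors.** $ACOV = (2/(N-1))H^{-1}$ with $H$ the numerically
  differentiated Hessian of $F_{ML}$ — central differences of the analytic
  gradient with step $10^{-5}\max(1,|\theta_j|)$, which is better
  conditioned than double-differencing the objective. Wald $z$ and
  two-sided normal $p$ values carry no multiple-testing adjustment,
  matching the single-prespecified-model framing. Whether an observed- or
  expected-information matrix produced the original tables is not
  documented; Hessian-based SEs are this package's default, and the test
  suite checks them against the empirical sampling variability instead.
* Disturbance covariances are fixed at zero (diagonal $\Psi$): the model
  diagrams declare no correlated errors.

The standardized solution is
$\beta_e^{std} = \hat\theta_e\,\hat\sigma_{source}/\hat\sigma_{target}$
with $\hat\sigma$ from $\mathrm{diag}\,\Sigma(\hat\theta)$; it is
invariant to rescaling observed variables.

## Fit indices and the randomised-null fit test

CFI and TLI are computed against the conventional independence baseline
($\Sigma_B = \mathrm{diag}(S)$, $df_B = p(p-1)/2$) — the baseline itself
is a documented choice, since naming the indices does not pin it down —
and RMSEA uses the $(N-1)$ denominator consistent with the $\chi^2$
scaling. Indices are reported but not used as the formal fit decision;
cut-offs are sensitive to df, complexity and sample size.

The formal test is structural: the observed variables are randomly
reassigned to the nodes of the same model definition (a uniform random
permutation of the variable-to-node map; the identity is excluded, and
exogenous nodes are permuted along with the rest — both choices are
parameters), the model is refitted on the permuted covariance matrix, and
the chi-square recorded; 10,000 iterations by default. The observed
chi-square is then expressed as a quantile within the null sample using
the add-one estimator $p = (1 + \#\{\chi^2_{null} \le
\chi^2_{obs}\})/(n+1)$, which never returns exactly 0, and a one-sided
one-sample $t$ test asks whether the null mean exceeds the observed value.
Non-converged null fits are dropped and counted (dropping is conservative
and the counts are reported); a convergence rate under 50% is an error.

## Mediation: coefficient products

Indirect effects of `PA` on the glycaemic nodes are products of the
standardized coefficients along each simple directed path (paths through a
node twice are excluded). Eligibility follows the Baron–Kenny screen: a
pathway is quantified only when every traversed edge is individually
significant, two-sided $p < 0.05$ per fitted cohort — the threshold that
reproduces which pathways were and were not reportable per cohort in the
reference analysis. The SE is the multivariate delta method with the
*joint* parameter covariance of the path's edges
($g_i = \prod_{j\ne i}\beta_j$, $\mathrm{Var} = g^T ACOV_{path}\, g$); the
Sobel independence simplification is available as an option. Which SE
construction produced the original pathway tables is uncited; the
delta-method choice is validated against a parametric bootstrap in the
test suite. Counterfactual (natural direct/indirect) estimands are out of
scope — the method is purely the coefficient product on a linear system.

## The synthetic cohort generator

Participant-level data with the reported characteristics are
access-restricted, so the package ships a generator
(`syntheticCohortSpec()`, `generateCohort()`) used by every end-to-end
test. It emulates:

* **Structural signal.** Node scores follow $y = (I-B)^{-1}\zeta$ with the
  reference standardized estimates as default generating coefficients per
  cohort. Disturbance variances are chosen so every implied variance is 1;
  that condition, $\mathrm{diag}(A\Psi A^T) = 1$, is linear in $\psi$ and
  solved exactly in one linear solve — making the generating coefficients
  their own standardized solution.
* **Confounding and strata.** Age, 4 study centres, sex, treatment group
  (cohort 2) and energy-correlated macronutrient intakes are drawn
  independently of the disturbances and added linearly (defaults: age
  0.10, each diet variable 0.05 SD/SD on every node, centre offsets
  0/0.15/−0.15/0.10 SD, sex 0.2 SD; cohort 2 adds metformin-group offsets
  of −0.3 SD on FG and −0.2 SD on PG). Independence of confounders and
  disturbances keeps the residualisation tests interpretable.
* **Marginal calibration.** Each node is rescaled to the reported cohort
  mean/SD for its subset (e.g. fasting glucose 5.8 (0.5) mmol/l in cohort
  1). Physical activity intensity was not tabulated alongside the others;
  the generator uses mean 30, SD 10 m*g*, typical of adult wrist-worn
  accelerometry, chosen once and not revisited.

What it does *not* emulate — and hence what passing tests cannot show
about real data: skewed or heavy-tailed marginals beyond what the
rank-normal transform removes, structured missingness (generated cohorts
are complete), measurement error, nonlinear confounding, and disturbance
correlations. The diagonal-$\Psi$ generator matches the fitted model by
construction, so it cannot probe that form of misspecification.

## Problem sizes used in the checks

The test suite and acceptance script run at sizes chosen to make
Monte-Carlo error small relative to the tolerances they assert: chi-square
calibration uses 500 replicates at $n = 920$ under the TC truth; parameter
and SE recovery 200 replicates at $n = 1{,}000$ under the TC-PA truth;
the null-test property 20 seeded cohorts at $n = 725$ with 1,000-iteration
nulls (the analysis default remains 10,000); large-sample closure a single
$n = 100{,}000$ cohort. Recursive-model exactness is checked against
equation-wise least squares on moments over 50 random positive-definite
inputs at $10^{-6}$.

## Known limitations

* No latent variables, measurement models, equality constraints, mean
  structures, GLS/WLS/robust estimators, or FIML missing-data handling.
* RMSEA is reported without confidence intervals or close-fit tests.
* The real cohort values (e.g. observed $\chi^2$ of the fitted models)
  are not reproducible without access to the restricted data; the
  package's claims are therefore calibration and recovery properties on
  synthetic cohorts, plus the desk-checkable identity between pathway
  products and their edge coefficients.
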