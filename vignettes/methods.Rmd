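---
title: "Models and methods behind psyvalid"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind psyvalid}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(psyvalid)
```

This vignette documents the statistical machinery of the package: the
measurement model and its estimation, the reliability and subscore
procedures, the invariance ladder, the effect-size comparison, the
synthetic-data generator, and the numerical and design choices a
maintainer would want stated explicitly.

## The measurement model and its estimation

All confirmatory models are linear common-factor models on both the
covariance and mean structure,

$$\Sigma(\theta) = \Lambda \Psi \Lambda' + \Theta, \qquad
  \mu(\theta) = \nu + \Lambda \kappa,$$

fitted to the sample moments $(S, \bar y)$ (covariances with
denominator $n-1$) by minimising the maximum-likelihood discrepancy

$$F_{ML} = \ln|\Sigma| - \ln|S| + \mathrm{tr}(S\Sigma^{-1}) - p +
  (\bar y - \mu)'\Sigma^{-1}(\bar y - \mu),$$

with multigroup discrepancies weighted by $(n_g-1)/(N-G)$ so that
$T_{ML} = (N-G)\hat F$ — the Wishart-likelihood convention that makes
the single-group statistic $(n-1)\hat F$. Item codes are treated as
continuous throughout; no polychoric machinery is used. That choice
trades some attenuation in loadings (coarse 4-point items) for a
reliability analysis that is not inflated by tetrachoric-style
correlations, and is the reason every test statistic is also reported
in a mean-scaled version (below).

Single-group models carry a saturated mean structure (free intercepts,
latent means fixed at 0), so their degrees of freedom coincide with a
covariance-only analysis: 27 and 26 for one- and two-factor nine-item
models, 14 for a one-factor seven-item model, 21 for the nine-item
bifactor-(S−1) model. Where published tables print dfs that contradict
parameter counting (this happens for seven-item models with correlated
residuals), the package reports the analytic counts.

Models are specified as parameter tables: one row per non-trivial
matrix entry, free rows carrying labels, rows sharing a label sharing
one parameter. Cross-group equality — the whole invariance ladder — is
nothing but label sharing, which keeps the constraint logic auditable
(`constrain_invariance()` only rewrites labels).

### Optimisation

The free parameters are estimated by bound-constrained quasi-Newton
iteration (`nlminb`) with analytic gradients assembled from
$\partial F/\partial\Sigma$ and $\partial F/\partial\mu$ by the chain
rule. Variances (residual and factor) carry a lower bound of $10^{-6}$
rather than a log transformation: positivity is enforced identically,
and a solution resting on the bound is detected directly and flagged
as a Heywood case instead of failing. Starting values are loadings
0.5, residual variances half the observed variances, factor
covariances 0.3, intercepts at the observed means; up to 10 jittered
restarts follow a failed or poor convergence (gradient norm above
$10^{-4}$). Nested sequences (the ladder, the partial search) warm-start
from the previous solution, which is purely a speed device — estimates
are optimiser-tolerance identical with cold starts. Identification is
by unit factor variances by default; marker-item identification is an
equivalent reparameterisation and yields the same $T_{ML}$, dfs,
indices and standardized solution (this equality is tested).

### Robust standard errors and scaled statistics

Discretized 4-point responses are not multivariate normal; their
excess kurtosis distorts normal-theory standard errors and test
statistics. The package therefore computes, from the casewise data,
the empirical fourth-moment matrix $\Gamma$ of the moment
contributions $(y_i, \mathrm{vech}((y_i-\bar y)(y_i-\bar y)'))$ and

* sandwich covariance $A^{-1}BA^{-1}/(N-G)$ with
  $A = J'V J$, $B = J'V\Gamma V J$, where $J$ is the analytic Jacobian
  of the moment structure and $V$ the normal-theory weight matrix at
  the fitted moments;
* the mean-scaling correction $\hat c = \mathrm{tr}(U\Gamma)/df$,
  $U = V - VJA^{-1}J'V$, giving $T_{scaled} = T_{ML}/\hat c$ — the
  statistic asymptotically equal to the Yuan–Bentler mean-corrected
  test. The mean-and-variance-adjusted variant is not implemented;
  the choice is recorded in the fitted object's metadata field.

For nested models the difference test uses
$\hat c_d = (df_r\hat c_r - df_f\hat c_f)/(df_r - df_f)$; a
non-positive $\hat c_d$ (possible in small samples) triggers a logged
fallback to the unscaled difference rather than a hard failure.

Scaled fit indices substitute the scaled statistics of both the target
and the independence baseline model (per-group diagonal covariance,
free means). RMSEA uses the multigroup convention
$\sqrt{G}\sqrt{\max(T-df,0)/(df\,(N-G))}$ with a 90% CI by
noncentral-$\chi^2$ inversion; SRMR is the n-weighted average of
per-group root-mean-square standardized residuals, with mean residuals
entering only when the mean structure is itself restricted.

## Reliability: bifactor-(S−1) omegas

With only two facets, a full bifactor model is unidentified; the
bifactor-(S−1) model drops one facet's group factor so that facet
anchors the general factor. The package fixes all factors orthogonal
with unit variance and computes, from the (raw, by default) solution,

$$\omega_T = \frac{(\Sigma\lambda_g)^2 + (\Sigma\lambda_s)^2}{V},\quad
  \omega_H = \frac{(\Sigma\lambda_g)^2}{V},\quad
  \omega_{HS} = \frac{(\Sigma_{i\in s}\lambda_{s,i})^2}
   {(\Sigma_{i\in s}\lambda_{g,i})^2 + (\Sigma_{i\in s}\lambda_{s,i})^2
    + \Sigma_{i\in s}\theta_i},$$

flagged against the conventional minima 0.70 ($\omega_H$) and 0.50
($\omega_{HS}$). The reference facet has no modeled group factor, so
its $\omega_{HS}$ is undefined under this parameterisation; the
package computes $\omega_{HS}$ only for modeled group factors by
default and emits a zero-convention value for the reference facet only
on explicit request (`include_reference = TRUE`). Published analyses
sometimes print a reference-facet value without stating its
convention; silence seemed worse than an opt-in.

## Haberman subscores and Olkin's Z

For subscore $S$, total $X$ and remainder $R = X - S$:
$\mathrm{PRMSE}_{sub}$ is the subscore reliability, estimated by
coefficient alpha (the procedure needs *a* CTT reliability estimator;
alpha is the standard choice in applications of this method and the
choice is recorded in the report); then
$\mathrm{var}(S_{true}) = \mathrm{PRMSE}_{sub}\,\mathrm{var}(S)$,
$\mathrm{cov}(X, S_{true}) = \mathrm{var}(S_{true}) +
\mathrm{cov}(S, R)$, and
$\mathrm{PRMSE}_{total} = \mathrm{cov}(X,S_{true})^2 /
(\mathrm{var}(X)\,\mathrm{var}(S_{true}))$. The subscore has added
value iff $\mathrm{PRMSE}_{sub} > \mathrm{PRMSE}_{total}$ *and*
Olkin's $Z > 1.64$. $Z$ compares the two dependent correlations
$\sqrt{\mathrm{PRMSE}_{sub}}$ and $\sqrt{\mathrm{PRMSE}_{total}}$
(common variable: the true subscore) using the Olkin–Siotani
asymptotic variance; the Monte-Carlo accuracy of that variance is part
of the test suite (within 15% of the empirical SD).

## The invariance ladder

Levels add cross-group equalities cumulatively: configural (pattern
only), metric (loadings; non-reference factor variances freed for
identification), scalar (intercepts; non-reference latent means
freed), residual (residual variances). Two structural decisions:

* **Residual nests on scalar, not on factor-variance.** The
  factor-variance step is a side branch tested against scalar and
  reported separately, because its role is interpretive — residual
  invariance only speaks to indicator reliability when factor
  variances are also invariant — while the df arithmetic of the
  published ladder (66 + 9 = 75 for a nine-item two-factor model)
  requires residual constraints on top of scalar.
* **The decision rule is the standard convention**: a step passes iff
  (CFI drop < 0.01 and RMSEA increase ≤ 0.015) or the scaled
  difference test is non-significant at $\alpha = 0.05$. The source
  literature's sentence describing the criterion reads literally as a
  non-invariance condition; it is implemented here in the standard
  (Chen) direction, and that reading is flagged rather than silent.

On failure, the partial search frees, one at a time, the constrained
parameter with the largest univariate score-test (modification)
contribution, computed analytically from the expanded parameter
table's Jacobian at the restricted optimum (the statistic tracks the
refitted $\Delta\chi^2$ closely; this is tested). Ties break toward
the lowest item index, making the search deterministic. The search
stops at a pass or after freeing half the items, after which the level
is declared non-invariant. How many invariant items are *enough* for a
usable partial solution is unsettled in the methods literature; the
package reports the freed set and count, and only enforces a minimum
if the caller sets `min_invariant_items`.

Longitudinal invariance is approximated as multigroup over occasions;
within-subject residual correlations across occasions are not modeled
(a known limitation shared with the table-style presentation this
mirrors).

## Effect sizes two ways

Unit-weighted: MM-regression (bisquare S-estimate of scale, 50%
breakdown, then an M-step at ~95% Gaussian efficiency, via
`MASS::rlm`) of the sum score on group dummies against the first
level; SES = coefficient / robust residual scale of the same
regression. The denominator choice is internal to the robust fit and
contamination-resistant; published analyses rarely state theirs, so
this one is documented rather than inferred. Latent: the
scalar-invariant multigroup model with baseline latent means at zero;
SES = $\hat\kappa_g$ / pooled (n-weighted) factor SD, p-values from
sandwich standard errors. Under a pure latent shift with noisy items
the observed SES is attenuated toward zero relative to the latent SES
— the systematic ordering the package's acceptance checks verify.

## What the generator emulates — and what it does not

`population_model()` draws continuous responses from the factor model,
cuts them at per-item thresholds, and applies MCAR missingness.
Defaults are chosen once to resemble community symptom-screening
data:

* thresholds at the 60th/80th/93rd percentiles of each item's
  continuous distribution, giving right-skewed marginals (roughly
  60/20/13/7%) and low mean scores, as severity items show in
  general-population samples where category frequencies are rarely
  published;
* the nine-item population has a cognitive/affective and a somatic
  factor correlated 0.77 with standardized loadings 0.45–0.73; the
  seven-item population has one factor with loadings 0.27–0.88 (one
  deliberately weak item) and three correlated somatic residuals —
  generic shapes of the published estimates, not a reproduction of
  any figure;
* multigroup scenarios share the base model's thresholds (cut points
  are a measurement property; letting groups re-derive them would
  silently absorb planted violations — the constructor pins them);
* seeds: one root seed, deterministic per-group child seeds, recorded
  in the scenario manifest.

Not emulated: non-normal latent distributions, graded-response (IRT)
category processes, MAR/MNAR mechanisms (MAR is available only as an
explicit device for power-testing Little's test), acquiescence or
method effects beyond the modeled correlated residuals. Passing
operating-characteristic tests on these generators therefore shows the
procedures are correct and calibrated under the stated model — not
that real survey data satisfy that model.

## Numerical choices and degenerate inputs

* Little's MCAR test: EM for the multivariate-normal mean and
  covariance (stop at max parameter change $<10^{-6}$ or 500
  iterations; ridge $10^{-8}$ on the covariance diagonal), then
  $d^2 = \sum_j n_j(\bar y_{j,obs}-\hat\mu_{obs})'
  \hat\Sigma_{obs}^{-1}(\bar y_{j,obs}-\hat\mu_{obs})$ with
  $df = \sum_j p_j - p$. Complete data: $d^2 = 0$, $df = 0$, reported
  as trivially passed. All-missing rows carry no information and are
  dropped; an all-missing table reports the test as undefined.
* Sum scores: any missing item makes the score missing (no
  proration), consistent with complete-case analysis everywhere else.
* $df = 0$ models report the perfect-fit conventions (CFI 1, RMSEA 0).
* A singular information matrix raises an error suggesting
  re-specification rather than returning pseudo-inverse standard
  errors.
* Degenerate subscales (fewer than two items) are flagged at
  definition time and excluded from factor-analytic treatment.

## Problem sizes in the tests and acceptance script

The simulation studies run at the sizes the validation questions need,
chosen once: parameter recovery over 100–200 replicates at $n = 1000$;
type-I calibration of the scaled difference and MCAR tests over
300–600 replicates; ladder operating characteristics over 100–200
replicates of two groups of 600 (the scale of the motivating survey's
gender split); attenuation over 30 replicates of two groups of 1000.
At these sizes the full test suite completes in a few minutes on one
CPU.

## Known limitations

* ML on 4-point items attenuates loadings relative to categorical
  estimators; DWLS/polychoric estimation is deliberately out of scope,
  as is the categorical (Green–Yang-style) reliability formula.
* The bifactor machinery covers exactly two facets (the
  bifactor-(S−1) case); larger facet structures are rejected.
* No imputation beyond the EM step inside Little's test; the package
  is complete-case by design.
* No alignment optimisation or Bayesian approximate invariance; the
  ladder is the classical exact-constraint one.
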