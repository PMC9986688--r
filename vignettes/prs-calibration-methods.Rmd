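---
title: "Calibrating a PRS to the age-dependent polygenic model: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calibrating a PRS to the age-dependent polygenic model: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

Multifactorial breast-cancer risk models of the BOADICEA family describe
the incidence for individual $i$ as a proportional-hazards model with a
latent polygenic component,

$$\lambda(t) = \lambda_0(t)\,\exp\{\sigma_P(t)\,x_P(i)\},$$

where $x_P \sim N(0,1)$ summarises common-variant susceptibility and the
polygenic variance of the log-hazard declines linearly with age,

$$\sigma_P^2(t) = \gamma + \theta t,$$

with segregation-analysis values $\gamma = 4.86$ and $\theta = -0.06$.
Positivity of the variance restricts the supported ages to below 81; the
package defaults to the range $[20, 79]$, matching the convention of
restricting analyses to diagnosis or censoring ages under 80.  This
package implements only the polygenic term: major-gene effects and
epidemiological risk factors sit outside its scope.

A measured polygenic risk score (PRS) is incorporated by splitting the
polygenotype into a known part $x_K$ (the standardized PRS) and an
unmeasured residual $x_R$, independent standard normals a priori, with

$$x_P = \alpha x_K + \sqrt{1-\alpha^2}\,x_R, \qquad
  \sigma_K^2(t) = \alpha^2(\gamma + \theta t).$$

The calibration parameter $\alpha$ — the square root of the proportion
of polygenic variance the PRS explains — is what everything here
estimates.  Given $\alpha$, any PRS can be supplied to the risk model as
a z-score without double-counting family history.

## The incidence-constrained baseline

$\lambda_0(t)$ is not free: marginalising the individual hazards over
$x_P$ must reproduce the population incidence $\mu(t)$.  With yearly
piecewise-constant hazards this gives, age by age,

$$\mu(t) = \lambda_0(t)\,
  \frac{\int e^{\sigma_P(t)x}\,S(t\mid x)\,\phi(x)\,dx}
       {\int S(t\mid x)\,\phi(x)\,dx},$$

which `constrain_baseline()` solves in closed form ascending in $t$,
since $\lambda_0(t)$ factors out of the numerator and $S(t \mid x)$
depends only on already-solved earlier ages.  No iteration is needed,
and recomputing the marginal incidence from the solved baseline
reproduces the input table to floating-point precision (the test suite
asserts $10^{-8}$ relative error; observed error is of order
$10^{-15}$).  Incidence tables are accepted in registry-style 5-year
bands and expanded to yearly rates by constant interpolation within
bands; the packaged fixture emulates the magnitude of recent England &
Wales female breast-cancer rates and is synthetic, not the registry
table.

## The three estimators

**Transformed-covariate GLM.**  Because the marginal log-odds ratio per
unit PRS at age $t$ is approximately $\alpha\,\sigma_P(t)$, regressing
case-control status on $S' = x_K/\sqrt{\gamma+\theta t}$ yields $\alpha$
directly as the coefficient of $S'$ (`estimate_alpha_glm()`), with a
Wald 95% interval.  Logistic rather than Cox regression is the default,
matching the case-control setting; covariates (country, principal
components) enter additively.  This estimator ignores the residual
polygene: affected individuals with high $x_P$ are removed from the
at-risk population early, inducing a negative correlation between $x_K$
and $x_R$ at later ages among those still observable — index event
bias — so $\alpha_{GLM}$ systematically underestimates $\alpha$.

**Retrospective likelihood.**  `estimate_alpha_rl()` maximises the
likelihood of the observed PRS values *conditional on phenotype*,

$$\ell(\alpha) = \sum_i \log
  \frac{P(\text{pheno}_i \mid x_K = z_i;\alpha)\,\phi(z_i)}
       {\int P(\text{pheno}_i \mid u;\alpha)\,\phi(u)\,du},$$

with controls contributing survival to their censoring age and cases
the yearly hazard density at their diagnosis age, each integrated over
$x_R$.  Conditioning on phenotype makes the case-control sampling
fraction cancel between numerator and denominator, so no ascertainment
correction is required — the standard argument for retrospective
likelihoods, which we make explicit here.  Cases contribute a density
at the diagnosis age (the year-$t$ hazard times survival to $t$) rather
than an interval probability; at yearly resolution with rates of order
$10^{-3}$ the two differ at second order.  The likelihood is maximised
by bounded one-dimensional search (`optimize`, tolerance $10^{-5}$ on
$\alpha$, default bounds $[0, 0.99]$).  The 95% interval is the set of
grid points (step 0.001) whose log-likelihood is within
$\chi^2_1(0.95)/2 = 1.92$ of the maximum; because the profile is
unimodal on every cohort we have examined (a test asserts this on a
coarse grid), the endpoints are located by root finding and snapped to
the outermost qualifying grid points rather than by exhaustively
evaluating all 990 grid values.

**Proportionality calibration.**  Under the rare-disease assumption and
ignoring differential age effects, $\alpha$ is approximately
proportional to the log odds ratio per SD, $\eta$.
`calibrate_alpha_app()` computes $\alpha_{APP} = (\eta/\eta_0)\alpha_0$
from a reference PRS; with the published reference values
($\eta_0 = 0.497$, $\alpha_0 = 0.441$) the constant is 0.887 when
rounded to three decimals, and `predict_alpha_app()` applies it to a
whole parameter table.  For one PRS in the shipped published table
(PRISMA) the recomputed prediction is 0.396 against a printed 0.395 — a
rounding discrepancy in the source column, not reproducible at any
rounding convention we tried, and documented rather than patched.

## Numerical choices

* **Quadrature.**  All latent-Gaussian integrals use Gauss–Hermite
  rules (nodes scaled by $\sqrt2$, weights renormalised to unit mass so
  constants integrate exactly — this also makes the $\alpha = 0$
  structural identity $\ell(0) = \sum_i \log\phi(z_i)$ hold to machine
  precision rather than to quadrature error).  The default order is 48:
  at order 30 the whole-cohort log-likelihood can differ from a dense
  trapezoid integration (4,000 points on $[-8,8]$) by about $10^{-6}$
  at small $\alpha$, while order 48 keeps the gap below $10^{-9}$
  across $\alpha \in [0, 0.7]$ at modest extra cost.  Doubling the
  order from 24 changes phenotype probabilities by less than $10^{-6}$,
  which the suite verifies.
* **Age grid.**  One-year intervals, hazards piecewise constant per
  year, cumulative hazards as yearly sums — the resolution of incidence
  tables and the convention of the risk model being calibrated.
* **Degenerate inputs.**  $\gamma = \theta = 0$ is admitted as the
  explicit no-polygene model (the baseline then equals the marginal
  incidence); any other configuration with $\gamma + \theta t \le
  10^{-10}$ inside the age range is rejected.
* **Performance.**  The likelihood kernel and the simulator's
  discrete-time onset draw are small C++ routines; everything else is
  plain R on top of `stats` fits.

## The simulator

`simulate_cohort()` reads the hazard model generatively: independent
standard-normal $x_K, x_R$, effective polygenotype
$\alpha x_K + \sqrt{1-\alpha^2} x_R$, and a yearly Bernoulli onset draw
with probability $1-e^{-\lambda(t)}$ against the incidence-constrained
baseline, up to a censoring age drawn uniformly from a configured
window.  Affected individuals enter as cases at their onset age,
unaffected ones as controls at their censoring age, until the requested
counts fill.  Defaults are chosen once to emulate a European
breast-cancer case-control study: the packaged incidence fixture,
$\gamma = 4.86$, $\theta = -0.06$, and censoring uniform on $[40, 79]$.
Country effects, when configured, shift only the *recorded* PRS mean —
mirroring the observation that PRS means differ between countries
without matching incidence differences — and are removed by
`residualize_prs()`, which regresses the PRS on country and principal
components adjusted for status and keeps the status contrast in the
residual.

The generator emits `prs_std` on the population z-score scale (exact,
since $x_K$ is standard normal by construction).  Real data require
standardizing against an external reference — conventionally the
control distribution, via `standardize()` — and that step introduces a
small scale error the simulator does not emulate.  Other features of
real cohorts the generator deliberately omits: genotype-level noise
(PRS values are drawn directly, not built from SNPs), major-gene
carriers, family structure, competing mortality, birth-cohort incidence
trends, and ancestry admixture beyond mean shifts.  Recovery tests
passing here therefore show correctness of the estimation machinery
under the model's own assumptions, not robustness to their violation.

A `bcac_like` preset targets the case age structure of the consortium
dataset behind the published calibrations (mean case age 59.9).  With a
single uniform censoring window the control mean age necessarily
exceeds the case mean (onset precedes censoring while incidence rises
with age), so the preset matches the case mean only, using a study
entry age of 49 and censoring uniform on $[53, 79]$; the entry age is
applied consistently in the model age range, so estimation on preset
cohorts is unbiased.

## Validation design and problem sizes

The test suite checks each operation against an independent oracle
where one exists: PRS scoring against a brute-force double loop,
logistic fits against a hand-rolled Newton–Raphson, the retrospective
likelihood against a dense-trapezoid integrator (whose denominator uses
the rotation identity that $\alpha U + \sqrt{1-\alpha^2}X_R$ is
standard normal), and the baseline against its own defining
self-consistency.  Parameter recovery runs 20 simulated cohorts of
20,000 individuals (8,000 cases, 12,000 controls — roughly the
consortium case fraction) at true $\alpha = 0.44$, asserting mean bias
below 0.02, profile-interval coverage of at least 90%, and
$\hat\alpha_{GLM} < \hat\alpha_{RL}$ in at least 16 of 20 replicates;
smaller cohorts (n = 8,000) check recovery at $\alpha = 0.2$ and 0.6.
These sizes give Monte-Carlo standard errors comfortably inside the
asserted bounds while keeping the default suite run in minutes.

## Known limitations

$\alpha$ is assumed age-constant (the age-specific effects of the PRS
and the residual polygene are taken as proportional), $(\gamma,
\theta)$ are fixed segregation-analysis inputs rather than jointly
estimated, and calibrations transfer poorly across ancestries — effect
sizes and PRS means both differ, and the package offers no
recalibration beyond re-running the estimators on population-specific
data.  Published $\alpha$ values for real PRSs are properties of the
consortium dataset they were estimated on; without that data the
package can reproduce the calibration identities and the qualitative
estimator ordering, but not the dataset-specific point estimates.
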