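---
title: "Joint models for a longitudinal marker with informative visit times and competing risks"
author: "visitjm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Joint models with informative visiting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(visitjm)
```

## The problem

Electronic-health-record markers such as CD4 cell counts are measured when
the patient shows up, and patients in worse condition may show up more (or
less) often.  When the timing of measurements depends on the latent disease
trajectory, a standard linear mixed model (LMM) fitted to the observed
measurements is biased: the sample of observed marker values over-represents
the states that trigger visits.  Terminal events — death, or disengagement
from care — stop observation altogether and can likewise depend on the
latent trajectory, making the missingness after the event non-ignorable.

`visitjm` fits a shared-parameter joint model with three linked submodels:

1. **Marker (LMM).**  $Y_i(t) = X_i^\top(t)\beta + Z_i^\top(t) b_i +
   \varepsilon_i(t)$ with $b_i \sim N(0, D)$, $\varepsilon_i(t) \sim
   N(0, \sigma^2)$.  The smooth part $m_i(t) = X_i^\top(t)\beta +
   Z_i^\top(t) b_i$ is the latent ("true") marker value, and $m_i'(t)$ its
   latent slope.

2. **Visiting process.**  The hazard of the next visit, on either the
   *gap-time* scale (time $u$ since the most recent visit) or the
   *calendar-time* scale (a counting-process intensity in $t$):
   $$h_v = h_{v0}(\cdot)\,
     \exp\{\gamma_v^\top \bar X_{vi}(t_{ij}) +
           \phi_v^\top g_v(\bar Y_i(t_{ij})) +
           \alpha_{v1} m_i(0) + \alpha_{v2} m_i'(\cdot)\},$$
   optionally multiplied by a gamma frailty $w_i \sim
   \mathrm{Gamma}(1/\eta, 1/\eta)$ (mean 1, variance $\eta$).  The
   covariates $\bar X_{vi}, g_v(\bar Y_i)$ are deterministic functions of
   the *observed* visit and marker history up to the current visit (most
   recent value, previous gap, visit count, ...), held constant between
   visits.  If $\alpha_{v1} = \alpha_{v2} = 0$ the visiting process is
   ignorable given the observed history (the visit-process analogue of
   MCAR/MAR); otherwise it is informative.

3. **Competing risks.**  One cause-specific proportional hazard per
   terminal cause, with the same structure (history features, latent
   baseline value and slope associations) and its own B-spline
   log-baseline.

Log-baselines are cubic B-splines, $\log h_0(u) = B(u)^\top \psi$.  The
likelihood factorizes as the closed-form marginal marker density times the
integral, over the random effects, of the visiting and competing-risk
conditional likelihoods weighted by the posterior of $b_i$ given the
marker alone — that posterior also serves as the importance density for
the numerical integration ("pseudo-adaptive" Gauss–Hermite, recentred at
every evaluation).  Estimation is full marginal maximum likelihood with an
analytic score, BFGS, and inverse-Hessian standard errors.

Deliberately *not* modeled: the current latent value $m_i(t)$ as a hazard
covariate (nearly collinear with the most recent observed value, a known
identifiability hazard), dual gap+calendar time scales, non-Gaussian
markers, serially correlated residuals, and interval-censored terminal
events.

## Fitting a model

```{r}
library(visitjm)

scn <- scenarioGap()                  # a complete generating mechanism
dat <- simulateData(scn, n = 300, seed = 1)

fit <- vjmFit(dat, scenarioConfig(scn, "correct", nodes = 4))
summary(fit, exponentiate = TRUE)
derivedMeanMarker(fit, t = 10)        # population-averaged value +/- SE
```

The configuration (see `validateConfig()`) declares, per submodel, the
time scale, the named history features, the latent associations, the
frailty, and the spline knots.  The "ignore the visiting process"
comparator is the same code path with the visiting block dropped
(`visiting$scale = "none"`), not a separate model.  Data enter either as
`jointData()` built from `subjectRecord()`s or from two CSV files via
`readJointData()` (long-format marker table plus a subject-level table).

## Parameters that matter

* `quadrature$nodes` — Gauss–Hermite nodes per random-effect dimension
  (default 7 for $q \le 3$).  For repeated scaled-down fits the harness
  uses 4: in our checks 3 nodes/dim visibly underestimates the
  third (cubic-trend) random-effect variance, while 4-node rules reproduce
  the 7-node optima at a fraction of the cost.  The Monte Carlo
  alternative (`kind = "MC"`) uses a fixed Latin-hypercube normal design.
* Visiting spline — default 3 interior knots at gap-time (or visit-time)
  quantiles; cause-specific baselines default to 1 interior knot.  For
  simulation studies the knots are fixed in the configuration so the
  baseline truth is well defined across replications.
* `prevGapCenter` (years, default 0.15) — centering constant of the
  previous-gap covariate, chosen so the first gap (which has no
  predecessor) is consistent with later gaps; 0.15 is the typical median
  first-visit time in the motivating setting.
* `optim` — BFGS with relative log-likelihood tolerance `1e-9` (and a
  gradient sup-norm check at `1e-5`).  The objective adds a smooth
  quadratic barrier outside $|\theta_j| > 30$ (hard wall at 50): with
  finitely many quadrature nodes the approximated likelihood can become
  spuriously unbounded in extreme corners of the parameter space where
  the nodes no longer cover the integrand, and the barrier keeps the line
  search away from them.  It is exactly zero at any plausible optimum.

## Numerical choices

* All inter-visit hazard integrals use one 15-point Gauss–Kronrod panel
  per piece; history features are frozen at the left endpoint of each
  piece while the latent slope varies continuously, matching the model's
  own structure.
* The frailty is integrated analytically (closed-form gamma mixture), and
  $\eta$ is estimated on the log scale; $D$ is parameterized by the
  half-vectorized matrix logarithm and $\sigma^2$ by its log, so the
  optimization is unconstrained.
* The analytic score is the complete-data score averaged with the
  normalized posterior node weights.  It is the exact score of the exact
  likelihood evaluated at the quadrature nodes; it does not include the
  motion of the pseudo-adaptive nodes with the marker parameters, so
  score-versus-finite-difference checks are run at node counts where both
  are converged (9/dim in the tests, agreeing to 1e-4 relative).
* Standard errors come from central finite differences of the analytic
  score (step $10^{-4}(1 + |\theta|)$), inverted at the optimum by
  eigendecomposition: genuine negative curvature flags the fit, while
  numerically flat directions (weakly identified coordinates) are clamped
  and surface as effectively infinite standard errors.  Wald
  95% intervals are formed on the packed (transformed) scale for variance
  parameters and the natural scale otherwise.
* Spline log-baselines are extended linearly (continuous value and first
  derivative) outside the boundary knots, keeping the optimization finite
  for gaps beyond the fitted range.  Equal coefficients give an exactly
  constant baseline (partition of unity), and coefficients at the
  Greville sites reproduce any log-linear baseline exactly — which is how
  spline-coefficient truths are defined in the simulation harness.
* Zero-length censored gaps contribute nothing to the integral and
  $\log 1$ to the survival term.  The baseline visit at $t = 0$ is the
  time origin, not an event; a configuration flag (`firstGapFromZero`)
  instead treats the first visit time itself as a gap from 0 for data
  without a baseline visit.
* Degenerate inputs (non-monotone times, follow-up before the last visit,
  unknown cause codes, non-positive-definite $D$) are rejected with the
  subject named.

## The simulator and what it emulates

`scenarioGap()` and `scenarioCalendar()` reproduce the two generating
mechanisms of the simulation study the package is built around: a 3-basis
LMM ($\{1, \log(t+1), (t/10)^3\}$ with $\beta = (17.20, 4.83, -2.80)$ —
the square-root-CD4-like trajectory whose population mean at 10 years is
25.98), a gap-time or calendar-time visiting mechanism depending on the
most recent observed value, the previous gap or calendar time, and the
latent baseline value and slope ($\phi_{v1} = 0.02$, $\alpha_{v1} = 0.02$,
$\alpha_{v2} = 0.20$, ...), and two cause-specific hazards with a binary
covariate $W \sim \mathrm{Bernoulli}(0.5)$.  Frailty variants
(`frailty = TRUE`, default $\eta = 0.36$, the value estimated in the
motivating cohort) multiply the visiting hazard by a gamma frailty and
drop the previous-gap covariate.  Event and visit times are drawn by
inverse-CDF sampling with composite Gauss–Kronrod quadrature and a
bracketing root finder (absolute tolerance 1e-8).

Quantities the published mechanism does not pin down are package
calibrations, chosen once: the random-effects covariance
(`defaultD()`: SDs 4/1.5/1 with mild correlations), $\sigma^2 = 6.25$,
and log-linear baseline shapes whose intercepts were calibrated so that
the gap-time scenario at $N = 1000$ yields about 11 visits per subject
and cause event rates near 11.3% and 14.6% (the calendar scenario has its
own calibrated intercepts).  When $\phi_{v1}$ is changed (e.g. the 0.15
variant), the baseline intercept absorbs the shift so the visit frequency
stays comparable.  Censoring is administrative at 10 years.

What passing simulation tests does and does not show: the generator
produces irregular, informatively timed visits and informative competing
risks, but real cohorts additionally have measurement batches, scheduled
(non-informative) visit mixtures, covariate-dependent enrolment, and
baseline shapes outside the log-linear family; recovery under the
generator demonstrates internal correctness of the estimation machinery,
not robustness to those features.

## The simulation-study harness

`runSimStudy()` simulates, fits, and reports per-parameter `True`, mean
estimate, `Bias`, `MSE`, `ASE` (mean model-based SE), `MCSD` (SD of
estimates), and 95% Wald coverage, plus the derived population-averaged
marker value at 10 years; non-converged replications are excluded and
counted.  Replication $r$ uses seed `seed + r` so each is individually
reproducible, and by default each fit warm-starts from the previous
converged optimum (pure optimizer plumbing: every fit is still judged by
its own convergence criterion).

Scaled-down defaults used by the package's own test suite (sizes chosen
as the study design for desk-scale verification): $N = 150$ with 15
replications for recovery and coverage, $N = 300$ with 2 paired
replications for the ignoring-the-visiting-process contrast, and
$N = 1000$ for the generator-level check, all with 4 GH nodes/dim,
replication fits at optimizer tolerance `1e-8` with a 150-iteration
cap, and cause baselines on
the minimal cubic basis (which spans the generating log-linear baselines
exactly).

Two classes of packed coordinates are reported but deliberately excluded
from the harness's recovery assertions, for reasons visible in their
Monte Carlo SDs: the matrix-logarithm coordinates of $D$ (rotation
coordinates that become nearly unidentified whenever two eigenvalues
approach each other, with correspondingly enormous SEs), and
cause-baseline spline coefficients whose basis mass sits where the
expected number of events is of order one at scaled-down $N$ (the MLE of
such a coefficient diverges whenever the corresponding region happens to
contain no events).  The scientifically interpreted parameters — fixed
effects, $\sigma^2$, history-feature coefficients, latent associations,
the visiting baseline, and the derived mean marker — are asserted.

## Known limitations

* Wald intervals on the packed scale can be poor for weakly identified
  spline coefficients at small event counts (see above).
* The pseudo-adaptive importance density uses the marker-only posterior;
  with very strong visiting associations the conditional tilt can demand
  more nodes (the node count is the knob).
* The gamma frailty applies to the visiting process only; frailty in the
  cause-specific hazards is out of scope.
* Interval censoring of the terminal event (relevant when "disengagement"
  is defined by a gap in visits) is not modeled.
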