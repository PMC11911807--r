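# visitjm

Joint models for a Gaussian longitudinal marker observed at irregular,
possibly **informative visit times**, with **informative competing
risks**.

## The problem

In clinic-based cohorts (the motivating setting is CD4 cell-count
monitoring in HIV care), the marker is only measured when the patient
shows up, and showing up may depend on how the patient is doing.  If
visit timing depends on the latent marker trajectory, a standard linear
mixed model over-represents the health states that trigger visits and
returns biased trajectories; terminal events (death, disengagement from
care) additionally cut observation short in a non-ignorable way.

`visitjm` fits a shared-parameter joint model with three linked
submodels sharing the random effects $b_i \sim N(0, D)$:

* **Marker:** $Y_i(t) = X_i^\top(t)\beta + Z_i^\top(t) b_i +
  \varepsilon_i(t)$, with latent value $m_i(t)$ and slope $m_i'(t)$;
* **Visiting process:** a proportional hazard for the time to the next
  visit on the gap-time scale $h_{v}(u) = h_{v0}(u)\exp\{\gamma_v^\top
  \bar X_{vi} + \phi_v^\top g_v(\bar Y_i) + \alpha_{v1} m_i(0) +
  \alpha_{v2} m_i'(t)\}$ — or a counting-process intensity on calendar
  time — with history covariates (most recent observed value, previous
  gap, visit count, ...), optional gamma frailty
  $w_i \sim \mathrm{Gamma}(1/\eta, 1/\eta)$, and cubic B-spline
  log-baselines;
* **Competing risks:** one cause-specific proportional hazard per
  terminal cause with the same structure.

Estimation is full marginal maximum likelihood: the likelihood
factorizes into the closed-form marker marginal times an integral over
$b_i$ of the visiting and competing-risk conditional likelihoods
against the marker-only posterior of $b_i$, evaluated by pseudo-adaptive
Gauss–Hermite (or Monte Carlo) quadrature, maximized by BFGS with an
analytic score, with inverse-Hessian standard errors.  A scenario
simulator and a replication harness (bias / MSE / ASE / MCSD / coverage)
are included.

## Worked example

Simulate from the gap-time informative-visiting scenario and fit the
correctly specified joint model plus the "ignore the visiting process"
comparator:

```r
library(visitjm)

scn <- scenarioGap()                 # beta = (17.20, 4.83, -2.80), ...
dat <- simulateData(scn, n = 300, seed = 1)
dat
#> Joint data: 300 subjects, 3336 visits (mean 11.12/subject)
#>   events by cause (0 = censored): 0=222, 1=38, 2=40

fit <- vjmFit(dat, scenarioConfig(scn, "correct", nodes = 4))
fit
#> Joint model fit (visiting scale: gap  )
#>   subjects: 300  visits: 3336  parameters: 38
#>   log-likelihood: -8683.337   AIC: 17442.674
#>   converged: TRUE (max |score| = 6.21e-02)

derivedMeanMarker(fit, t = 10)
#>    t estimate        se
#> 1 10 26.97406 0.6632531

ign <- vjmFit(dat, scenarioConfig(scn, "ignore-visits", nodes = 4))
derivedMeanMarker(ign, t = 10)
#>    t estimate        se
#> 1 10 26.72326 0.6619205
```

The population-averaged marker value at 10 years implied by the
generating fixed effects is $17.20 + 4.83\log(11) - 2.80 = 25.98$.  On
this single replicate both fits land within about 1.5 standard errors of
the truth; the systematic difference between them — the
ignore-the-visits comparator overestimating the late-time mean because
subjects with steeper latent trajectories contribute more late
measurements — is a property of the estimator's distribution and shows
up across replications in the harness below.
`summary(fit, exponentiate = TRUE)` prints the full parameter table with
hazard ratios; e.g. the latent-slope association in the visiting model
(`v.alpha.slope`, truth 0.20) is the log hazard ratio of making a visit
per unit latent slope.

The same machinery runs replication studies:

```r
rep <- runSimStudy(scenarioGap(), "correct", nReps = 15, n = 150,
                   seed = 2025, nodes = 4, causeKnots = numeric(0))
print(rep)   # True / Est / Bias / MSE / ASE / MCSD / Coverage per parameter
```

A thin command-line wrapper over the same functions is installed at
`inst/cli/visitjm.R` (`simulate`, `fit`, `simstudy` subcommands).
See the methods vignette (`vignettes/joint-visiting-models.Rmd`) for the
model, the numerical choices, the simulator's design, and known
limitations.

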