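# Hazard components: gap-time and calendar-time visiting likelihoods,
# gamma-frailty marginalization, and the cause-specific competing-risks
# likelihood, checked against closed forms and dense quadrature.

mbStudy <- logCubicBasis()
betaStudy <- c(17.20, 4.83, -2.80)

constVisit <- function(lambda, sb = constSpline(), ...) {
  visitParams(psi = rep(log(lambda), sb$ncoef), ...)
}

test_that("gap hazard reduces to 1 and obeys proportional hazards", {
  rec <- toyRecord()
  sb <- constSpline()
  vp0 <- visitParams(psi = rep(0, sb$ncoef))
  h <- gapHazard(c(0.2, 0.8), 2, rec, rep(0, 3), sb, vp0, mbStudy,
                 rep(0, 3))
  expect_equal(h, c(1, 1))
  # e^gamma per unit of a binary covariate
  vpW <- visitParams(psi = rep(0, sb$ncoef), coef = c(W = 0.7))
  rec0 <- toyRecord(W = 0); rec1 <- toyRecord(W = 1)
  h0 <- gapHazard(0.3, 2, rec0, rep(0, 3), sb, vpW, mbStudy, rep(0, 3))
  h1 <- gapHazard(0.3, 2, rec1, rep(0, 3), sb, vpW, mbStudy, rep(0, 3))
  expect_equal(h1 / h0, exp(0.7), tolerance = 1e-12)
})

test_that("hazard ratio per unit latent slope is exp(alpha2)", {
  rec <- toyRecord()
  sb <- constSpline()
  vp <- visitParams(psi = rep(0, sb$ncoef),
                    coef = c(last_y = 0.02, t_ij = -0.02,
                             prev_gap = -1.50),
                    alpha1 = 0.02, alpha2 = 0.20)
  j <- 2; u <- 0.35
  tstar <- rec$times[j] + u
  b <- c(0.4, -0.6, 0.2)
  # raising the log-time random slope by (tstar + 1) raises m'(tstar) by 1
  # without touching m(0) or any observed feature
  b2 <- b + c(0, tstar + 1, 0)
  h1 <- gapHazard(u, j, rec, b, sb, vp, mbStudy, betaStudy)
  h2 <- gapHazard(u, j, rec, b2, sb, vp, mbStudy, betaStudy)
  expect_equal(h2 / h1, exp(0.20), tolerance = 1e-10)
})

test_that("gap likelihood matches exponential closed forms", {
  lam <- 1.7
  sb <- constSpline()
  vp <- constVisit(lam)
  u <- 0.9
  rec <- subjectRecord("a", c(0, u), c(17, 18), Tobs = u)
  expect_equal(gapLoglikConditional(rec, rep(0, 3), sb, vp, mbStudy,
                                    rep(0, 3)),
               log(lam) - lam * u, tolerance = 1e-10)
  recc <- subjectRecord("b", 0, 17, Tobs = u)
  expect_equal(gapLoglikConditional(recc, rep(0, 3), sb, vp, mbStudy,
                                    rep(0, 3)),
               -lam * u, tolerance = 1e-10)
})

test_that("integrated gap hazard matches dense trapezoid quadrature", {
  rec <- toyRecord()
  sb <- splineBasisHazard(interior = c(0.5), boundary = c(0, 2))
  set.seed(8)
  vp <- visitParams(psi = rnorm(sb$ncoef, -0.3, 0.4),
                    coef = c(last_y = 0.03, prev_gap = -0.8),
                    alpha1 = 0.02, alpha2 = 0.15)
  b <- c(0.5, -0.8, 0.3)
  ll <- gapLoglikConditional(rec, b, sb, vp, mbStudy, betaStudy)
  gaps <- c(diff(rec$times), rec$Tobs - rec$times[rec$n])
  evLog <- sum(log(vapply(seq_len(rec$n - 1), function(j)
    gapHazard(gaps[j], j, rec, b, sb, vp, mbStudy, betaStudy),
    numeric(1))))
  cum <- sum(vapply(seq_len(rec$n), function(j) {
    s <- seq(0, gaps[j], length.out = 10001)
    h <- gapHazard(s, j, rec, b, sb, vp, mbStudy, betaStudy)
    sum((h[-1] + h[-length(h)]) / 2) * diff(s)[1]
  }, numeric(1)))
  expect_equal(ll, evLog - cum, tolerance = 1e-6)
})

test_that("calendar intensity likelihood matches Poisson closed form", {
  lam <- 0.8
  sb <- constSpline(boundary = c(0, 5))
  vp <- constVisit(lam, sb)
  rec <- subjectRecord("a", c(0, 0.7, 1.9), c(17, 18, 16), Tobs = 3.1)
  expect_equal(intensityLoglikConditional(rec, rep(0, 3), sb, vp, mbStudy,
                                          rep(0, 3)),
               2 * log(lam) - lam * 3.1, tolerance = 1e-10)
})

test_that("time-varying intensity matches the analytic integral", {
  a <- -0.4; bslope <- 0.3
  sb <- splineBasisHazard(interior = c(1), boundary = c(0, 3))
  vp <- visitParams(psi = a + bslope * grevilleSites(sb))
  rec <- subjectRecord("a", 0, 17, Tobs = 2)
  expect_equal(intensityLoglikConditional(rec, rep(0, 3), sb, vp, mbStudy,
                                          rep(0, 3)),
               -(exp(a + 2 * bslope) - exp(a)) / bslope,
               tolerance = 1e-10)
})

test_that("gap and calendar likelihoods coincide for constant hazards", {
  lam <- 1.1
  sbG <- constSpline(boundary = c(0, 4))
  sbC <- constSpline(boundary = c(0, 6))
  vp <- visitParams(psi = rep(log(lam), sbG$ncoef),
                    coef = c(last_y = 0.04, W = -0.3), alpha1 = 0.05)
  vpC <- visitParams(psi = rep(log(lam), sbC$ncoef),
                     coef = c(last_y = 0.04, W = -0.3), alpha1 = 0.05)
  rec <- toyRecord()
  b <- c(0.2, -0.4, 0.1)
  expect_equal(gapLoglikConditional(rec, b, sbG, vp, mbStudy, betaStudy),
               intensityLoglikConditional(rec, b, sbC, vpC, mbStudy,
                                          betaStudy),
               tolerance = 1e-9)
})

test_that("frailty marginal likelihood has the right limits", {
  sb <- constSpline()
  rec <- toyRecord()
  b <- c(0.1, 0.2, -0.1)
  vp0 <- visitParams(psi = rep(-0.4, sb$ncoef), coef = c(last_y = 0.02),
                     alpha1 = 0.01, alpha2 = 0.1)
  ll0 <- gapLoglikConditional(rec, b, sb, vp0, mbStudy, betaStudy)
  vpe <- vp0; vpe$eta <- 1e-6
  lle <- frailtyMarginalLoglik(rec, b, sb, vpe, mbStudy, betaStudy)
  expect_lt(abs(lle - ll0) / abs(ll0), 1e-4)
  # d = 0: Laplace transform of the gamma frailty
  lam <- 0.9; Tobs <- 2.3; eta <- 0.5
  rec0 <- subjectRecord("c", 0, 17, Tobs = Tobs)
  vpc <- constVisit(lam); vpc$eta <- eta
  expect_equal(frailtyMarginalLoglik(rec0, rep(0, 3), constSpline(), vpc,
                                     mbStudy, rep(0, 3)),
               -(1 / eta) * log(1 + eta * lam * Tobs), tolerance = 1e-10)
})

test_that("frailty closed form matches 60-point Gauss-Laguerre", {
  sb <- splineBasisHazard(interior = c(0.6), boundary = c(0, 2.5))
  set.seed(12)
  vp <- visitParams(psi = rnorm(sb$ncoef, -0.2, 0.3),
                    coef = c(last_y = 0.02, t_ij = -0.05),
                    alpha1 = 0.02, alpha2 = 0.12, eta = 0.4)
  rec <- toyRecord()
  b <- c(0.3, -0.5, 0.2)
  ll <- frailtyMarginalLoglik(rec, b, sb, vp, mbStudy, betaStudy)
  # frailty-free event sum S and cumulative Lambda
  vp0 <- vp; vp0$eta <- 0
  cond <- gapLoglikConditional(rec, b, sb, vp0, mbStudy, betaStudy)
  gaps <- diff(rec$times)
  S <- sum(log(vapply(seq_len(rec$n - 1), function(j)
    gapHazard(gaps[j], j, rec, b, sb, vp0, mbStudy, betaStudy),
    numeric(1))))
  Lam <- S - cond
  d <- rec$n - 1
  nu <- 1 / vp$eta
  gl <- oracleGaussLaguerre(60)
  lref <- logSumExpOracle(log(gl$w) + d * (log(gl$x) - log(nu)) + S -
                          gl$x * Lam / nu + (nu - 1) * log(gl$x) -
                          lgamma(nu))
  expect_equal(ll, lref, tolerance = 1e-6)
})

test_that("frailty marginal decreases with the integrated hazard", {
  sb <- constSpline()
  rec <- toyRecord()
  vals <- vapply(c(0.5, 1, 2, 4), function(lam) {
    vp <- constVisit(lam); vp$eta <- 0.4
    # remove the event-term dependence on the baseline level so only the
    # cumulative-hazard part varies
    frailtyMarginalLoglik(rec, rep(0, 3), sb, vp, mbStudy, rep(0, 3)) -
      (rec$n - 1) * log(lam)
  }, numeric(1))
  expect_true(all(diff(vals) < 0))
})

test_that("competing-risks likelihood matches constant-hazard closed forms", {
  mb0 <- mbStudy
  sb <- constSpline(boundary = c(0, 5))
  lam1 <- 0.25; lam2 <- 0.4; Tobs <- 2.8
  c1 <- causeParams(psi = rep(log(lam1), sb$ncoef))
  c2 <- causeParams(psi = rep(log(lam2), sb$ncoef))
  rec1 <- subjectRecord("a", 0, 17, Tobs = Tobs, cause = 1L)
  expect_equal(competingLoglikConditional(rec1, rep(0, 3), list(sb),
                                          list(c1), mb0, rep(0, 3)),
               log(lam1) - lam1 * Tobs, tolerance = 1e-10)
  rec0 <- subjectRecord("b", 0, 17, Tobs = Tobs, cause = 0L)
  expect_equal(competingLoglikConditional(rec0, rep(0, 3), list(sb, sb),
                                          list(c1, c2), mb0, rep(0, 3)),
               -(lam1 + lam2) * Tobs, tolerance = 1e-10)
})

test_that("piecewise competing-risks hazard matches dense quadrature", {
  sb <- splineBasisHazard(interior = c(2), boundary = c(0, 5))
  set.seed(19)
  cp <- causeParams(psi = rnorm(sb$ncoef, -1, 0.3),
                    coef = c(last_y = -0.1, W = 0.4),
                    alpha1 = -0.05, alpha2 = -0.1)
  rec <- toyRecord(cause = 1L)
  b <- c(0.6, -0.3, 0.2)
  ll <- competingLoglikConditional(rec, b, list(sb), list(cp), mbStudy,
                                   betaStudy)
  m0 <- trueValueSlope(b, mbStudy, betaStudy, 0)$value
  lp0 <- drop(historyFeatures(rec, names(cp$coef)) %*% cp$coef)
  hz <- function(t, j) {
    sl <- trueValueSlope(b, mbStudy, betaStudy, t)$slope
    exp(logBaseline(sb, cp$psi, t) + lp0[j] + cp$alpha1 * m0 +
        cp$alpha2 * sl)
  }
  lows <- rec$times; ups <- c(rec$times[-1], rec$Tobs)
  cum <- sum(vapply(seq_len(rec$n), function(j) {
    s <- seq(lows[j], ups[j], length.out = 10001)
    h <- hz(s, j)
    sum((h[-1] + h[-length(h)]) / 2) * diff(s)[1]
  }, numeric(1)))
  expect_equal(ll, log(hz(rec$Tobs, rec$n)) - cum, tolerance = 1e-6)
})

test_that("likelihoods are invariant to cause and feature relabeling", {
  sb <- constSpline(boundary = c(0, 5))
  c1 <- causeParams(psi = rep(-1, sb$ncoef), coef = c(last_y = -0.1))
  c2 <- causeParams(psi = rep(-2, sb$ncoef), coef = c(W = 0.4))
  rec <- toyRecord(cause = 2L)
  recSwap <- toyRecord(cause = 1L)
  b <- c(0.1, 0.1, 0.1)
  expect_equal(
    competingLoglikConditional(rec, b, list(sb, sb), list(c1, c2),
                               mbStudy, betaStudy),
    competingLoglikConditional(recSwap, b, list(sb, sb), list(c2, c1),
                               mbStudy, betaStudy),
    tolerance = 1e-12)
  vpA <- visitParams(psi = rep(-0.5, 6), coef = c(last_y = 0.02, W = -0.3))
  vpB <- visitParams(psi = rep(-0.5, 6), coef = c(W = -0.3, last_y = 0.02))
  sb5 <- constSpline()
  expect_equal(gapLoglikConditional(rec, b, sb5, vpA, mbStudy, betaStudy),
               gapLoglikConditional(rec, b, sb5, vpB, mbStudy, betaStudy),
               tolerance = 1e-12)
})

test_that("a shift in an always-on coefficient acts multiplicatively", {
  sb <- constSpline()
  rec <- toyRecord(W = 1)
  b <- rep(0, 3)
  gam <- 0.3; cc <- 0.5
  vp1 <- visitParams(psi = rep(-0.2, sb$ncoef), coef = c(W = gam))
  vp2 <- visitParams(psi = rep(-0.2, sb$ncoef), coef = c(W = gam + cc))
  ll1 <- gapLoglikConditional(rec, b, sb, vp1, mbStudy, rep(0, 3))
  ll2 <- gapLoglikConditional(rec, b, sb, vp2, mbStudy, rep(0, 3))
  d <- rec$n - 1
  # event terms at W = 1 pick up c each; cumulative terms scale by e^c
  S1 <- d * (-0.2 + gam)
  Lam1 <- S1 - ll1
  expect_equal(ll2 - ll1, cc * d - (exp(cc) - 1) * Lam1, tolerance = 1e-9)
})
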