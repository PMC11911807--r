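# Parameter transforms, the assembled joint likelihood, the analytic
# score, initialization, and derived quantities.

oneBasis <- function()
  markerBasis(list(one = function(t) rep(1, length(t))),
              fixedDeriv = list(function(t) rep(0, length(t))))

test_that("pack/unpack is an exact round trip", {
  dat <- smallData(6)
  fr <- modelFrame(dat, smallConfig())
  sk <- fr$skeleton
  set.seed(2)
  A <- matrix(rnorm(9), 3)
  D <- crossprod(A) + diag(3)
  th <- list(
    lmm = lmmParams(c(17, 5, -3), D, 6),
    visiting = visitParams(psi = rnorm(fr$visitBasis$ncoef),
                           coef = c(last_y = 0.02, t_ij = -0.02,
                                    prev_gap = -1.5),
                           alpha1 = 0.02, alpha2 = 0.2),
    causes = list(
      causeParams(psi = rnorm(fr$causeBases[[1]]$ncoef),
                  coef = c(last_y = -0.2, W = 0.5),
                  alpha1 = -0.05, alpha2 = -0.1),
      causeParams(psi = rnorm(fr$causeBases[[2]]$ncoef),
                  coef = c(last_y = -0.02, prev_gap = 1.4, W = 0.5),
                  alpha1 = -0.05, alpha2 = -0.2)))
  pk <- packParams(th, sk)
  expect_equal(length(pk), sk$npar)
  th2 <- unpackParams(pk, sk, fr)
  expect_equal(th2$lmm$D, D, tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(th2$lmm$sigma2, 6, tolerance = 1e-12)
  expect_equal(th2$visiting$coef, th$visiting$coef, tolerance = 1e-12)
  expect_equal(th2$causes[[2]]$psi, th$causes[[2]]$psi, tolerance = 1e-12)
  # identity covariance packs to a zero matrix-log
  th$lmm <- lmmParams(c(17, 5, -3), diag(3), 6)
  expect_equal(unname(packParams(th, sk)[sk$idx$D]), rep(0, 6))
})

test_that("marker-only joint likelihood equals the sum of marginals", {
  dat0 <- smallData(8)
  dat <- jointData(lapply(dat0$records, function(r)
    subjectRecord(r$id, r$times, r$y, r$Tobs, 0L, r$covariates)))
  cfg <- list(marker = list(basis = logCubicBasis()),
              visiting = list(scale = "none"), causes = list())
  fr <- modelFrame(dat, cfg)
  th <- list(lmm = lmmParams(c(17, 5, -3), scenarioGap()$D, 6),
             visiting = NULL, causes = list())
  pk <- packParams(th, fr$skeleton)
  ll <- jointLoglik(pk, fr)
  ref <- sum(vapply(fr$subs, function(s)
    markerMarginalLoglik(s$y, s$X, s$Z, th$lmm), numeric(1)))
  expect_equal(as.numeric(ll), ref, tolerance = 1e-10)
})

test_that("with no latent associations the likelihood separates", {
  dat <- smallData(8)
  fr <- modelFrame(dat, smallConfig(nodes = 3))
  th <- list(
    lmm = lmmParams(c(17.2, 4.8, -2.8), scenarioGap()$D, 6.25),
    visiting = visitParams(psi = rep(-0.1, fr$visitBasis$ncoef),
                           coef = c(last_y = 0, t_ij = 0, prev_gap = 0),
                           alpha1 = 0, alpha2 = 0),
    causes = list(
      causeParams(psi = rep(-2, fr$causeBases[[1]]$ncoef),
                  coef = c(last_y = 0, W = 0), alpha1 = 0, alpha2 = 0),
      causeParams(psi = rep(-2.5, fr$causeBases[[2]]$ncoef),
                  coef = c(last_y = 0, prev_gap = 0, W = 0),
                  alpha1 = 0, alpha2 = 0)))
  pk <- packParams(th, fr$skeleton)
  ll <- jointLoglik(pk, fr)
  b0 <- rep(0, 3)
  mb <- logCubicBasis()
  ref <- sum(vapply(seq_along(dat$records), function(i) {
    s <- fr$subs[[i]]; r <- dat$records[[i]]
    markerMarginalLoglik(s$y, s$X, s$Z, th$lmm) +
      gapLoglikConditional(r, b0, fr$visitBasis, th$visiting, mb,
                           th$lmm$beta) +
      competingLoglikConditional(r, b0, fr$causeBases, th$causes, mb,
                                 th$lmm$beta)
  }, numeric(1)))
  expect_equal(as.numeric(ll), ref, tolerance = 1e-9)
})

test_that("fast likelihood equals the reference per-subject assembly", {
  dat <- smallData(6)
  fr <- modelFrame(dat, smallConfig(nodes = 5))
  pk <- vjmInit(fr)
  pk[fr$skeleton$idx$v$alpha1] <- 0.02
  pk[fr$skeleton$idx$v$alpha2] <- 0.2
  pk[fr$skeleton$idx$causes[[1]]$alpha2] <- -0.1
  th <- unpackParams(pk, fr$skeleton, fr)
  rule <- quadratureRule(3, "GH", nodes = 5)
  mb <- logCubicBasis()
  ref <- sum(vapply(seq_along(dat$records), function(i) {
    s <- fr$subs[[i]]; r <- dat$records[[i]]
    post <- posteriorRE(s$y, s$X, s$Z, th$lmm)
    cl <- function(B) vapply(seq_len(ncol(B)), function(m)
      gapLoglikConditional(r, B[, m], fr$visitBasis, th$visiting, mb,
                           th$lmm$beta) +
      competingLoglikConditional(r, B[, m], fr$causeBases, th$causes, mb,
                                 th$lmm$beta), numeric(1))
    markerMarginalLoglik(s$y, s$X, s$Z, th$lmm) +
      marginalizeRE(cl, post, rule)$logMarginal
  }, numeric(1)))
  expect_equal(as.numeric(jointLoglik(pk, fr, rule)), ref,
               tolerance = 1e-8)
})

test_that("a single-subject toy matches hand-assembled closed forms", {
  u1 <- 0.6; t2 <- 0.6; Tobs <- 1.4
  rec <- subjectRecord("a", c(0, t2), c(16, 18), Tobs, cause = 1L,
                       covariates = list(W = 1))
  dat <- jointData(list(rec))
  cfg <- list(
    marker = list(basis = logCubicBasis()),
    visiting = list(scale = "gap", features = character(),
                    assocM0 = FALSE, assocSlope = FALSE,
                    knots = numeric(), boundary = c(0, 2)),
    causes = list(list(features = character(), assocM0 = FALSE,
                       assocSlope = FALSE, knots = numeric(),
                       boundary = c(0, 2))))
  fr <- modelFrame(dat, cfg)
  lamV <- 1.3; lam1 <- 0.4
  th <- list(lmm = lmmParams(c(17, 5, -3), scenarioGap()$D, 6),
             visiting = visitParams(psi = rep(log(lamV),
                                             fr$visitBasis$ncoef)),
             causes = list(causeParams(psi = rep(log(lam1),
                                                fr$causeBases[[1]]$ncoef))))
  pk <- packParams(th, fr$skeleton)
  s <- fr$subs[[1]]
  ref <- markerMarginalLoglik(s$y, s$X, s$Z, th$lmm) +
    (log(lamV) - lamV * u1 - lamV * (Tobs - t2)) +
    (log(lam1) - lam1 * Tobs)
  expect_equal(as.numeric(jointLoglik(pk, fr)), ref, tolerance = 1e-9)
})

test_that("the joint likelihood is invariant to subject order", {
  dat <- smallData(7)
  cfg <- smallConfig(nodes = 3)
  fr1 <- modelFrame(dat, cfg)
  dat2 <- jointData(rev(dat$records))
  fr2 <- modelFrame(dat2, cfg)
  pk <- vjmInit(fr1)
  expect_equal(as.numeric(jointLoglik(pk, fr1)),
               as.numeric(jointLoglik(pk, fr2)), tolerance = 1e-10)
})

test_that("the analytic score matches finite differences in all blocks", {
  datGap <- smallData(10, seed = 71)
  datCal <- simulateData(scenarioCalendar(), 10, seed = 72)
  cases <- list(
    list(dat = datGap, scn = scenarioGap(), frailty = FALSE),
    list(dat = datCal, scn = scenarioCalendar(), frailty = FALSE),
    list(dat = simulateData(scenarioGap(frailty = TRUE), 10, seed = 73),
         scn = scenarioGap(frailty = TRUE), frailty = TRUE))
  for (cs in cases) {
    # the anchored (fixed-node) objective, whose exact gradient is the
    # analytic score, at 5 nodes/dim; plus the per-evaluation adaptive
    # objective at 9 nodes/dim, where the two converge
    cfg <- scenarioConfig(cs$scn, "correct", nodes = 5)
    fr <- modelFrame(cs$dat, cfg)
    rule <- quadratureRule(3, "GH", nodes = 5)
    set.seed(99)
    p0 <- vjmInit(fr) + rnorm(fr$skeleton$npar, sd = 0.03)
    thA <- unpackParams(p0, fr$skeleton, fr)
    anc <- frameAnchor(fr, thA$lmm, rule)
    sc <- jointScore(p0, fr, rule, anc)
    fd <- fdGrad(function(v)
      as.numeric(jointLoglik(v, fr, rule, anc)), p0)
    expect_lt(max(abs(sc - fd) / pmax(1e-3, abs(fd))), 1e-4)
  }
  # adaptive route on one case at converged node counts
  cs <- cases[[1]]
  fr <- modelFrame(cs$dat, scenarioConfig(cs$scn, "correct", nodes = 9))
  rule9 <- quadratureRule(3, "GH", nodes = 9)
  set.seed(99)
  p0 <- vjmInit(fr) + rnorm(fr$skeleton$npar, sd = 0.03)
  sc <- jointScore(p0, fr, rule9)
  fd <- fdGrad(function(v) as.numeric(jointLoglik(v, fr, rule9)), p0)
  expect_lt(max(abs(sc - fd) / pmax(1e-3, abs(fd))), 1e-4)
})

test_that("b-free parameters reduce to the survival-block gradient", {
  dat <- smallData(8)
  cfg <- smallConfig(nodes = 3)
  fr <- modelFrame(dat, cfg)
  pk <- vjmInit(fr)   # all alphas zero at initialization
  sc <- jointScore(pk, fr)
  th <- unpackParams(pk, fr$skeleton, fr)
  mb <- logCubicBasis()
  iW <- which(names(pk) == "s1.W")
  survW <- function(g) {
    th$causes[[1]]$coef["W"] <- g
    sum(vapply(dat$records, function(r)
      competingLoglikConditional(r, rep(0, 3), fr$causeBases, th$causes,
                                 mb, th$lmm$beta), numeric(1)))
  }
  h <- 1e-6
  fd <- (survW(th$causes[[1]]$coef["W"] + h) -
         survW(th$causes[[1]]$coef["W"] - h)) / (2 * h)
  expect_equal(unname(sc[iW]), fd, tolerance = 1e-6)
})

test_that("dropping the visiting block matches an independent joint model", {
  set.seed(41)
  base <- smallData(6, seed = 44)
  recs <- lapply(base$records, function(r)
    subjectRecord(r$id, r$times, r$y, r$Tobs,
                  as.integer(r$cause == 1L), r$covariates))
  dat <- jointData(recs)
  cfg <- list(
    marker = list(basis = oneBasis()),
    visiting = list(scale = "none"),
    causes = list(list(features = character(), assocM0 = TRUE,
                       assocSlope = FALSE, knots = numeric(),
                       boundary = c(0, 10))),
    quadrature = list(nodes = 25))
  fr <- modelFrame(dat, cfg)
  beta0 <- 17; d <- 4; s2 <- 6; a1 <- -0.06
  sb <- fr$causeBases[[1]]
  psi <- c(-1.1, -0.8, -1.4, -0.9)
  th <- list(lmm = lmmParams(beta0, matrix(d), s2), visiting = NULL,
             causes = list(causeParams(psi = psi, alpha1 = a1)))
  pk <- packParams(th, fr$skeleton)
  expect_equal(unname(pk[fr$skeleton$idx$D]), log(d))
  # independent route: closed-form marker marginal x 1-d quadrature of
  # the survival likelihood against the exact posterior of b
  ref <- sum(vapply(dat$records, function(r) {
    n <- r$n
    V <- s2 * diag(n) + d
    llY <- denseMvnLogd(r$y, rep(beta0, n), V)
    Cpost <- 1 / (1 / d + n / s2)
    mpost <- Cpost * sum(r$y - beta0) / s2
    H0 <- integrate(function(s) exp(logBaseline(sb, psi, s)), 0,
                    r$Tobs, rel.tol = 1e-10)$value
    h0T <- exp(logBaseline(sb, psi, r$Tobs))
    f <- function(b) {
      m0 <- beta0 + b
      (h0T * exp(a1 * m0))^(r$cause == 1) * exp(-H0 * exp(a1 * m0)) *
        dnorm(b, mpost, sqrt(Cpost))
    }
    llS <- log(integrate(Vectorize(f), -30, 30, rel.tol = 1e-10)$value)
    llY + llS
  }, numeric(1)))
  expect_equal(as.numeric(jointLoglik(pk, fr)), ref, tolerance = 1e-6)
})

test_that("initialization follows the staged recipe", {
  dat <- smallData(15, seed = 91)
  fr <- modelFrame(dat, smallConfig(nodes = 3))
  pk <- vjmInit(fr)
  idx <- fr$skeleton$idx
  expect_equal(unname(pk[idx$v$alpha1]), 0)
  expect_equal(unname(pk[idx$v$alpha2]), 0)
  expect_equal(unname(pk[idx$v$coef]), rep(0, 3))
  dtot <- sum(vapply(dat$records, function(r) r$n - 1, numeric(1)))
  Ttot <- sum(vapply(dat$records, function(r) r$Tobs, numeric(1)))
  expect_equal(unname(pk[idx$v$psi]),
               rep(log(dtot / Ttot), fr$visitBasis$ncoef))
  d1 <- sum(vapply(dat$records, function(r) r$cause == 1L, logical(1)))
  expect_equal(unname(pk[idx$causes[[1]]$psi]),
               rep(log(max(d1, 0.5) / Ttot), fr$causeBases[[1]]$ncoef))
})

test_that("stage-1 initialization recovers the marker fixed effects", {
  scn <- scenarioGap()
  scn$visiting$features[] <- 0
  scn$visiting$alpha1 <- 0; scn$visiting$alpha2 <- 0
  scn$visiting$base <- c(log(1.5), 0)
  for (k in 1:2) {
    scn$causes[[k]]$features[] <- 0
    scn$causes[[k]]$alpha1 <- 0; scn$causes[[k]]$alpha2 <- 0
    scn$causes[[k]]$base <- c(-3.2, 0)
  }
  dat <- simulateData(scn, 120, seed = 5)
  fr <- modelFrame(dat, smallConfig(scn, nodes = 3))
  pk <- vjmInit(fr)
  beta <- pk[fr$skeleton$idx$beta]
  expect_lt(abs(beta[1] - 17.20), 1.2)
  expect_lt(abs(beta[2] - 4.83), 0.7)
  expect_lt(abs(beta[3] - (-2.80)), 2.0)
})

test_that("derived mean marker applies the delta method", {
  dat <- smallData(5)
  fr <- modelFrame(dat, smallConfig(nodes = 3))
  np <- fr$skeleton$npar
  coefs <- numeric(np)
  names(coefs) <- fr$skeleton$names
  coefs[fr$skeleton$idx$beta] <- c(17.20, 4.83, -2.80)
  V <- diag(seq_len(np) * 0.001)
  dimnames(V) <- list(names(coefs), names(coefs))
  fit <- structure(list(coefficients = coefs, vcov = V,
                        se = sqrt(diag(V)), skeleton = fr$skeleton,
                        config = fr$config), class = "vjm")
  d0 <- derivedMeanMarker(fit, 0)
  expect_equal(d0$estimate, 17.20)
  d10 <- derivedMeanMarker(fit, 10)
  expect_equal(round(d10$estimate, 2), 25.98)
  x <- c(1, log(11), 1)
  expect_equal(d10$se, sqrt(sum(x^2 * diag(V)[1:3])), tolerance = 1e-12)
})
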