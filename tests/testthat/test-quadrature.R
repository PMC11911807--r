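# Quadrature machinery: Gauss-Kronrod panels, Gauss-Hermite rules, and the
# pseudo-adaptive marginalization over the random effects.

test_that("15-point Gauss-Kronrod is exact on polynomials and sharp on exp", {
  expect_equal(gaussKronrod15(function(t) rep(1, length(t)), 0, 1), 1)
  expect_equal(gaussKronrod15(function(t) t^4, 0, 1), 0.2,
               tolerance = 1e-14)
  expect_equal(gaussKronrod15(function(t) exp(0.3 * t), 0, 2),
               (exp(0.6) - 1) / 0.3, tolerance = 1e-12)
  expect_error(gaussKronrod15(identity, 1, 0), "a <= b")
})

test_that("Gauss-Hermite rules integrate polynomials to degree 2N - 1", {
  for (n in c(3, 5, 8)) {
    r <- quadratureRule(1, "GH", nodes = n)
    # E[x^k] under N(0, 1/2): nodes are the raw GH points, weights
    # normalized; moments of the Gaussian weight
    x <- drop(r$A)
    w <- exp(r$logw)
    expect_equal(sum(w), 1, tolerance = 1e-12)
    for (k in seq_len(2 * n - 1)) {
      mom <- if (k %% 2 == 1) 0 else prod(seq(1, k - 1, by = 2)) / 2^(k / 2)
      expect_equal(sum(w * x^k), mom, tolerance = 1e-9)
    }
  }
})

test_that("marginalization preserves constants and normalizes weights", {
  post <- structure(list(mu = c(0.3, -0.2), C = diag(2) * 0.5,
                         B = chol(solve(diag(2) * 0.5))),
                    class = "posteriorRE")
  for (kind in c("GH", "MC")) {
    r <- quadratureRule(2, kind, nodes = 5, draws = 64, seed = 4)
    mg <- marginalizeRE(function(B) rep(-3.2, ncol(B)), post, r)
    expect_equal(mg$logMarginal, -3.2, tolerance = 1e-12)
    expect_true(all(mg$weights >= 0))
    expect_equal(sum(mg$weights), 1, tolerance = 1e-12)
  }
})

test_that("polynomial moments are integrated exactly (q = 1)", {
  # integrands whose exponential is a low-degree polynomial are within the
  # quadrature's exactness degree for any N >= 2
  mu <- 0.4; C <- 0.9
  post <- structure(list(mu = mu, C = matrix(C),
                         B = matrix(sqrt(1 / C))), class = "posteriorRE")
  r <- quadratureRule(1, "GH", nodes = 5)
  mg <- marginalizeRE(function(B) log(1 + drop(B)^2), post, r)
  expect_equal(mg$logMarginal, log(1 + C + mu^2), tolerance = 1e-12)
})

test_that("Gaussian-quadratic integrands reproduce the convolution", {
  mu <- 0.4; C <- 0.9; a <- 1.7; m <- -0.6; cst <- 0.8
  post <- structure(list(mu = mu, C = matrix(C),
                         B = matrix(sqrt(1 / C))), class = "posteriorRE")
  closed <- cst - 0.5 * log(1 + a * C) - a * (m - mu)^2 / (2 * (1 + a * C))
  vals <- vapply(c(5, 15, 40), function(nd)
    marginalizeRE(function(B) cst - a / 2 * (drop(B) - m)^2, post,
                  quadratureRule(1, "GH", nodes = nd))$logMarginal,
    numeric(1))
  # geometric convergence toward the closed form; converged by 40 nodes
  errs <- abs(vals - closed)
  expect_true(all(diff(errs) < 0))
  expect_lt(errs[3], 1e-10)
})

test_that("GH and Monte Carlo marginals agree on a joint-model instance", {
  scn <- scenarioGap()
  dat <- smallData(1, seed = 31)
  rec <- dat$records[[1]]
  mb <- logCubicBasis()
  lp <- lmmParams(scn$beta, scn$D, scn$sigma2)
  sb <- constSpline(c(0, 3), c(0.5, 1))
  vp <- visitParams(psi = rep(-0.2, sb$ncoef),
                    coef = c(last_y = 0.02, t_ij = -0.02),
                    alpha1 = 0.02, alpha2 = 0.2)
  X <- evalBasis(mb, rec$times); Z <- X
  post <- posteriorRE(rec$y, X, Z, lp)
  cl <- function(B) vapply(seq_len(ncol(B)), function(m)
    gapLoglikConditional(rec, B[, m], sb, vp, mb, scn$beta), numeric(1))
  gh <- marginalizeRE(cl, post, quadratureRule(3, "GH", nodes = 9))
  mc <- marginalizeRE(cl, post,
                      quadratureRule(3, "MC", draws = 4096, seed = 9))
  expect_lt(abs(gh$logMarginal - mc$logMarginal), 3 * mc$se)
})

test_that("the importance transform is invariant to the factor B", {
  # Gaussian-quadratic integrand: any B with B'B = C^{-1} integrates it
  # exactly, so the marginal cannot depend on the factor chosen
  C <- matrix(c(0.8, 0.3, 0.3, 0.6), 2)
  Cinv <- solve(C)
  e <- eigen(Cinv, symmetric = TRUE)
  Bs <- list(chol(Cinv),
             diag(sqrt(e$values)) %*% t(e$vectors))
  m <- c(0.5, -1)
  cl <- function(B) log(1 + colSums((B - m))^2)
  vals <- vapply(Bs, function(B) {
    post <- structure(list(mu = c(0.1, 0.2), C = C, B = B),
                      class = "posteriorRE")
    marginalizeRE(cl, post, quadratureRule(2, "GH", nodes = 7))$logMarginal
  }, numeric(1))
  expect_equal(vals[1], vals[2], tolerance = 1e-10)
})

test_that("increasing GH nodes converges monotonically on a test instance", {
  scn <- scenarioGap()
  dat <- smallData(1, seed = 77)
  rec <- dat$records[[1]]
  mb <- logCubicBasis()
  lp <- lmmParams(scn$beta, scn$D, scn$sigma2)
  sb <- constSpline(c(0, 3), c(0.5, 1))
  vp <- visitParams(psi = rep(-0.1, sb$ncoef), coef = c(last_y = 0.02),
                    alpha1 = 0.02, alpha2 = 0.2)
  X <- evalBasis(mb, rec$times)
  post <- posteriorRE(rec$y, X, X, lp)
  cl <- function(B) vapply(seq_len(ncol(B)), function(m)
    gapLoglikConditional(rec, B[, m], sb, vp, mb, scn$beta), numeric(1))
  L <- vapply(c(5, 7, 9, 15), function(nd)
    marginalizeRE(cl, post, quadratureRule(3, "GH", nodes = nd))$logMarginal,
    numeric(1))
  errs <- abs(L[1:3] - L[4])
  expect_true(all(diff(errs) <= 1e-12))
})
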