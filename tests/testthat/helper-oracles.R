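# Independent oracles and small builders used across the test files.
# Everything here is deliberately written without reference to the package
# internals (dense-matrix densities, textbook quadrature rules, central
# differences) so that package results are checked against a second route.

# multivariate normal log-density via dense solve (no Cholesky tricks)
denseMvnLogd <- function(x, mean, Sigma) {
  k <- length(x)
  r <- x - mean
  -0.5 * (k * log(2 * pi) + log(det(Sigma)) +
          drop(t(r) %*% solve(Sigma) %*% r))
}

# central finite-difference gradient
fdGrad <- function(f, x, h = 1e-4) {
  vapply(seq_along(x), function(j) {
    hj <- h * (1 + abs(x[j]))
    up <- x; up[j] <- up[j] + hj
    lo <- x; lo[j] <- lo[j] - hj
    (f(up) - f(lo)) / (2 * hj)
  }, numeric(1))
}

# Golub-Welsch Gauss-Hermite (physicists' weight exp(-x^2)), independent
# of the package implementation
oracleGaussHermite <- function(n) {
  i <- seq_len(n - 1)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1)] <- J[cbind(i + 1, i)] <- sqrt(i / 2)
  e <- eigen(J, symmetric = TRUE)
  list(x = e$values, w = sqrt(pi) * e$vectors[1, ]^2)
}

# Golub-Welsch Gauss-Laguerre (weight exp(-x) on [0, Inf))
oracleGaussLaguerre <- function(n) {
  i <- seq_len(n)
  J <- diag(2 * i - 1)
  off <- seq_len(n - 1)
  J[cbind(off, off + 1)] <- J[cbind(off + 1, off)] <- off
  e <- eigen(J, symmetric = TRUE)
  ord <- order(e$values)
  list(x = e$values[ord], w = (e$vectors[1, ]^2)[ord])
}

logSumExpOracle <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}

# a small deterministic subject record with a baseline visit
toyRecord <- function(id = "s1", times = c(0, 0.4, 1.1, 2.0), Tobs = 2.6,
                      cause = 1L, W = 1, yshift = 0) {
  set.seed(42 + yshift)
  subjectRecord(id, times, 17 + cumsum(rnorm(length(times))) + yshift,
                Tobs, cause, covariates = list(W = W))
}

# constant-achieving spline: equal coefficients give log-baseline = c
constSpline <- function(boundary = c(0, 5), interior = c(1, 2))
  splineBasisHazard(interior = interior, boundary = boundary)

# a tiny joint data set simulated from the gap scenario
smallData <- function(n = 12, seed = 7, scn = scenarioGap()) {
  simulateData(scn, n, seed = seed)
}

smallConfig <- function(scn = scenarioGap(), nodes = 7, ...) {
  scenarioConfig(scn, "correct", nodes = nodes, ...)
}
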