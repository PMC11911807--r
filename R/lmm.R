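#' Linear mixed model parameters
#'
#' Container for the marker submodel parameters: fixed effects `beta`, the
#' random-effects covariance `D` (symmetric positive definite), and the
#' residual variance `sigma2`.
#'
#' @param beta numeric fixed-effect vector (marker units).
#' @param D q x q symmetric positive-definite covariance matrix.
#' @param sigma2 residual variance, > 0.
#' @return an object of class `lmmParams`.
#' @export
lmmParams <- function(beta, D, sigma2) {
  beta <- as.numeric(beta)
  D <- as.matrix(D)
  if (!isSymmetric(unname(D), tol = 1e-8))
    stop("random-effects covariance D must be symmetric")
  ev <- eigen(D, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-10 * max(abs(ev)))
    stop("random-effects covariance D must be positive definite ",
         "(smallest eigenvalue ", signif(min(ev), 3), ")")
  if (min(ev) <= 0) {
    # repair pure-roundoff indefiniteness from the matrix-exponential map
    D <- D + diag(2 * abs(min(ev)) + 1e-12, nrow(D))
  }
  if (!is.numeric(sigma2) || length(sigma2) != 1L || sigma2 <= 0)
    stop("residual variance sigma2 must be a positive scalar")
  structure(list(beta = beta, D = (D + t(D)) / 2, sigma2 = sigma2,
                 q = nrow(D)),
            class = "lmmParams")
}

#' @export
print.lmmParams <- function(x, ...) {
  cat("LMM parameters: p =", length(x$beta), ", q =", x$q, "\n")
  cat("  beta  :", paste(signif(x$beta, 5), collapse = ", "), "\n")
  cat("  sigma2:", signif(x$sigma2, 5), "\n")
  cat("  D     :\n")
  print(signif(x$D, 4))
  invisible(x)
}

checkMarkerDims <- function(y, X, Z, params) {
  n <- length(y)
  if (n < 1L) stop("marker vector must have length >= 1")
  if (nrow(X) != n || nrow(Z) != n)
    stop("design matrices must have one row per marker measurement")
  if (ncol(X) != length(params$beta))
    stop("fixed design has ", ncol(X), " columns but beta has length ",
         length(params$beta))
  if (ncol(Z) != params$q)
    stop("random design has ", ncol(Z), " columns but D is ",
         params$q, " x ", params$q)
  invisible(TRUE)
}

#' Marginal log-likelihood of one subject's marker vector
#'
#' Evaluates `log N(y; X beta, sigma2 I + Z D Z')` through a Cholesky
#' factorization of the n_i x n_i marginal covariance (no explicit
#' inversion).
#'
#' @param y numeric marker vector of length n_i.
#' @param X,Z fixed and random design matrices (n_i rows).
#' @param params an [lmmParams()] object.
#' @return the log-density (scalar).
#' @export
markerMarginalLoglik <- function(y, X, Z, params) {
  checkMarkerDims(y, X, Z, params)
  n <- length(y)
  V <- params$sigma2 * diag(n) + Z %*% params$D %*% t(Z)
  R <- tryCatch(chol(V), error = function(e)
    stop("marginal marker covariance is not positive definite: ",
         conditionMessage(e)))
  r <- y - drop(X %*% params$beta)
  z <- backsolve(R, r, transpose = TRUE)
  -0.5 * n * log(2 * pi) - sum(log(diag(R))) - 0.5 * sum(z^2)
}

#' Posterior of the random effects given the marker only
#'
#' Conjugate update `C^{-1} = D^{-1} + Z'Z / sigma2`,
#' `mu = C Z'(y - X beta) / sigma2`.  The returned factor `B` is the upper
#' Cholesky factor of `C^{-1}` (so `B'B = C^{-1}`); this is the importance
#' density used by the pseudo-adaptive quadrature.
#'
#' @inheritParams markerMarginalLoglik
#' @return an object of class `posteriorRE` with fields `mu`, `C`, `B`.
#' @export
posteriorRE <- function(y, X, Z, params) {
  checkMarkerDims(y, X, Z, params)
  Dinv <- tryCatch(chol2inv(chol(params$D)), error = function(e)
    stop("random-effects covariance D is singular: ", conditionMessage(e)))
  Cinv <- Dinv + crossprod(Z) / params$sigma2
  B <- chol(Cinv)
  C <- chol2inv(B)
  mu <- drop(C %*% crossprod(Z, y - drop(X %*% params$beta))) / params$sigma2
  structure(list(mu = mu, C = C, B = B), class = "posteriorRE")
}

#' @export
print.posteriorRE <- function(x, ...) {
  cat("Posterior of random effects given marker (q =", length(x$mu), ")\n")
  cat("  mu:", paste(signif(x$mu, 5), collapse = ", "), "\n")
  invisible(x)
}

#' Latent marker value and slope
#'
#' Computes `m(t) = X(t)'beta + Z(t)'b` and its time derivative for given
#' random effects `b`.  Slopes use analytic basis derivatives when available,
#' otherwise central differences.
#'
#' @param b random-effects vector.
#' @param basis a [markerBasis()].
#' @param beta fixed-effect vector.
#' @param t numeric vector of times.
#' @return a list with numeric vectors `value` and `slope`.
#' @export
trueValueSlope <- function(b, basis, beta, t) {
  X <- evalBasis(basis, t, "fixed")
  Z <- evalBasis(basis, t, "random")
  Xd <- evalBasisDeriv(basis, t, "fixed")
  Zd <- evalBasisDeriv(basis, t, "random")
  list(value = drop(X %*% beta) + drop(Z %*% b),
       slope = drop(Xd %*% beta) + drop(Zd %*% b))
}

#' Population-averaged marker value
#'
#' `X(t)'beta`, the mean trajectory implied by the fixed effects alone.
#'
#' @inheritParams trueValueSlope
#' @return numeric vector of mean marker values at `t`.
#' @export
meanMarker <- function(basis, beta, t) {
  drop(evalBasis(basis, t, "fixed") %*% beta)
}
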