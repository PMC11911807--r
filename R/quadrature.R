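# 15-point Gauss-Kronrod abscissae and weights on [-1, 1] (symmetric).
.gk15 <- local({
  x <- c(0.991455371120813, 0.949107912342759, 0.864864423359769,
         0.741531185599394, 0.586087235467691, 0.405845151377397,
         0.207784955007898, 0)
  w <- c(0.022935322010529, 0.063092092629979, 0.104790010322250,
         0.140653259715525, 0.169004726639267, 0.190350578064785,
         0.204432940075298, 0.209482141084728)
  list(nodes = c(-x[1:7], 0, rev(x[1:7])),
       weights = c(w[1:7], w[8], rev(w[1:7])))
})

#' Fixed 15-point Gauss-Kronrod integration
#'
#' One-panel 15-node Gauss-Kronrod estimate of `int_a^b f`, the rule used
#' for every inter-visit hazard integral (no adaptivity: the integrands are
#' smooth within each piece).
#'
#' @param f vectorized integrand.
#' @param a,b integration limits, `a <= b`.
#' @return the integral estimate (scalar).
#' @export
gaussKronrod15 <- function(f, a, b) {
  if (!is.numeric(a) || !is.numeric(b) || a > b)
    stop("need numeric limits with a <= b")
  if (a == b) return(0)
  half <- (b - a) / 2
  mid <- (a + b) / 2
  sum(.gk15$weights * f(mid + half * .gk15$nodes)) * half
}

# Nodes/weights of the 15-point rule mapped to [a, b]
gk15Points <- function(a, b) {
  half <- (b - a) / 2
  list(x = (a + b) / 2 + half * .gk15$nodes, w = .gk15$weights * half)
}

# Gauss-Hermite nodes/weights (physicists' weight exp(-x^2)) via
# Golub-Welsch on the Jacobi matrix of the Hermite recurrence.
gaussHermite <- function(n) {
  stopifnot(n >= 1)
  if (n == 1L) return(list(x = 0, w = sqrt(pi)))
  i <- seq_len(n - 1)
  J <- matrix(0, n, n)
  off <- sqrt(i / 2)
  J[cbind(i, i + 1)] <- off
  J[cbind(i + 1, i)] <- off
  e <- eigen(J, symmetric = TRUE)
  list(x = rev(e$values), w = rev(sqrt(pi) * e$vectors[1, ]^2))
}

#' Quadrature rule for random-effects marginalization
#'
#' Either a tensor-product Gauss-Hermite grid (`kind = "GH"`) pruned to
#' nodes whose normalized product weight exceeds `prune`, or Monte Carlo
#' draws (`kind = "MC"`) from a Latin-hypercube design mapped through the
#' standard-normal quantile function, held fixed across likelihood
#' evaluations.
#'
#' @param q dimension of the random effects.
#' @param kind `"GH"` or `"MC"`.
#' @param nodes Gauss-Hermite nodes per dimension (GH).
#' @param draws number of Monte Carlo draws (MC).
#' @param seed integer seed fixing the Monte Carlo design.
#' @param prune discard GH tensor nodes with normalized product weight below
#'   this threshold.
#' @return an object of class `quadratureRule` with the standardized node
#'   matrix `A` (M x q) and log-weights `logw` (including the `pi^{-q/2}`
#'   normalization for GH, `-log M` for MC).
#' @export
quadratureRule <- function(q, kind = c("GH", "MC"), nodes = 7L, draws = 500L,
                           seed = 1L, prune = 1e-10) {
  kind <- match.arg(kind)
  if (kind == "GH") {
    gh <- gaussHermite(nodes)
    grids <- rep(list(seq_len(nodes)), q)
    idx <- as.matrix(expand.grid(grids))
    A <- matrix(gh$x[idx], ncol = q)
    logw <- rowSums(matrix(log(gh$w[idx]), ncol = q)) - q / 2 * log(pi)
    keep <- logw > log(prune)
    A <- A[keep, , drop = FALSE]
    logw <- logw[keep]
    # renormalize so pruned weights still sum to one against the Gaussian
    logw <- logw - logSumExp(logw)
  } else {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    set.seed(seed)
    U <- lhs::randomLHS(draws, q)
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    A <- stats::qnorm(U) / sqrt(2)  # so that mu + sqrt(2) B^{-1} A' ~ N(mu, C)
    logw <- rep(-log(draws), draws)
  }
  structure(list(kind = kind, q = q, A = A, logw = logw,
                 nodes = if (kind == "GH") nodes else NA_integer_,
                 draws = if (kind == "MC") draws else NA_integer_,
                 seed = seed),
            class = "quadratureRule")
}

#' @export
print.quadratureRule <- function(x, ...) {
  cat("Quadrature rule:", x$kind, "with", nrow(x$A), "points in dimension",
      x$q, "\n")
  invisible(x)
}

logSumExp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Marginalize a conditional log-likelihood over the random effects
#'
#' Integrates `exp(condLoglik(b))` against the marker-only posterior
#' `N(mu, C)` used as importance density: nodes are
#' `b = mu + sqrt(2) B^{-1} A'` for Gauss-Hermite (with `B'B = C^{-1}`) and
#' Latin-hypercube normal draws for Monte Carlo.  Everything is computed in
#' log space with a max shift.  Also returns the normalized per-node
#' posterior weights `f(.|Y, b) / f(.|Y)` reused by the score.
#'
#' @param condLoglik function taking a q x M matrix of random-effects
#'   columns and returning M conditional log-likelihood values.
#' @param post a [posteriorRE()] object.
#' @param rule a [quadratureRule()] object.
#' @return list with `logMarginal`, `weights` (nonnegative, summing to 1),
#'   node matrix `b` (q x M), and for MC rules `se`, the delta-method
#'   standard error of `logMarginal`.
#' @export
marginalizeRE <- function(condLoglik, post, rule) {
  q <- length(post$mu)
  if (rule$q != q) stop("rule dimension does not match the posterior")
  if (rule$kind == "GH") {
    # post$B may be any factor with B'B = C^{-1}, not necessarily
    # triangular, so use a general solve
    Binv <- solve(post$B)
    b <- post$mu + sqrt(2) * Binv %*% t(rule$A)
  } else {
    Ct <- chol(post$C)
    b <- post$mu + t(Ct) %*% t(sqrt(2) * rule$A)
  }
  ll <- condLoglik(b)
  if (length(ll) != nrow(rule$A))
    stop("condLoglik must return one value per node")
  lw <- rule$logw + ll
  logI <- logSumExp(lw)
  if (!is.finite(logI)) {
    out <- list(logMarginal = -Inf, weights = rep(NA_real_, length(ll)),
                b = b, se = NA_real_)
    attr(out, "diagnostic") <- "all quadrature nodes underflowed"
    return(out)
  }
  w <- exp(lw - logI)
  se <- NA_real_
  if (rule$kind == "MC") {
    v <- exp(ll - max(ll))
    se <- stats::sd(v) / (mean(v) * sqrt(length(v)))
  }
  list(logMarginal = logI, weights = w, b = b, se = se)
}
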