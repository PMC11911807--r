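# Model frame: everything about (data, config) that does not depend on the
# parameters, precomputed once per fit -- design matrices at visit times,
# spline/feature/derivative rows at the event times and at the 15
# Gauss-Kronrod nodes of every inter-visit piece.  The likelihood and score
# then reduce to dense matrix algebra over the quadrature nodes of the
# random effects.

resolveVisitBasis <- function(data, cfg) {
  v <- cfg$visiting
  if (!is.null(v$boundary))
    return(splineBasisHazard(interior = v$knots, boundary = v$boundary))
  m <- as.integer(v$knots)
  if (v$scale == "gap") {
    gaps <- unlist(lapply(data$records, function(r)
      if (r$n > 1) diff(r$times) else numeric()))
    if (!length(gaps)) gaps <- vapply(data$records, function(r) r$Tobs,
                                      numeric(1))
    hi <- max(c(gaps, vapply(data$records, function(r)
      r$Tobs - r$times[r$n], numeric(1))))
    src <- gaps
  } else {
    src <- unlist(lapply(data$records, function(r) r$times[-1]))
    ev <- vapply(data$records, function(r) r$Tobs, numeric(1))
    if (!length(src)) src <- ev
    hi <- max(ev)
  }
  interior <- if (m > 0)
    unique(stats::quantile(src, probs = seq_len(m) / (m + 1), names = FALSE))
  else numeric()
  interior <- interior[interior > 0 & interior < hi]
  splineBasisHazard(interior = interior, boundary = c(0, hi))
}

resolveCauseBasis <- function(data, ck, k) {
  if (!is.null(ck$boundary))
    return(splineBasisHazard(interior = ck$knots, boundary = ck$boundary))
  m <- as.integer(ck$knots)
  Tall <- vapply(data$records, function(r) r$Tobs, numeric(1))
  evs <- Tall[vapply(data$records, function(r) r$cause, integer(1)) == k]
  src <- if (length(evs) > max(3, m)) evs else Tall
  hi <- max(Tall)
  interior <- if (m > 0)
    unique(stats::quantile(src, probs = seq_len(m) / (m + 1), names = FALSE))
  else numeric()
  interior <- interior[interior > 0 & interior < hi]
  splineBasisHazard(interior = interior, boundary = c(0, hi))
}

# feature row "before any visit" used when the first visit time itself is
# modeled as a gap from the time origin
preVisitFeatureRow <- function(record, features, center) {
  vapply(features, function(nm) switch(nm,
    last_y = stop("feature 'last_y' is unavailable before the first visit; ",
                  "drop it or disable firstGapFromZero"),
    t_ij = 0, prev_gap = 0, visit_count = 0, mean_gap = center,
    {
      v <- record$covariates[[nm]]
      if (is.null(v)) stop("unknown feature or covariate '", nm, "'")
      as.numeric(v)
    }), numeric(1))
}

prepVisitSub <- function(record, cfg, sb, mbasis, covNames) {
  v <- cfg$visiting
  center <- v$prevGapCenter
  nf <- length(v$features)
  n <- record$n
  covZero <- function(t) matrix(0, length(t), length(covNames))
  Fm <- if (nf) historyFeatures(record, v$features, center)
        else matrix(0, n, 0)
  if (v$scale == "gap") {
    origins <- record$times
    lens <- c(diff(record$times), record$Tobs - record$times[n])
    Frows <- Fm
    if (v$firstGapFromZero && record$times[1] > 0) {
      origins <- c(0, origins)
      lens <- c(record$times[1], lens)
      Frows <- rbind(preVisitFeatureRow(record, v$features, center), Fm)
    }
    nG <- length(lens)
    evIdx <- seq_len(nG - 1L)           # all but the final censored gap
    d <- length(evIdx)
    evB <- evF <- evXd <- evZd <- NULL
    if (d) {
      evU <- lens[evIdx]
      evT <- origins[evIdx] + evU       # calendar time of each visit event
      evB <- evalSpline(sb, evU)
      evF <- Frows[evIdx, , drop = FALSE]
      evXd <- cbind(evalBasisDeriv(mbasis, evT, "fixed"), covZero(evT))
      evZd <- evalBasisDeriv(mbasis, evT, "random")
    }
    keep <- which(lens > 0)
    qB <- qF <- qXd <- qZd <- NULL; qw <- numeric(0)
    if (length(keep)) {
      nodes <- lapply(keep, function(j) gk15Points(0, lens[j]))
      qu <- unlist(lapply(nodes, `[[`, "x"))       # gap-scale node times
      qw <- unlist(lapply(nodes, `[[`, "w"))
      pieceIdx <- rep(keep, each = 15L)
      qB <- evalSpline(sb, qu)
      qF <- Frows[pieceIdx, , drop = FALSE]
      slopeT <- origins[pieceIdx] + qu             # calendar time for m'(t)
      qXd <- cbind(evalBasisDeriv(mbasis, slopeT, "fixed"), covZero(slopeT))
      qZd <- evalBasisDeriv(mbasis, slopeT, "random")
    }
  } else {
    # calendar-time intensity: events at t_2..t_n, pieces between visits
    # and from the last visit to the end of follow-up
    lows <- record$times
    ups <- c(record$times[-1], record$Tobs)
    d <- n - 1L
    evB <- evF <- evXd <- evZd <- NULL
    if (d) {
      evT <- record$times[-1]
      evB <- evalSpline(sb, evT)
      evF <- Fm[seq_len(d), , drop = FALSE]
      evXd <- cbind(evalBasisDeriv(mbasis, evT, "fixed"), covZero(evT))
      evZd <- evalBasisDeriv(mbasis, evT, "random")
    }
    keep <- which(ups > lows)
    qB <- qF <- qXd <- qZd <- NULL; qw <- numeric(0)
    if (length(keep)) {
      nodes <- lapply(keep, function(j) gk15Points(lows[j], ups[j]))
      qt <- unlist(lapply(nodes, `[[`, "x"))
      qw <- unlist(lapply(nodes, `[[`, "w"))
      pieceIdx <- rep(keep, each = 15L)
      qB <- evalSpline(sb, qt)
      qF <- Fm[pieceIdx, , drop = FALSE]
      qXd <- cbind(evalBasisDeriv(mbasis, qt, "fixed"), covZero(qt))
      qZd <- evalBasisDeriv(mbasis, qt, "random")
    }
  }
  list(d = d, evB = evB, evF = evF, evXd = evXd, evZd = evZd,
       qB = qB, qF = qF, qXd = qXd, qZd = qZd, qw = qw)
}

prepCauseSub <- function(record, ck, sb, k, mbasis, covNames) {
  n <- record$n
  center <- 0.15
  nf <- length(ck$features)
  covZero <- function(t) matrix(0, length(t), length(covNames))
  Fm <- if (nf) historyFeatures(record, ck$features, center)
        else matrix(0, n, 0)
  delta <- as.integer(record$cause == k)
  evB <- evalSpline(sb, record$Tobs)
  evF <- Fm[n, , drop = FALSE]
  evXd <- cbind(evalBasisDeriv(mbasis, record$Tobs, "fixed"),
                covZero(record$Tobs))
  evZd <- evalBasisDeriv(mbasis, record$Tobs, "random")
  lows <- record$times
  ups <- c(record$times[-1], record$Tobs)
  keep <- which(ups > lows)
  qB <- qF <- qXd <- qZd <- NULL; qw <- numeric(0)
  if (length(keep)) {
    nodes <- lapply(keep, function(j) gk15Points(lows[j], ups[j]))
    qt <- unlist(lapply(nodes, `[[`, "x"))
    qw <- unlist(lapply(nodes, `[[`, "w"))
    pieceIdx <- rep(keep, each = 15L)
    qB <- evalSpline(sb, qt)
    qF <- Fm[pieceIdx, , drop = FALSE]
    qXd <- cbind(evalBasisDeriv(mbasis, qt, "fixed"), covZero(qt))
    qZd <- evalBasisDeriv(mbasis, qt, "random")
  }
  list(delta = delta, evB = evB, evF = evF, evXd = evXd, evZd = evZd,
       qB = qB, qF = qF, qXd = qXd, qZd = qZd, qw = qw)
}

#' Build a model frame
#'
#' Precomputes, per subject, the marker design matrices and the spline,
#' feature, and slope-design rows at every event time and at the 15-point
#' Gauss-Kronrod nodes of every inter-visit piece, for the visiting block
#' and each cause-specific block.  Also resolves data-driven spline knots
#' and the parameter skeleton.
#'
#' @param data a [jointData()] object.
#' @param config a configuration list (normalized via [validateConfig()]).
#' @return an object of class `vjmFrame`.
#' @export
modelFrame <- function(data, config) {
  cfg <- validateConfig(config)
  mbasis <- cfg$marker$basis
  covNames <- cfg$marker$covariates
  frame <- list(config = cfg, data = data,
                p = mbasis$p + length(covNames), q = mbasis$q,
                betaNames = c(names(mbasis$fixed), covNames),
                n = length(data$records))
  frame$visitBasis <- if (cfg$visiting$scale != "none")
    resolveVisitBasis(data, cfg) else NULL
  frame$causeBases <- lapply(seq_along(cfg$causes), function(k)
    resolveCauseBasis(data, cfg$causes[[k]], k))
  K <- length(cfg$causes)
  frame$subs <- lapply(data$records, function(r) {
    if (r$cause > K)
      stop("subject ", r$id, ": cause code ", r$cause,
           " but the model declares ", K, " causes")
    covRow <- if (length(covNames))
      vapply(covNames, function(nm) {
        v <- r$covariates[[nm]]
        if (is.null(v)) stop("subject ", r$id, ": missing covariate ", nm)
        as.numeric(v)
      }, numeric(1)) else numeric()
    X <- cbind(evalBasis(mbasis, r$times, "fixed"),
               matrix(rep(covRow, each = r$n), nrow = r$n))
    Z <- evalBasis(mbasis, r$times, "random")
    X0 <- c(evalBasis(mbasis, 0, "fixed")[1, ], covRow)
    Z0 <- evalBasis(mbasis, 0, "random")[1, ]
    sub <- list(id = r$id, n = r$n, y = r$y, X = X, Z = Z, X0 = X0,
                Z0 = Z0, XtX = crossprod(X), ZtZ = crossprod(Z))
    sub$v <- if (cfg$visiting$scale != "none")
      prepVisitSub(r, cfg, frame$visitBasis, mbasis, covNames) else NULL
    sub$causes <- lapply(seq_len(K), function(k)
      prepCauseSub(r, cfg$causes[[k]], frame$causeBases[[k]], k, mbasis,
                   covNames))
    p <- mbasis$p + length(covNames)
    cb <- list()
    if (!is.null(sub$v))
      cb <- c(cb, list(mkCblock(sub$v, TRUE, sub$v$d,
                                frame$visitBasis$ncoef,
                                length(cfg$visiting$features), p,
                                mbasis$q)))
    for (k in seq_len(K))
      cb <- c(cb, list(mkCblock(sub$causes[[k]], FALSE,
                                sub$causes[[k]]$delta,
                                frame$causeBases[[k]]$ncoef,
                                length(cfg$causes[[k]]$features), p,
                                mbasis$q)))
    sub$cblocks <- cb
    sub
  })
  frame$skeleton <- paramSkeleton(frame)
  class(frame) <- "vjmFrame"
  frame
}

#' @export
print.vjmFrame <- function(x, ...) {
  cat("Joint model frame:", x$n, "subjects,", x$skeleton$npar,
      "parameters\n")
  cat("  visiting scale:", x$config$visiting$scale,
      if (x$config$visiting$frailty) "(gamma frailty)" else "", "\n")
  cat("  causes:", length(x$config$causes), "\n")
  invisible(x)
}
# -- fast likelihood / score ------------------------------------------------

emptyMat <- function(ncol) matrix(0, 0L, ncol)

# constant kernel inputs for one hazard block (shared with the design
# matrices already stored on the subject; no copies)
mkCblock <- function(blk, isVisit, dcount, npsi, nf, p, q) {
  list(qZd = blk$qZd %||% emptyMat(q), qw = blk$qw %||% numeric(),
       evZd = blk$evZd %||% emptyMat(q),
       qB = blk$qB %||% emptyMat(npsi), qF = blk$qF %||% emptyMat(nf),
       qXd = blk$qXd %||% emptyMat(p),
       evB = blk$evB %||% emptyMat(npsi), evF = blk$evF %||% emptyMat(nf),
       evXd = blk$evXd %||% emptyMat(p),
       dcount = as.integer(dcount), isVisit = isVisit,
       npsi = as.integer(npsi), nf = as.integer(nf), np = as.integer(p),
       evBsum = if (!is.null(blk$evB) && nrow(blk$evB)) colSums(blk$evB)
                else numeric(npsi),
       evFsum = if (!is.null(blk$evF) && nrow(blk$evF)) colSums(blk$evF)
                else numeric(nf),
       evXdsum = if (!is.null(blk$evXd) && nrow(blk$evXd))
                   colSums(blk$evXd) else numeric(p),
       nev = if (is.null(blk$evB)) 0L else nrow(blk$evB))
}

# per-block parameter lists, ordered visiting-first then causes
blockPars <- function(th, hasVisit) {
  out <- list()
  if (hasVisit) out <- c(out, list(visitPars(th$visiting)))
  for (k in seq_along(th$causes))
    out <- c(out, list(visitPars(th$causes[[k]])))
  lapply(out, function(p) list(psi = as.numeric(p$psi),
                               coef = as.numeric(p$coef),
                               a1 = p$alpha1, a2 = p$alpha2))
}

visitPars <- function(v) list(psi = v$psi, coef = v$coef,
                              alpha1 = v$alpha1, alpha2 = v$alpha2)

# Marker marginal log-density and random-effects posterior through the
# q x q Woodbury identities; Dinv and logdetD are shared across subjects
# within one likelihood evaluation.
markerStats <- function(sub, beta, Dinv, logdetD, sigma2) {
  r0 <- sub$y - drop(sub$X %*% beta)
  Zr <- drop(crossprod(sub$Z, r0))
  Cinv <- Dinv + sub$ZtZ / sigma2
  U <- chol(Cinv)
  w1 <- backsolve(U, Zr, transpose = TRUE)
  quad <- (sum(r0^2) - sum(w1^2) / sigma2) / sigma2
  llY <- -0.5 * (sub$n * log(2 * pi * sigma2) + logdetD +
                 2 * sum(log(diag(U))) + quad)
  mu <- backsolve(U, w1) / sigma2
  list(llY = llY, mu = mu, U = U, r0 = r0)
}

frameEta <- function(th) if (!is.null(th$visiting)) th$visiting$eta else 0

#' Joint marginal log-likelihood
#'
#' The factorized marginal likelihood: per subject, the closed-form
#' marginal marker log-density plus the log of the visiting and
#' competing-risks conditional likelihood integrated over the random
#' effects with the marker-only posterior as importance density.
#'
#' @param par packed parameter vector (see [packParams()]).
#' @param frame a [modelFrame()] object.
#' @param rule optional [quadratureRule()]; defaults to the frame's
#'   configured rule.
#' @param anchor optional frozen importance density built with
#'   [frameAnchor()]; when supplied, the random-effects nodes are fixed at
#'   the anchor's marker-only posterior (classic pseudo-adaptive scheme)
#'   and the analytic score is the exact gradient of this objective.  The
#'   default recomputes the posterior from the current parameters at every
#'   evaluation.
#' @return scalar log-likelihood, with attribute `"subject"` holding the
#'   per-subject contributions.
#' @export
jointLoglik <- function(par, frame, rule = NULL, anchor = NULL) {
  th <- unpackParams(par, frame$skeleton, frame)
  rule <- rule %||% frameRule(frame)
  Rd <- chol(th$lmm$D)
  Dinv <- chol2inv(Rd)
  logdetD <- 2 * sum(log(diag(Rd)))
  tA <- sqrt(2) * t(rule$A)
  persub <- .datasetLLCpp(frame$subs, th$lmm$beta, Dinv, logdetD,
                          th$lmm$sigma2,
                          blockPars(th, !is.null(frame$skeleton$idx$v)),
                          frameEta(th), rule$logw, tA, anchor)
  structure(sum(persub), subject = persub)
}

#' Frozen importance density for the random-effects integral
#'
#' Evaluates, per subject, the marker-only posterior of the random effects
#' at the supplied marker parameters and freezes the corresponding
#' Gauss-Hermite node matrix and log importance density.  Passing the
#' result to [jointLoglik()]/[jointScore()] makes them a fixed-node
#' importance-sampling approximation whose analytic score is exact.
#'
#' @param frame a [modelFrame()] object.
#' @param lmm an [lmmParams()] object (the anchor marker parameters).
#' @param rule a [quadratureRule()] object.
#' @return a list with one element per subject (`B`: q x M node matrix,
#'   `logg`: log importance density at the nodes).
#' @export
frameAnchor <- function(frame, lmm, rule) {
  Rd <- chol(lmm$D)
  Dinv <- chol2inv(Rd)
  logdetD <- 2 * sum(log(diag(Rd)))
  tA <- sqrt(2) * t(rule$A)
  a2 <- rowSums(rule$A^2)
  q <- frame$q
  lapply(frame$subs, function(sub) {
    ms <- markerStats(sub, lmm$beta, Dinv, logdetD, lmm$sigma2)
    B <- ms$mu + backsolve(ms$U, tA)
    list(B = B,
         logg = -q / 2 * log(2 * pi) + sum(log(diag(ms$U))) - a2)
  })
}

frameRule <- function(frame) {
  qc <- frame$config$quadrature
  quadratureRule(frame$q, kind = qc$kind, nodes = qc$nodes,
                 draws = qc$draws, seed = qc$seed, prune = qc$prune)
}

#' Analytic score of the joint marginal log-likelihood
#'
#' The complete-data score averaged over the quadrature nodes with the
#' normalized posterior node weights (the ratio of the conditional to the
#' marginal density at each node), with exact chain rules through the
#' matrix-log parameterization of `D` and the log transforms of `sigma2`
#' and `eta`.
#'
#' @inheritParams jointLoglik
#' @return named gradient vector on the packed scale.
#' @export
jointScore <- function(par, frame, rule = NULL, anchor = NULL) {
  th <- unpackParams(par, frame$skeleton, frame)
  rule <- rule %||% frameRule(frame)
  sk <- frame$skeleton
  idx <- sk$idx
  Rd <- chol(th$lmm$D)
  Dinv <- chol2inv(Rd)
  logdetD <- 2 * sum(log(diag(Rd)))
  tA <- sqrt(2) * t(rule$A)
  sc <- .datasetScoreCpp(frame$subs, th$lmm$beta, Dinv, logdetD,
                         th$lmm$sigma2,
                         blockPars(th, !is.null(idx$v)),
                         frameEta(th), rule$logw, tA, anchor)
  g <- numeric(sk$npar)
  g[idx$beta] <- drop(sc$gBeta)
  g[idx$sigma2] <- sc$gLogSig
  b <- 1L
  fill <- function(ix, b) {
    if (length(ix$psi)) g[ix$psi] <<- drop(sc$gPsi[[b]])
    if (length(ix$coef)) g[ix$coef] <<- drop(sc$gCoef[[b]])
    if (length(ix$alpha1)) g[ix$alpha1] <<- sc$gA1[b]
    if (length(ix$alpha2)) g[ix$alpha2] <<- sc$gA2[b]
  }
  if (!is.null(idx$v)) {
    fill(idx$v, b)
    if (length(idx$v$eta)) g[idx$v$eta] <- sc$gEta
    b <- b + 1L
  }
  for (k in seq_along(idx$causes)) {
    fill(idx$causes[[k]], b)
    b <- b + 1L
  }
  GD <- sc$GD
  g[idx$D] <- chainRuleLogm(GD, logmSym(th$lmm$D))
g[idx$D] <- chainRuleLogm(GD, logmSym(th$lmm$D))
  names(g) <- sk$names
  g
}
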