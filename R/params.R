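# Symmetric matrix log / exp via eigendecomposition, and the Frechet
# derivative machinery used to push log-likelihood gradients in D through
# the matrix-log parameterization.

logmSym <- function(D) {
  e <- eigen((D + t(D)) / 2, symmetric = TRUE)
  if (min(e$values) <= 0) stop("matrix is not positive definite")
  L <- e$vectors %*% (log(e$values) * t(e$vectors))
  (L + t(L)) / 2
}

expmSym <- function(L) {
  e <- eigen((L + t(L)) / 2, symmetric = TRUE)
  D <- e$vectors %*% (exp(e$values) * t(e$vectors))
  (D + t(D)) / 2
}

vechIdx <- function(q) which(lower.tri(diag(q), diag = TRUE))

vech <- function(M) M[vechIdx(nrow(M))]

unvech <- function(v, q) {
  M <- matrix(0, q, q)
  M[lower.tri(M, diag = TRUE)] <- v
  M + t(M) - diag(diag(M), q)
}

# Map a full-matrix gradient G = d loglik / dD (symmetric, trace
# convention) to the gradient with respect to vech(L), D = expm(L).
chainRuleLogm <- function(G, L) {
  e <- eigen((L + t(L)) / 2, symmetric = TRUE)
  lam <- e$values
  Q <- e$vectors
  num <- outer(exp(lam), exp(lam), "-")
  den <- outer(lam, lam, "-")
  V <- ifelse(abs(den) < 1e-12, exp(outer(lam, lam, function(a, b) (a + b) / 2)),
              num / den)
  Ghat <- Q %*% (V * crossprod(Q, G %*% Q)) %*% t(Q)
  Ghat <- (Ghat + t(Ghat)) / 2
  q <- nrow(L)
  scale <- matrix(2, q, q); diag(scale) <- 1
  (Ghat * scale)[vechIdx(q)]
}

# Parameter skeleton: block sizes, packed names, and index map, derived
# from a model frame.
paramSkeleton <- function(frame) {
  cfg <- frame$config
  p <- frame$p; q <- frame$q
  nms <- c(paste0("beta.", frame$betaNames),
           paste0("D.logm.", apply(which(lower.tri(diag(q), diag = TRUE),
                                         arr.ind = TRUE), 1,
                                   paste, collapse = ".")),
           "sigma2.log")
  idx <- list(beta = seq_len(p),
              D = p + seq_len(q * (q + 1) / 2),
              sigma2 = p + q * (q + 1) / 2 + 1L)
  pos <- idx$sigma2
  if (cfg$visiting$scale != "none") {
    npsi <- frame$visitBasis$ncoef
    nf <- length(cfg$visiting$features)
    vn <- c(paste0("v.psi", seq_len(npsi)),
            if (nf) paste0("v.", cfg$visiting$features),
            if (cfg$visiting$assocM0) "v.alpha.m0",
            if (cfg$visiting$assocSlope) "v.alpha.slope",
            if (cfg$visiting$frailty) "v.eta.log")
    idx$v <- list(psi = pos + seq_len(npsi),
                  coef = if (nf) pos + npsi + seq_len(nf) else integer(),
                  alpha1 = if (cfg$visiting$assocM0)
                    pos + npsi + nf + 1L else integer(),
                  alpha2 = if (cfg$visiting$assocSlope)
                    pos + npsi + nf + cfg$visiting$assocM0 + 1L
                  else integer(),
                  eta = if (cfg$visiting$frailty)
                    pos + npsi + nf + cfg$visiting$assocM0 +
                      cfg$visiting$assocSlope + 1L else integer())
    nms <- c(nms, vn)
    pos <- pos + length(vn)
  }
  idx$causes <- list()
  for (k in seq_along(cfg$causes)) {
    ck <- cfg$causes[[k]]
    npsi <- frame$causeBases[[k]]$ncoef
    nf <- length(ck$features)
    cn <- c(paste0("s", k, ".psi", seq_len(npsi)),
            if (nf) paste0("s", k, ".", ck$features),
            if (ck$assocM0) paste0("s", k, ".alpha.m0"),
            if (ck$assocSlope) paste0("s", k, ".alpha.slope"))
    idx$causes[[k]] <- list(psi = pos + seq_len(npsi),
                            coef = if (nf) pos + npsi + seq_len(nf)
                            else integer(),
                            alpha1 = if (ck$assocM0)
                              pos + npsi + nf + 1L else integer(),
                            alpha2 = if (ck$assocSlope)
                              pos + npsi + nf + ck$assocM0 + 1L
                            else integer())
    nms <- c(nms, cn)
    pos <- pos + length(cn)
  }
  list(names = nms, idx = idx, npar = pos, p = p, q = q)
}

#' Pack joint parameters into an unconstrained vector
#'
#' `D` enters through the half-vectorization of its matrix logarithm,
#' `sigma2` and the frailty variance `eta` through natural logs; everything
#' else is packed identically.  The inverse map [unpackParams()] is exact.
#'
#' @param theta a `jointParams` list with elements `lmm` ([lmmParams()]),
#'   optionally `visiting` ([visitParams()]), and `causes` (list of
#'   [causeParams()]).
#' @param skeleton a parameter skeleton as stored in a model frame
#'   (`frame$skeleton`).
#' @return named numeric vector of length `skeleton$npar`.
#' @export
packParams <- function(theta, skeleton) {
  out <- numeric(skeleton$npar)
  idx <- skeleton$idx
  out[idx$beta] <- theta$lmm$beta
  out[idx$D] <- vech(logmSym(theta$lmm$D))
  out[idx$sigma2] <- log(theta$lmm$sigma2)
  if (!is.null(idx$v)) {
    v <- theta$visiting
    out[idx$v$psi] <- v$psi
    if (length(idx$v$coef)) out[idx$v$coef] <- v$coef
    if (length(idx$v$alpha1)) out[idx$v$alpha1] <- v$alpha1
    if (length(idx$v$alpha2)) out[idx$v$alpha2] <- v$alpha2
    if (length(idx$v$eta)) out[idx$v$eta] <- log(v$eta)
  }
  for (k in seq_along(idx$causes)) {
    ik <- idx$causes[[k]]
    ck <- theta$causes[[k]]
    out[ik$psi] <- ck$psi
    if (length(ik$coef)) out[ik$coef] <- ck$coef
    if (length(ik$alpha1)) out[ik$alpha1] <- ck$alpha1
    if (length(ik$alpha2)) out[ik$alpha2] <- ck$alpha2
  }
  if (any(!is.finite(out))) stop("packed parameter vector is not finite")
  names(out) <- skeleton$names
  out
}

#' Unpack a parameter vector
#'
#' @param par named numeric vector as produced by [packParams()].
#' @param skeleton the matching parameter skeleton.
#' @param frame optional model frame supplying feature/coefficient names.
#' @return a `jointParams` list.
#' @export
unpackParams <- function(par, skeleton, frame = NULL) {
  idx <- skeleton$idx
  q <- skeleton$q
  lmm <- lmmParams(unname(par[idx$beta]),
                   expmSym(unvech(unname(par[idx$D]), q)),
                   exp(unname(par[idx$sigma2])))
  visiting <- NULL
  if (!is.null(idx$v)) {
    cf <- if (length(idx$v$coef)) par[idx$v$coef] else numeric()
    if (length(cf) && !is.null(frame))
      names(cf) <- frame$config$visiting$features
    else if (length(cf))
      names(cf) <- sub("^v\\.", "", names(cf))
    visiting <- visitParams(
      psi = unname(par[idx$v$psi]), coef = cf,
      alpha1 = if (length(idx$v$alpha1)) unname(par[idx$v$alpha1]) else 0,
      alpha2 = if (length(idx$v$alpha2)) unname(par[idx$v$alpha2]) else 0,
      eta = if (length(idx$v$eta)) exp(unname(par[idx$v$eta])) else 0)
  }
  causes <- lapply(seq_along(idx$causes), function(k) {
    ik <- idx$causes[[k]]
    cf <- if (length(ik$coef)) par[ik$coef] else numeric()
    if (length(cf) && !is.null(frame))
      names(cf) <- frame$config$causes[[k]]$features
    else if (length(cf))
      names(cf) <- sub(paste0("^s", k, "\\."), "", names(cf))
    causeParams(
      psi = unname(par[ik$psi]), coef = cf,
      alpha1 = if (length(ik$alpha1)) unname(par[ik$alpha1]) else 0,
      alpha2 = if (length(ik$alpha2)) unname(par[ik$alpha2]) else 0)
  })
  list(lmm = lmm, visiting = visiting, causes = causes)
}
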