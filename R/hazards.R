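#' Visiting-process parameters
#'
#' @param psi spline coefficients for the log baseline.
#' @param coef named coefficients of the history features (the gamma and phi
#'   blocks; names select features from [historyFeatures()]).
#' @param alpha1 association with the latent baseline value `m_i(0)`.
#' @param alpha2 association with the latent slope `m_i'(t)`.
#' @param eta gamma-frailty variance, `>= 0` (0 means no frailty).
#' @return an object of class `visitParams`.
#' @export
visitParams <- function(psi, coef = numeric(), alpha1 = 0, alpha2 = 0,
                        eta = 0) {
  if (length(coef) && is.null(names(coef)))
    stop("feature coefficients must be named")
  if (eta < 0) stop("frailty variance eta must be >= 0")
  structure(list(psi = as.numeric(psi), coef = coef,
                 alpha1 = alpha1, alpha2 = alpha2, eta = eta),
            class = "visitParams")
}

#' Cause-specific hazard parameters (one cause)
#'
#' @inheritParams visitParams
#' @return an object of class `causeParams`.
#' @export
causeParams <- function(psi, coef = numeric(), alpha1 = 0, alpha2 = 0) {
  if (length(coef) && is.null(names(coef)))
    stop("feature coefficients must be named")
  structure(list(psi = as.numeric(psi), coef = coef,
                 alpha1 = alpha1, alpha2 = alpha2),
            class = "causeParams")
}

# Linear predictor pieces shared by all hazard components: the feature part
# (constant within a gap / inter-visit interval) and the latent associations.
featurePart <- function(record, params, center) {
  if (!length(params$coef)) return(rep(0, record$n))
  Fm <- historyFeatures(record, names(params$coef), center)
  drop(Fm %*% params$coef)
}

#' Visiting hazard on the gap-time scale
#'
#' `h_vj(u) = w * h_v0(u) exp[coef' features(t_ij) + alpha1 m(0)
#' + alpha2 m'(t_ij + u)]` where `u` is time since the most recent visit.
#'
#' @param u nonnegative gap times (vectorized).
#' @param j visit index (features are those at `t_ij`).
#' @param record a [subjectRecord()].
#' @param b random-effects vector.
#' @param sb spline basis for the log baseline.
#' @param params a [visitParams()] object.
#' @param mbasis marker [markerBasis()].
#' @param beta marker fixed effects.
#' @param center `prev_gap` centering constant.
#' @param frailty multiplicative frailty value `w` (default 1).
#' @return hazard values at `u`.
#' @export
gapHazard <- function(u, j, record, b, sb, params, mbasis, beta,
                      center = 0.15, frailty = 1) {
  if (any(u < 0)) stop("gap times must be nonnegative")
  lp0 <- featurePart(record, params, center)[j]
  tcal <- record$times[j] + u
  ms <- trueValueSlope(b, mbasis, beta, c(0, tcal))
  m0 <- ms$value[1]
  slope <- ms$slope[-1]
  frailty * exp(logBaseline(sb, params$psi, u) + lp0 +
                params$alpha1 * m0 + params$alpha2 * slope)
}

#' Visiting intensity on the calendar-time scale
#'
#' `lambda(t) = w * lambda_v0(t) exp[coef' features(t_ij) + alpha1 m(0)
#' + alpha2 m'(t)]` for `t` in `[t_ij, t_{ij+1})`.
#'
#' @param t calendar times (vectorized), all within one inter-visit
#'   interval.
#' @inheritParams gapHazard
#' @return intensity values at `t`.
#' @export
intensityHazard <- function(t, j, record, b, sb, params, mbasis, beta,
                            center = 0.15, frailty = 1) {
  lp0 <- featurePart(record, params, center)[j]
  ms <- trueValueSlope(b, mbasis, beta, c(0, t))
  frailty * exp(logBaseline(sb, params$psi, t) + lp0 +
                params$alpha1 * ms$value[1] + params$alpha2 * ms$slope[-1])
}

# event log-hazards and per-gap integrated hazards for the gap-time model;
# shared by the conditional and frailty-marginal likelihoods
gapPieces <- function(record, b, sb, params, mbasis, beta, center) {
  n <- record$n
  gaps <- c(diff(record$times), record$Tobs - record$times[n])
  if (gaps[n] < 0) stop("subject ", record$id,
                        ": follow-up ends before the last visit")
  lp0 <- featurePart(record, params, center)
  m0 <- trueValueSlope(b, mbasis, beta, 0)$value
  evLog <- numeric(0)
  if (n > 1) {
    tev <- record$times[-1]
    slev <- trueValueSlope(b, mbasis, beta, tev)$slope
    evLog <- logBaseline(sb, params$psi, gaps[-n]) + lp0[seq_len(n - 1)] +
      params$alpha1 * m0 + params$alpha2 * slev
  }
  cum <- vapply(seq_len(n), function(j) {
    if (gaps[j] <= 0) return(0)
    gaussKronrod15(function(s) {
      sl <- trueValueSlope(b, mbasis, beta, record$times[j] + s)$slope
      exp(logBaseline(sb, params$psi, s) + lp0[j] +
          params$alpha1 * m0 + params$alpha2 * sl)
    }, 0, gaps[j])
  }, numeric(1))
  list(evLog = evLog, cum = cum, d = n - 1L)
}

#' Conditional visiting log-likelihood, gap-time model
#'
#' Sum over the uncensored gaps of the log-hazard at the observed gap, minus
#' the integrated hazard over every gap including the final censored one
#' (15-point Gauss-Kronrod per gap).
#'
#' @inheritParams gapHazard
#' @return scalar log-likelihood given `b`.
#' @export
gapLoglikConditional <- function(record, b, sb, params, mbasis, beta,
                                 center = 0.15) {
  pc <- gapPieces(record, b, sb, params, mbasis, beta, center)
  sum(pc$evLog) - sum(pc$cum)
}

# event log-intensities and piecewise integrals for the calendar-time model
intensityPieces <- function(record, b, sb, params, mbasis, beta, center) {
  n <- record$n
  if (record$Tobs < record$times[n])
    stop("subject ", record$id, ": follow-up ends before the last visit")
  lp0 <- featurePart(record, params, center)
  m0 <- trueValueSlope(b, mbasis, beta, 0)$value
  evLog <- numeric(0)
  if (n > 1) {
    tev <- record$times[-1]
    slev <- trueValueSlope(b, mbasis, beta, tev)$slope
    evLog <- logBaseline(sb, params$psi, tev) + lp0[seq_len(n - 1)] +
      params$alpha1 * m0 + params$alpha2 * slev
  }
  lows <- record$times
  ups <- c(record$times[-1], record$Tobs)
  cum <- vapply(seq_len(n), function(j) {
    if (ups[j] <= lows[j]) return(0)
    gaussKronrod15(function(s) {
      sl <- trueValueSlope(b, mbasis, beta, s)$slope
      exp(logBaseline(sb, params$psi, s) + lp0[j] +
          params$alpha1 * m0 + params$alpha2 * sl)
    }, lows[j], ups[j])
  }, numeric(1))
  list(evLog = evLog, cum = cum, d = n - 1L)
}

#' Conditional visiting log-likelihood, calendar-time intensity model
#'
#' Events at the observed visit times `t_{i2}, ..., t_{i n_i}` (the baseline
#' visit is the time origin, not an event), minus the integrated intensity
#' from baseline to the end of follow-up, with features updated at each
#' visit.
#'
#' @inheritParams gapHazard
#' @return scalar log-likelihood given `b`.
#' @export
intensityLoglikConditional <- function(record, b, sb, params, mbasis, beta,
                                       center = 0.15) {
  pc <- intensityPieces(record, b, sb, params, mbasis, beta, center)
  sum(pc$evLog) - sum(pc$cum)
}

#' Gamma-frailty marginal visiting log-likelihood
#'
#' Closed-form gamma mixture of the conditional visiting likelihood: with
#' `d` uncensored gaps/visits, total integrated (frailty-free) hazard
#' `Lambda`, and `nu = 1/eta`,
#' `sum log h(events) + log Gamma(nu + d) - log Gamma(nu) + nu log nu -
#' (nu + d) log(nu + Lambda)`.
#'
#' @inheritParams gapHazard
#' @param scale `"gap"` or `"calendar"`, selecting the conditional model
#'   being marginalized.
#' @return scalar marginal log-likelihood given `b` (frailty integrated
#'   out).
#' @export
frailtyMarginalLoglik <- function(record, b, sb, params, mbasis, beta,
                                  center = 0.15,
                                  scale = c("gap", "calendar")) {
  scale <- match.arg(scale)
  if (params$eta <= 0)
    stop("frailtyMarginalLoglik requires eta > 0; use the conditional ",
         "likelihood when there is no frailty")
  pc <- if (scale == "gap")
    gapPieces(record, b, sb, params, mbasis, beta, center)
  else
    intensityPieces(record, b, sb, params, mbasis, beta, center)
  nu <- 1 / params$eta
  Lam <- sum(pc$cum)
  sum(pc$evLog) + lgamma(nu + pc$d) - lgamma(nu) + nu * log(nu) -
    (nu + pc$d) * log(nu + Lam)
}

#' Conditional competing-risks log-likelihood
#'
#' For each cause `k`: the event log-hazard at `T_i` if the subject failed
#' from cause `k`, minus the cumulative cause-specific hazard accumulated
#' piecewise over the inter-visit intervals (features frozen at the left
#' visit of each piece, latent slope varying continuously).
#'
#' @param record a [subjectRecord()]; `record$cause` must be in
#'   `0..length(causes)`.
#' @param b random-effects vector.
#' @param sbList list of spline bases, one per cause.
#' @param causes list of [causeParams()], one per cause.
#' @inheritParams gapHazard
#' @return scalar log-likelihood given `b`.
#' @export
competingLoglikConditional <- function(record, b, sbList, causes, mbasis,
                                       beta, center = 0.15) {
  K <- length(causes)
  if (record$cause > K)
    stop("subject ", record$id, ": unknown cause code ", record$cause,
         " (model has ", K, " causes)")
  n <- record$n
  m0 <- trueValueSlope(b, mbasis, beta, 0)$value
  lows <- record$times
  ups <- c(record$times[-1], record$Tobs)
  ll <- 0
  for (k in seq_len(K)) {
    pk <- causes[[k]]
    lp0 <- featurePart(record, pk, center)
    if (record$cause == k) {
      slT <- trueValueSlope(b, mbasis, beta, record$Tobs)$slope
      ll <- ll + logBaseline(sbList[[k]], pk$psi, record$Tobs) + lp0[n] +
        pk$alpha1 * m0 + pk$alpha2 * slT
    }
    for (j in seq_len(n)) {
      if (ups[j] <= lows[j]) next
      ll <- ll - gaussKronrod15(function(s) {
        sl <- trueValueSlope(b, mbasis, beta, s)$slope
        exp(logBaseline(sbList[[k]], pk$psi, s) + lp0[j] +
            pk$alpha1 * m0 + pk$alpha2 * sl)
      }, lows[j], ups[j])
    }
  }
  ll
}
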