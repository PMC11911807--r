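#' Fitted-model configuration for a scenario
#'
#' Builds the model configuration matching a simulation scenario, or one
#' of the deliberately reduced comparators used throughout the simulation
#' study:
#' \describe{
#'   \item{`correct`}{visiting scale, features, associations, and frailty
#'     matching the generating mechanism.}
#'   \item{`ignore-visits`}{the same joint model with the visiting block
#'     dropped (marker + competing risks only).}
#'   \item{`ignore-marker`}{the visiting model without the observed
#'     marker-value covariate.}
#' }
#' Spline knots are fixed (not data-driven) so that the baseline truth is
#' well defined across replications: the log-linear generating baselines
#' lie exactly in the cubic spline span via the Greville representation.
#'
#' @param scn a [simScenario()].
#' @param preset comparator name.
#' @param nodes Gauss-Hermite nodes per dimension.
#' @param visitKnots,visitBoundary interior/boundary knots of the visiting
#'   baseline spline.
#' @param causeKnots,causeBoundary interior/boundary knots of the
#'   cause-specific baseline splines.
#' @param optim optional overrides of the optimizer settings.
#' @return a configuration list for [vjmFit()].
#' @export
scenarioConfig <- function(scn,
                           preset = c("correct", "ignore-visits",
                                      "ignore-marker"),
                           nodes = 7L,
                           visitKnots = NULL, visitBoundary = NULL,
                           causeKnots = numeric(0), causeBoundary = c(0, 10),
                           optim = list()) {
  preset <- match.arg(preset)
  if (is.null(visitBoundary))
    visitBoundary <- if (scn$scale == "gap") c(0, 3) else c(0, 10)
  if (is.null(visitKnots))
    visitKnots <- if (scn$scale == "gap") c(0.3, 0.8) else c(3, 6.5)
  vfeat <- names(scn$visiting$features)
  if (preset == "ignore-marker") vfeat <- setdiff(vfeat, "last_y")
  cfg <- list(
    marker = list(basis = scenarioBasis(scn)),
    visiting = if (preset == "ignore-visits") list(scale = "none")
    else list(scale = scn$scale, features = vfeat,
              assocM0 = TRUE, assocSlope = TRUE,
              frailty = scn$visiting$eta > 0,
              knots = visitKnots, boundary = visitBoundary,
              prevGapCenter = scn$center),
    causes = lapply(scn$causes, function(ck)
      list(features = names(ck$features), assocM0 = TRUE,
           assocSlope = TRUE, knots = causeKnots,
           boundary = causeBoundary)),
    quadrature = list(nodes = nodes),
    optim = optim)
  cfg
}

#' True packed parameter vector of a scenario under a fitted configuration
#'
#' Spline-baseline truths use the Greville representation of the
#' log-linear generating baselines (exact for linear log-baselines);
#' variance components are expressed on the packed scale (matrix log of
#' `D`, log of `sigma2` and `eta`).  Parameters of a misspecified visiting
#' submodel (`ignore-marker`) have no generating-truth counterpart and are
#' returned as `NA`.
#'
#' @param scn a [simScenario()].
#' @param frame a [modelFrame()] built under the matching configuration.
#' @param misspecifiedVisiting mark visiting-block truths as `NA`.
#' @return named numeric vector aligned with `frame$skeleton$names`.
#' @export
scenarioTruth <- function(scn, frame, misspecifiedVisiting = FALSE) {
  sk <- frame$skeleton
  idx <- sk$idx
  out <- rep(NA_real_, sk$npar)
  names(out) <- sk$names
  out[idx$beta] <- scn$beta
  out[idx$D] <- vech(logmSym(scn$D))
  out[idx$sigma2] <- log(scn$sigma2)
  if (!is.null(idx$v) && !misspecifiedVisiting) {
    xi <- grevilleSites(frame$visitBasis)
    out[idx$v$psi] <- scn$visiting$base[1] + scn$visiting$base[2] * xi
    feats <- frame$config$visiting$features
    if (length(idx$v$coef))
      out[idx$v$coef] <- unname(scn$visiting$features[feats])
    if (length(idx$v$alpha1)) out[idx$v$alpha1] <- scn$visiting$alpha1
    if (length(idx$v$alpha2)) out[idx$v$alpha2] <- scn$visiting$alpha2
    if (length(idx$v$eta)) out[idx$v$eta] <- log(scn$visiting$eta)
  }
  for (k in seq_along(idx$causes)) {
    ik <- idx$causes[[k]]
    ck <- scn$causes[[k]]
    xi <- grevilleSites(frame$causeBases[[k]])
    out[ik$psi] <- ck$base[1] + ck$base[2] * xi
    feats <- frame$config$causes[[k]]$features
    if (length(ik$coef)) out[ik$coef] <- unname(ck$features[feats])
    if (length(ik$alpha1)) out[ik$alpha1] <- ck$alpha1
    if (length(ik$alpha2)) out[ik$alpha2] <- ck$alpha2
  }
  out
}

#' Aggregate replication-level estimates into study metrics
#'
#' @param est matrix of estimates (replications x parameters).
#' @param se matrix of model-based standard errors, same shape.
#' @param truth named truth vector (NA rows get no bias/coverage).
#' @return data.frame with columns `parameter`, `True`, `Est`, `Bias`,
#'   `MSE`, `ASE`, `MCSD`, `Coverage`.
#' @export
simMetrics <- function(est, se, truth) {
  stopifnot(ncol(est) == length(truth), all(dim(est) == dim(se)))
  data.frame(
    parameter = names(truth),
    True = unname(truth),
    Est = colMeans(est),
    Bias = colMeans(est) - unname(truth),
    MSE = colMeans((est - matrix(truth, nrow(est), ncol(est),
                                 byrow = TRUE))^2),
    ASE = colMeans(se),
    MCSD = apply(est, 2, stats::sd),
    Coverage = 100 * colMeans(
      est - 1.96 * se <= matrix(truth, nrow(est), ncol(est), byrow = TRUE) &
      est + 1.96 * se >= matrix(truth, nrow(est), ncol(est), byrow = TRUE)),
    row.names = NULL)
}

#' Run a simulation study
#'
#' Simulates `nReps` data sets from the scenario, fits the requested model
#' to each, and aggregates bias, MSE, average model-based SE (ASE), Monte
#' Carlo SD (MCSD), and 95% Wald coverage per parameter, plus the derived
#' population-averaged marker value at `tDerived` years.  Comparisons for
#' variance components are made on the packed (transformed) scale;
#' non-converged replications are excluded and counted.
#'
#' @param scn a [simScenario()].
#' @param preset fitted-model comparator, see [scenarioConfig()].
#' @param nReps number of replications.
#' @param n subjects per replication.
#' @param seed master seed; replication r uses `seed + r`.
#' @param nodes Gauss-Hermite nodes per dimension for the fits.
#' @param tDerived time at which the derived mean marker is reported.
#' @param keepEstimates keep the replication-level estimate/SE matrices in
#'   the result (for reproducibility and reuse).
#' @param reltol,maxit optimizer tolerance and iteration cap for the
#'   replication fits.
#' @param warmStart start each replication's optimizer from the previous
#'   converged optimum (the first, and any replication after a failure,
#'   starts from [vjmInit()]); convergence is assessed per replication
#'   either way.
#' @param ... further arguments passed to [scenarioConfig()].
#' @return an object of class `simReport`.
#' @export
runSimStudy <- function(scn, preset = "correct", nReps = 50L, n = 300L,
                        seed = 1L, nodes = 4L, tDerived = 10,
                        keepEstimates = TRUE, warmStart = TRUE,
                        reltol = 1e-8, maxit = 150L, ...) {
  cfg <- scenarioConfig(scn, preset, nodes = nodes,
                        optim = list(reltol = reltol, maxit = maxit), ...)
  if (nReps < 2L) stop("need at least 2 replications")
  est <- se <- NULL
  mm <- matrix(NA_real_, nReps, 2,
               dimnames = list(NULL, c("estimate", "se")))
  excluded <- 0L
  truth <- NULL
  prev <- NULL
  for (r in seq_len(nReps)) {
    dat <- simulateData(scn, n, seed = seed + r)
    fit <- tryCatch(vjmFit(dat, cfg, init = prev),
                    error = function(e) NULL)
    ok <- !is.null(fit) && fit$convergence && !all(is.na(fit$se))
    if (warmStart) prev <- if (ok) fit$coefficients else NULL
    if (!ok) { excluded <- excluded + 1L; next }
    if (is.null(truth)) {
      frame <- modelFrame(dat, cfg)
      truth <- scenarioTruth(scn, frame,
                             misspecifiedVisiting =
                               preset == "ignore-marker")
      est <- matrix(NA_real_, nReps, length(truth),
                    dimnames = list(NULL, names(truth)))
      se <- est
    }
    est[r, ] <- fit$coefficients
    se[r, ] <- fit$se
    dm <- derivedMeanMarker(fit, tDerived)
    mm[r, ] <- c(dm$estimate, dm$se)
  }
  if (is.null(est) || sum(stats::complete.cases(est)) < 2L)
    stop("fewer than 2 converged replications")
  ok <- stats::complete.cases(est)
  tab <- simMetrics(est[ok, , drop = FALSE], se[ok, , drop = FALSE], truth)
  mmTruth <- meanMarker(scenarioBasis(scn), scn$beta, tDerived)
  mmRow <- simMetrics(mm[ok, 1, drop = FALSE], mm[ok, 2, drop = FALSE],
                      stats::setNames(mmTruth, sprintf("meanMarker@%gy",
                                                       tDerived)))
  tab <- rbind(tab, mmRow)
  structure(list(table = tab, nReps = nReps, nUsed = sum(ok),
                 excluded = excluded, n = n, seed = seed,
                 scenario = scn$name, preset = preset,
                 estimates = if (keepEstimates)
                   list(est = est[ok, , drop = FALSE],
                        se = se[ok, , drop = FALSE],
                        meanMarker = mm[ok, , drop = FALSE]) else NULL),
            class = "simReport")
}

#' @export
print.simReport <- function(x, digits = 3, ...) {
  cat("Simulation study:", x$scenario, "/", x$preset, "-", x$nUsed, "of",
      x$nReps, "replications used (", x$excluded, "excluded ), n =",
      x$n, "\n")
  tab <- x$table
  tab[-1] <- lapply(tab[-1], function(v) round(v, digits))
  print(tab, row.names = FALSE)
  invisible(x)
}
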