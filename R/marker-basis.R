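#' Marker design bases
#'
#' A `markerBasis` bundles the named basis functions of time that make up the
#' fixed- and random-effect design rows of the longitudinal marker model,
#' together with (optional) analytic time derivatives.  Evaluating the basis
#' at a vector of times returns one design row per time.  When analytic
#' derivatives are not supplied, slopes fall back to central differences with
#' step `1e-5 * max(1, |t|)`.
#'
#' @param fixed named list of vectorized functions of time, one per fixed
#'   design column.
#' @param random named list of functions for the random design; defaults to
#'   the fixed basis (shared trajectory shape).
#' @param fixedDeriv,randomDeriv optional lists of analytic derivatives,
#'   aligned with `fixed`/`random`.
#' @return an object of class `markerBasis`.
#' @export
markerBasis <- function(fixed, random = fixed,
                        fixedDeriv = NULL, randomDeriv = NULL) {
  stopifnot(is.list(fixed), length(fixed) >= 1L,
            all(vapply(fixed, is.function, logical(1))),
            is.list(random), all(vapply(random, is.function, logical(1))))
  if (is.null(names(fixed))) names(fixed) <- paste0("f", seq_along(fixed))
  if (is.null(names(random))) names(random) <- paste0("r", seq_along(random))
  if (!is.null(fixedDeriv)) stopifnot(length(fixedDeriv) == length(fixed))
  if (!is.null(randomDeriv)) stopifnot(length(randomDeriv) == length(random))
  if (identical(fixed, random) && is.null(randomDeriv)) randomDeriv <- fixedDeriv
  structure(list(fixed = fixed, random = random,
                 fixedDeriv = fixedDeriv, randomDeriv = randomDeriv,
                 p = length(fixed), q = length(random)),
            class = "markerBasis")
}

#' @export
print.markerBasis <- function(x, ...) {
  cat("Marker design basis\n")
  cat("  fixed  (p =", x$p, "):", paste(names(x$fixed), collapse = ", "), "\n")
  cat("  random (q =", x$q, "):", paste(names(x$random), collapse = ", "), "\n")
  cat("  analytic derivatives:",
      if (is.null(x$fixedDeriv)) "no (central differences)" else "yes", "\n")
  invisible(x)
}

#' Preset basis: intercept, log(t + 1), (t / 10)^3
#'
#' The trajectory shape used for square-root CD4 counts after treatment
#' initiation: a steep early rise that levels off (log term) plus a late
#' cubic trend.  Analytic derivatives are included.
#'
#' @return a `markerBasis` with identical fixed and random parts (q = 3).
#' @export
logCubicBasis <- function() {
  fns <- list(
    intercept = function(t) rep(1, length(t)),
    logt1     = function(t) log(t + 1),
    cubic     = function(t) (t / 10)^3
  )
  der <- list(
    intercept = function(t) rep(0, length(t)),
    logt1     = function(t) 1 / (t + 1),
    cubic     = function(t) 3 * t^2 / 1000
  )
  markerBasis(fixed = fns, fixedDeriv = der)
}

evalFns <- function(fns, t) {
  out <- vapply(fns, function(f) as.numeric(f(t)), numeric(length(t)))
  matrix(out, nrow = length(t), ncol = length(fns),
         dimnames = list(NULL, names(fns)))
}

#' Evaluate marker design rows
#'
#' @param basis a [markerBasis()].
#' @param t numeric vector of times (years).
#' @param which `"fixed"` or `"random"`.
#' @return a `length(t)` x p design matrix.
#' @export
evalBasis <- function(basis, t, which = c("fixed", "random")) {
  which <- match.arg(which)
  evalFns(basis[[which]], t)
}

#' Evaluate time derivatives of marker design rows
#'
#' Uses analytic derivatives when the basis carries them, otherwise central
#' differences with step `1e-5 * max(1, |t|)` per time point.
#'
#' @inheritParams evalBasis
#' @return a `length(t)` x p matrix of derivative rows.
#' @export
evalBasisDeriv <- function(basis, t, which = c("fixed", "random")) {
  which <- match.arg(which)
  dfns <- basis[[paste0(which, "Deriv")]]
  if (!is.null(dfns)) return(evalFns(dfns, t))
  fns <- basis[[which]]
  h <- 1e-5 * pmax(1, abs(t))
  up <- evalFns(fns, t + h)
  lo <- evalFns(fns, t - h)
  (up - lo) / (2 * h)
}
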