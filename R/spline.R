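#' Cubic B-spline basis for log-baseline hazards
#'
#' Builds the cubic B-spline machinery behind the log baseline hazard or
#' intensity, `log h0(u) = B(u)' psi`.  Inside the boundary knots the basis
#' is the standard cubic B-spline basis (a partition of unity); outside it is
#' extended linearly, matching the value and first derivative at the nearest
#' boundary, so the log-baseline stays finite and well behaved during
#' optimization.
#'
#' @param interior numeric vector of interior knots (time units), may be
#'   empty.
#' @param boundary length-2 numeric vector of boundary knots.
#' @param degree spline degree; only cubic (3) is supported.
#' @return an object of class `splineBasis` with `ncoef = length(interior) +
#'   degree + 1` basis columns.
#' @export
splineBasisHazard <- function(interior = numeric(), boundary, degree = 3L) {
  if (degree != 3L) stop("only cubic B-splines are supported")
  boundary <- sort(as.numeric(boundary))
  if (length(boundary) != 2L || boundary[1] >= boundary[2])
    stop("boundary must be two increasing knots")
  interior <- sort(as.numeric(interior))
  if (length(interior) && (min(interior) <= boundary[1] ||
                           max(interior) >= boundary[2]))
    stop("interior knots must lie strictly inside the boundary")
  knots <- c(rep(boundary[1], degree + 1L), interior,
             rep(boundary[2], degree + 1L))
  structure(list(degree = 3L, interior = interior, boundary = boundary,
                 knots = knots, ncoef = length(interior) + degree + 1L),
            class = "splineBasis")
}

#' @export
print.splineBasis <- function(x, ...) {
  cat("Cubic B-spline basis:", x$ncoef, "coefficients\n")
  cat("  boundary:", paste(x$boundary, collapse = " - "),
      " interior:", if (length(x$interior))
        paste(signif(x$interior, 4), collapse = ", ") else "(none)", "\n")
  invisible(x)
}

#' Evaluate spline basis rows
#'
#' Rows for times inside the boundary come from [splines::splineDesign()];
#' rows outside are the linear extension `B(b) + (u - b) B'(b)` at the
#' nearest boundary knot `b`.
#'
#' @param sb a [splineBasisHazard()] object.
#' @param u numeric vector of evaluation times.
#' @param deriv derivative order (0 or 1).
#' @return a `length(u)` x `ncoef` matrix.
#' @export
evalSpline <- function(sb, u, deriv = 0L) {
  u <- as.numeric(u)
  lo <- sb$boundary[1]; hi <- sb$boundary[2]
  ucl <- pmin(pmax(u, lo), hi)
  B <- splines::splineDesign(sb$knots, ucl, ord = sb$degree + 1L,
                             derivs = rep(deriv, length(u)))
  out <- which(u < lo | u > hi)
  if (length(out)) {
    if (deriv == 0L) {
      Bd <- splines::splineDesign(sb$knots, ucl[out], ord = sb$degree + 1L,
                                  derivs = rep(1L, length(out)))
      B[out, ] <- B[out, , drop = FALSE] + (u[out] - ucl[out]) * Bd
    }
    # deriv == 1: derivative of the linear extension is B'(boundary),
    # already what the clamped evaluation returns.
  }
  B
}

#' Log-baseline hazard
#'
#' `B(u)' psi`; its exponential is the baseline hazard (gap scale) or
#' intensity (calendar scale).
#'
#' @param sb a [splineBasisHazard()] object.
#' @param psi coefficient vector of length `sb$ncoef`.
#' @param u evaluation times.
#' @return numeric vector `B(u)' psi`.
#' @export
logBaseline <- function(sb, psi, u) {
  if (length(psi) != sb$ncoef)
    stop("psi must have length ", sb$ncoef)
  drop(evalSpline(sb, u) %*% psi)
}

#' Greville abscissae of a spline basis
#'
#' The coefficient sites at which equal coefficients reproduce constants and
#' linearly spaced coefficients reproduce linear functions; used to express
#' a log-linear baseline exactly in the spline span.
#'
#' @param sb a [splineBasisHazard()] object.
#' @return numeric vector of length `sb$ncoef`.
#' @export
grevilleSites <- function(sb) {
  k <- sb$knots
  d <- sb$degree
  vapply(seq_len(sb$ncoef),
         function(i) mean(k[(i + 1):(i + d)]), numeric(1))
}
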