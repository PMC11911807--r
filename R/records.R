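#' One subject's joint record
#'
#' Visit times (strictly increasing, typically starting at the baseline
#' visit t = 0), the marker value measured at each visit, the follow-up time
#' `Tobs >=` last visit time, the event cause (`0` = noninformative right
#' censoring, `1..K` = competing causes), and named baseline covariates.
#'
#' @param id subject identifier.
#' @param times numeric visit times in years, strictly increasing.
#' @param y marker values, one per visit.
#' @param Tobs follow-up time (years).
#' @param cause integer event code, 0 for censored.
#' @param covariates named list/vector of baseline covariates.
#' @return an object of class `subjectRecord`.
#' @export
subjectRecord <- function(id, times, y, Tobs, cause = 0L,
                          covariates = list()) {
  times <- as.numeric(times); y <- as.numeric(y)
  if (length(times) < 1L)
    stop("subject ", id, ": at least one visit is required")
  if (any(diff(times) <= 0))
    stop("subject ", id, ": visit times must be strictly increasing")
  if (length(y) != length(times))
    stop("subject ", id, ": one marker value per visit is required")
  if (anyNA(y) || anyNA(times))
    stop("subject ", id, ": missing marker values/times are not allowed")
  if (!is.numeric(Tobs) || length(Tobs) != 1L || Tobs < times[length(times)])
    stop("subject ", id, ": follow-up time T must be >= the last visit time")
  cause <- as.integer(cause)
  if (is.na(cause) || cause < 0L)
    stop("subject ", id, ": cause code must be a nonnegative integer")
  structure(list(id = id, times = times, y = y, n = length(times),
                 Tobs = Tobs, cause = cause,
                 covariates = as.list(covariates)),
            class = "subjectRecord")
}

#' @export
print.subjectRecord <- function(x, ...) {
  cat("Subject", x$id, ":", x$n, "visits over [0,",
      signif(x$Tobs, 4), "], cause =", x$cause, "\n")
  invisible(x)
}

#' History feature registry
#'
#' Named deterministic maps from the visit/marker history up to the j-th
#' visit (and baseline covariates) to scalar covariates entering the
#' hazard/intensity models.  Features at `t_ij` use only data with time
#' `<= t_ij` and are held constant until the next visit.
#'
#' Built-in features:
#' \describe{
#'   \item{`last_y`}{most recent observed marker value, `Y_ij`.}
#'   \item{`t_ij`}{the j-th visit time itself (calendar trend).}
#'   \item{`prev_gap`}{previous gap time centered at `center`
#'     (`(u_{i,j-1} - center) I(j > 1)`; 0 at the first visit).}
#'   \item{`visit_count`}{number of visits made so far, `N*(t^-) = j`.}
#'   \item{`mean_gap`}{mean of the gaps observed so far (the centering
#'     constant when none exist yet).}
#' }
#' Any other name is looked up among the subject's baseline covariates.
#'
#' @param record a [subjectRecord()].
#' @param features character vector of feature names.
#' @param center centering constant for `prev_gap` (years).
#' @return an `n_i` x `length(features)` matrix, row j holding the features
#'   at `t_ij`.
#' @export
historyFeatures <- function(record, features, center = 0.15) {
  n <- record$n
  gaps <- diff(record$times)
  out <- matrix(0, n, length(features),
                dimnames = list(NULL, features))
  for (f in seq_along(features)) {
    nm <- features[f]
    out[, f] <- switch(nm,
      last_y = record$y,
      t_ij = record$times,
      prev_gap = c(0, gaps - center),
      visit_count = seq_len(n),
      mean_gap = c(center, cumsum(gaps) / seq_along(gaps)),
      {
        v <- record$covariates[[nm]]
        if (is.null(v))
          stop("subject ", record$id, ": unknown feature or covariate '",
               nm, "'")
        rep(as.numeric(v), n)
      })
  }
  out
}
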