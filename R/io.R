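#' Joint data set
#'
#' Bundles a list of [subjectRecord()]s with the two tabular views: the
#' long-format marker table (`id`, `time`, `y`) and the subject-level table
#' (`id`, `Tobs`, `cause`, baseline covariates).
#'
#' @param records list of [subjectRecord()]s.
#' @return an object of class `jointData`.
#' @export
jointData <- function(records) {
  stopifnot(length(records) >= 1L,
            all(vapply(records, inherits, logical(1), "subjectRecord")))
  ids <- vapply(records, function(r) as.character(r$id), character(1))
  if (anyDuplicated(ids)) stop("duplicate subject ids")
  structure(list(records = records), class = "jointData")
}

#' @export
length.jointData <- function(x) length(x$records)

#' @export
print.jointData <- function(x, ...) {
  n <- length(x$records)
  nv <- vapply(x$records, function(r) r$n, numeric(1))
  ks <- vapply(x$records, function(r) r$cause, integer(1))
  cat("Joint data:", n, "subjects,", sum(nv), "visits",
      sprintf("(mean %.2f/subject)\n", mean(nv)))
  tb <- table(factor(ks, levels = 0:max(1, max(ks))))
  cat("  events by cause (0 = censored):",
      paste(names(tb), tb, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Long-format marker table of a joint data set
#' @param data a [jointData()] object.
#' @return data.frame with columns `id`, `time`, `y`.
#' @export
markerTable <- function(data) {
  do.call(rbind, lapply(data$records, function(r)
    data.frame(id = r$id, time = r$times, y = r$y)))
}

#' Subject-level table of a joint data set
#' @param data a [jointData()] object.
#' @return data.frame with columns `id`, `Tobs`, `cause`, and one column
#'   per baseline covariate.
#' @export
subjectTable <- function(data) {
  do.call(rbind, lapply(data$records, function(r) {
    base <- data.frame(id = r$id, Tobs = r$Tobs, cause = r$cause)
    if (length(r$covariates))
      base <- cbind(base, as.data.frame(r$covariates))
    base
  }))
}

#' Read a joint data set from CSV files
#'
#' Validates the long-format marker file (`id`, `time`, `y`) against the
#' subject-level file (`id`, `Tobs`, `cause`, covariates): ids must match
#' across files, times must be strictly increasing without duplicates, and
#' follow-up must not end before the last visit.  A short summary is
#' reported via `message()`.
#'
#' @param markerPath path to the marker CSV.
#' @param subjectPath path to the subject CSV.
#' @param quiet suppress the summary message.
#' @return a [jointData()] object.
#' @export
readJointData <- function(markerPath, subjectPath, quiet = FALSE) {
  mk <- utils::read.csv(markerPath)
  su <- utils::read.csv(subjectPath)
  need <- function(df, cols, path)
    if (!all(cols %in% names(df)))
      stop("file ", path, " must have columns ",
           paste(cols, collapse = ", "))
  need(mk, c("id", "time", "y"), markerPath)
  need(su, c("id", "Tobs", "cause"), subjectPath)
  mids <- unique(as.character(mk$id))
  sids <- as.character(su$id)
  if (anyDuplicated(sids)) stop("duplicate ids in the subject file")
  only <- c(setdiff(mids, sids), setdiff(sids, mids))
  if (length(only))
    stop("subjects present in only one file: ",
         paste(utils::head(only, 5), collapse = ", "))
  covNames <- setdiff(names(su), c("id", "Tobs", "cause"))
  records <- lapply(seq_len(nrow(su)), function(i) {
    id <- su$id[i]
    rows <- mk[as.character(mk$id) == as.character(id), , drop = FALSE]
    rows <- rows[order(rows$time), , drop = FALSE]
    if (anyDuplicated(rows$time))
      stop("subject ", id, ": duplicate (id, time) marker rows")
    subjectRecord(id, rows$time, rows$y, su$Tobs[i], su$cause[i],
                  covariates = as.list(su[i, covNames, drop = FALSE]))
  })
  data <- jointData(records)
  if (!quiet) {
    ks <- vapply(records, function(r) r$cause, integer(1))
    message("read ", length(records), " subjects, ",
            sum(vapply(records, function(r) r$n, numeric(1))), " visits; ",
            "events by cause: ",
            paste(names(table(ks)), table(ks), sep = "=", collapse = ", "))
  }
  data
}

#' Write a joint data set to CSV files
#'
#' @param data a [jointData()] object.
#' @param dir output directory (created if missing).
#' @param prefix file-name prefix.
#' @return invisibly, the two file paths.
#' @export
writeJointData <- function(data, dir, prefix = "data") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  mp <- file.path(dir, paste0(prefix, "_marker.csv"))
  sp <- file.path(dir, paste0(prefix, "_subjects.csv"))
  utils::write.csv(markerTable(data), mp, row.names = FALSE)
  utils::write.csv(subjectTable(data), sp, row.names = FALSE)
  invisible(c(marker = mp, subjects = sp))
}
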