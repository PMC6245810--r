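# Core container for right-censored, case-weighted survival data.

#' Construct a survival cohort
#'
#' A cohort is a weighted collection of right-censored observations: one
#' follow-up time per subject (years from the study origin), an event
#' indicator (1 = event, 0 = censored), and a positive case weight. Weights
#' default to 1; the ghost-augmentation machinery raises them uniformly to
#' `(N + M) / N` when `M` pseudo-observations are spread across the `N`
#' real subjects.
#'
#' @param time Numeric vector of strictly positive, finite follow-up times
#'   (years). Ties are permitted; zero follow-up is rejected because a
#'   subject with no time at risk has no defined contribution.
#' @param event Vector of event indicators, each 0 (censored) or 1 (event).
#' @param weight Positive, finite case weights. A scalar is recycled.
#' @param label Free-text label carried through to printed output.
#' @param n_nominal Unweighted sample size N. Defaults to the number of
#'   observations; it is retained unchanged under ghost weighting so that
#'   the uniform weight `(N + M) / N` stays anchored to the real sample.
#'
#' @return An object of class `cohort`: a list with elements `time`,
#'   `event`, `weight`, `n_nominal`, and `label`.
#' @seealso [read_cohort()], [generate_cohort()], [apply_ghost_weights()]
#' @export
#' @examples
#' cohort(time = c(1, 2, 3), event = c(1, 0, 1))
cohort <- function(time, event, weight = 1, label = "", n_nominal = length(time)) {
  time <- as.numeric(time)
  event <- as.numeric(event)
  weight <- rep_len(as.numeric(weight), length(time))
  if (length(time) < 1L) {
    stop("a cohort needs at least one observation", call. = FALSE)
  }
  if (length(event) != length(time)) {
    stop("'time' and 'event' must have the same length", call. = FALSE)
  }
  bad_time <- which(!is.finite(time) | time <= 0)
  if (length(bad_time) > 0L) {
    stop(sprintf("non-positive or non-finite time in row %d", bad_time[1L]),
         call. = FALSE)
  }
  bad_event <- which(!(event %in% c(0, 1)))
  if (length(bad_event) > 0L) {
    stop(sprintf("event indicator outside {0, 1} in row %d", bad_event[1L]),
         call. = FALSE)
  }
  bad_weight <- which(!is.finite(weight) | weight <= 0)
  if (length(bad_weight) > 0L) {
    stop(sprintf("non-positive or non-finite weight in row %d", bad_weight[1L]),
         call. = FALSE)
  }
  structure(
    list(time = time, event = as.integer(event), weight = weight,
         n_nominal = as.integer(n_nominal), label = as.character(label)[1L]),
    class = "cohort"
  )
}

#' @export
print.cohort <- function(x, ...) {
  cat("<cohort>", if (nzchar(x$label)) paste0(" ", x$label), "\n", sep = "")
  cat(sprintf("  observations: %d (nominal N = %d, weighted size = %.6g)\n",
              length(x$time), x$n_nominal, weighted_size(x)))
  cat(sprintf("  events: %d unweighted (%.6g weighted), follow-up %.3g-%.3g years\n",
              sum(x$event), sum(x$weight * x$event),
              min(x$time), max(x$time)))
  invisible(x)
}

#' Total weighted size of a cohort
#'
#' The sum of case weights; equals `n_nominal` when all weights are 1 and
#' `n_nominal + M` after `M` ghosts have been spread uniformly.
#'
#' @param cohort A [cohort()] object.
#' @return A single number.
#' @export
weighted_size <- function(cohort) {
  stopifnot(inherits(cohort, "cohort"))
  sum(cohort$weight)
}

#' @export
as.data.frame.cohort <- function(x, ...) {
  data.frame(time = x$time, event = x$event, weight = x$weight)
}

#' Read a cohort from delimited text
#'
#' Expects a header row and '.' as decimal separator. When the weight
#' column is absent all weights are 1. Every parsed row is validated
#' against the cohort invariants (positive finite time, event in \{0, 1\},
#' positive finite weight) and the first offending row is named in the
#' error.
#'
#' @param path Path to a delimited text file.
#' @param time_column,event_column,weight_column Column names; the weight
#'   column is optional.
#' @param delimiter Field separator, comma by default.
#' @return A [cohort()] with one observation per data row and
#'   `n_nominal` equal to the row count.
#' @export
read_cohort <- function(path, time_column = "time", event_column = "event",
                        weight_column = "weight", delimiter = ",") {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  df <- utils::read.table(path, header = TRUE, sep = delimiter,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          fileEncoding = "UTF-8")
  if (nrow(df) == 0L) stop("empty cohort file", call. = FALSE)
  for (col in c(time_column, event_column)) {
    if (!col %in% names(df)) {
      stop(sprintf("column '%s' not found in %s", col, path), call. = FALSE)
    }
  }
  parse_num <- function(col) {
    raw <- df[[col]]
    x <- suppressWarnings(as.numeric(raw))
    bad <- which(is.na(x) & !is.na(raw))
    if (length(bad) > 0L) {
      stop(sprintf("non-numeric value '%s' in column '%s', row %d",
                   raw[bad[1L]], col, bad[1L]), call. = FALSE)
    }
    x
  }
  w <- if (weight_column %in% names(df)) parse_num(weight_column) else 1
  cohort(time = parse_num(time_column), event = parse_num(event_column),
         weight = w, label = basename(path))
}

#' Write a cohort to delimited text
#'
#' Numbers are written with 17 significant digits so that a re-read
#' reproduces times, events, and weights exactly (lossless round trip).
#'
#' @param cohort A [cohort()] object.
#' @param path Output path.
#' @param delimiter Field separator, comma by default.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path, delimiter = ",") {
  stopifnot(inherits(cohort, "cohort"))
  fmt <- function(x) formatC(x, digits = 17, format = "g")
  lines <- c(
    paste(c("time", "event", "weight"), collapse = delimiter),
    paste(fmt(cohort$time), cohort$event, fmt(cohort$weight), sep = delimiter)
  )
  ok <- tryCatch({
    writeLines(lines, path, useBytes = TRUE)
    TRUE
  }, error = function(e) e, warning = function(w) w)
  if (!isTRUE(ok)) {
    stop(sprintf("cannot write cohort to '%s': %s", path,
                 conditionMessage(ok)), call. = FALSE)
  }
  invisible(path)
}
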