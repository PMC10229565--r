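#' Interbeat-interval series
#'
#' An `ibi_series` holds one short (typically 5-minute) assessment of RR
#' intervals together with its subject, study-day and session tags. Intervals
#' are in milliseconds throughout the package; values that look like seconds
#' (all below 10) are rejected rather than silently converted.
#'
#' @param intervals numeric vector of interbeat intervals in milliseconds,
#'   all strictly positive.
#' @param subject_id subject identifier (opaque string).
#' @param day_index integer days since the subject's first assessment
#'   (day 0 = first day).
#' @param session `"morning"` or `"evening"`.
#' @return an object of class `ibi_series`.
#' @examples
#' s <- ibi_series(c(800, 810, 790), "s01", day_index = 0, session = "morning")
#' length(s$intervals)
#' @export
ibi_series <- function(intervals, subject_id = "anonymous", day_index = 0L,
                       session = c("morning", "evening")) {
  session <- match.arg(session)
  if (!is.numeric(intervals) || length(intervals) < 2) {
    stop("an IBI series needs at least 2 numeric intervals", call. = FALSE)
  }
  bad <- which(!is.finite(intervals) | intervals <= 0)
  if (length(bad) > 0) {
    stop(sprintf("invalid interbeat interval at row %d: %s (must be > 0 ms)",
                 bad[1], format(intervals[bad[1]])), call. = FALSE)
  }
  if (all(intervals < 10)) {
    stop(paste0("all intervals are below 10; this looks like seconds, not ",
                "milliseconds - convert to ms before loading"), call. = FALSE)
  }
  day_index <- as.integer(day_index)
  if (is.na(day_index) || day_index < 0) {
    stop("day_index must be a non-negative integer", call. = FALSE)
  }
  structure(
    list(subject_id = as.character(subject_id), day_index = day_index,
         session = session, intervals = as.numeric(intervals)),
    class = "ibi_series"
  )
}

#' @export
print.ibi_series <- function(x, ...) {
  cat(sprintf("<ibi_series> subject %s, day %d, %s: %d beats, mean %.1f ms\n",
              x$subject_id, x$day_index, x$session, length(x$intervals),
              mean(x$intervals)))
  invisible(x)
}

#' Weekly symptom-score series
#'
#' Weekly SCL-90 depression-subscale scores for one subject. Weeks are
#' 0-indexed from study start; week `w` covers study days `7w .. 7w + 6`.
#' Missing weeks are allowed (gaps stay gaps, nothing is imputed); duplicate
#' weeks are an error.
#'
#' @param week_index integer vector of week numbers (0-based), unique.
#' @param score numeric vector of non-negative subscale scores (points).
#' @param subject_id subject identifier.
#' @return an object of class `symptom_series`, sorted by week.
#' @export
symptom_series <- function(week_index, score, subject_id = "anonymous") {
  week_index <- as.integer(week_index)
  if (length(week_index) != length(score)) {
    stop("week_index and score must have equal length", call. = FALSE)
  }
  if (anyNA(week_index) || any(week_index < 0)) {
    stop("week_index must be non-negative integers", call. = FALSE)
  }
  if (anyDuplicated(week_index)) {
    stop(sprintf("duplicate week_index: %d",
                 week_index[duplicated(week_index)][1]), call. = FALSE)
  }
  if (anyNA(score) || any(score < 0)) {
    stop("scores must be non-negative", call. = FALSE)
  }
  ord <- order(week_index)
  structure(
    list(subject_id = as.character(subject_id),
         week_index = week_index[ord], score = as.numeric(score)[ord]),
    class = "symptom_series"
  )
}

#' @export
print.symptom_series <- function(x, ...) {
  cat(sprintf("<symptom_series> subject %s: %d weeks (%d..%d)\n",
              x$subject_id, length(x$week_index),
              min(x$week_index), max(x$week_index)))
  invisible(x)
}
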