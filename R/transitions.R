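#' Detect a depressive transition from weekly symptom scores
#'
#' A subject transitions when (1) a weekly SCL-90 depression-subscale score
#' rises by at least `threshold` points above a reference level, and (2) the
#' elevation persists for at least `persistence_weeks` consecutive observed
#' weeks (missing weeks break the run). The reference level is the mean of
#' the subject's first `reference_weeks` available weekly scores. A clinical
#' override flag (start/increase of treatment or interruption of tapering,
#' established outside this package) substitutes for the persistence
#' criterion when set; it is never inferred from the data.
#'
#' @param symptoms a [symptom_series()].
#' @param threshold reliable-increase threshold in points (default 8.5).
#' @param persistence_weeks consecutive elevated weeks required (default 3).
#' @param reference_weeks number of initial scores averaged into the
#'   reference level (default 4).
#' @param override logical clinical override for the persistence criterion.
#' @return a list of class `transition_label`: `transitioned` (logical, `NA`
#'   when unlabelable), `transition_week`, `criteria` (named logical flags),
#'   `reference`, `pseudo = FALSE`, and `reason` when unlabelable.
#' @export
detect_transition <- function(symptoms, threshold = 8.5,
                              persistence_weeks = 3L, reference_weeks = 4L,
                              override = FALSE) {
  stopifnot(inherits(symptoms, "symptom_series"))
  wk <- symptoms$week_index
  sc <- symptoms$score
  if (length(sc) < reference_weeks) {
    return(structure(list(subject_id = symptoms$subject_id, transitioned = NA,
                          transition_week = NA_integer_,
                          criteria = c(increase = NA, persistence = NA,
                                       override = override),
                          reference = NA_real_, pseudo = FALSE,
                          reason = sprintf("fewer_than_%d_scores",
                                           reference_weeks)),
                     class = "transition_label"))
  }
  reference <- mean(sc[seq_len(reference_weeks)])
  elevated <- (sc - reference) >= threshold
  n <- length(sc)
  hit_week <- NA_integer_
  persistence_ok <- FALSE
  for (i in which(elevated)) {
    # run of consecutive observed weeks, all elevated, starting at i
    run <- 1L
    while (i + run <= n && wk[i + run] == wk[i] + run && elevated[i + run]) {
      run <- run + 1L
    }
    if (run >= persistence_weeks) {
      hit_week <- wk[i]
      persistence_ok <- TRUE
      break
    }
    if (override && is.na(hit_week)) {
      hit_week <- wk[i]
      break
    }
  }
  transitioned <- !is.na(hit_week)
  structure(list(subject_id = symptoms$subject_id, transitioned = transitioned,
                 transition_week = hit_week,
                 criteria = c(increase = any(elevated),
                              persistence = persistence_ok,
                              override = override),
                 reference = reference, pseudo = FALSE, reason = NULL),
            class = "transition_label")
}

#' @export
print.transition_label <- function(x, ...) {
  cat(sprintf("<transition_label> %s: %s%s\n", x$subject_id,
              if (isTRUE(x$transitioned)) sprintf("transition at week %d", x$transition_week)
              else if (isFALSE(x$transitioned)) "no transition"
              else paste0("unlabelable (", x$reason, ")"),
              if (x$pseudo) " [pseudo]" else ""))
  invisible(x)
}

#' Pair-match pseudo-transition weeks onto non-transitioning subjects
#'
#' Each non-transitioning subject receives an anchor ("pseudo-transition")
#' week pair-matched from the transitioning group: both lists are sorted by
#' subject id and matched positionally; if the groups differ in size the
#' shorter week list cycles (logged in the output). A pseudo week beyond a
#' subject's last observed week is capped at that week (`capped = TRUE`).
#'
#' @param transition_weeks named integer vector: observed transition week per
#'   transitioning subject (names = subject ids).
#' @param non_transition_subjects character vector of subject ids.
#' @param last_observed_weeks named integer vector: last observed week per
#'   non-transitioning subject.
#' @return tibble with columns `subject_id`, `pseudo_week`, `source_subject`,
#'   `capped`, `cycled`.
#' @export
assign_pseudo_transitions <- function(transition_weeks,
                                      non_transition_subjects,
                                      last_observed_weeks) {
  if (length(transition_weeks) == 0) {
    stop("no transition weeks to pair-match", call. = FALSE)
  }
  tw <- transition_weeks[order(names(transition_weeks))]
  subj <- sort(non_transition_subjects)
  src_idx <- ((seq_along(subj) - 1L) %% length(tw)) + 1L
  wk <- unname(tw[src_idx])
  last <- unname(last_observed_weeks[subj])
  if (anyNA(last)) stop("last_observed_weeks missing for some subjects",
                        call. = FALSE)
  capped <- wk > last
  tibble::tibble(subject_id = subj,
                 pseudo_week = as.integer(pmin(wk, last)),
                 source_subject = names(tw)[src_idx],
                 capped = capped,
                 cycled = seq_along(subj) > length(tw))
}

#' Extract a pre-transition or baseline window of assessments
#'
#' Windows are half-open day intervals with day 0 = the subject's first
#' assessment day and week `w` starting at day `7w`. `kind = "pretransition"`
#' covers the 8 weeks before the anchor week, days `[7(anchor - 8),
#' 7 anchor)`, truncated at day 0; `kind = "baseline"` covers the first 4
#' weeks of measurement, days `[0, 28)`. A window is flagged insufficient
#' when the span of days holding data is shorter than 3 weeks (21 days).
#'
#' @param assessments tibble of per-assessment rows with a `day_index`
#'   column (e.g. from [compute_quantifiers()]).
#' @param anchor_week transition (or pseudo-transition) week; unused for
#'   baseline windows.
#' @param kind `"pretransition"` or `"baseline"`.
#' @param pre_weeks pre-transition window length in weeks (default 8).
#' @param baseline_weeks baseline window length in weeks (default 4).
#' @param min_span_days minimum data span for sufficiency (default 21).
#' @return a list: `data` (the subset, sessions preserved), `sufficient`,
#'   `span_days`, `interval` (`c(start_day, end_day_exclusive)`).
#' @export
extract_window <- function(assessments, anchor_week = NULL,
                           kind = c("pretransition", "baseline"),
                           pre_weeks = 8L, baseline_weeks = 4L,
                           min_span_days = 21L) {
  kind <- match.arg(kind)
  stopifnot("day_index" %in% names(assessments))
  if (kind == "pretransition") {
    if (is.null(anchor_week) || is.na(anchor_week)) {
      stop("pretransition window needs an anchor week", call. = FALSE)
    }
    end <- 7L * as.integer(anchor_week)
    start <- max(0L, end - 7L * as.integer(pre_weeks))
  } else {
    start <- 0L
    end <- 7L * as.integer(baseline_weeks)
  }
  sel <- assessments$day_index >= start & assessments$day_index < end
  data <- assessments[sel, , drop = FALSE]
  span <- if (nrow(data) == 0) 0L else
    as.integer(max(data$day_index) - min(data$day_index))
  list(data = data, sufficient = span >= min_span_days,
       span_days = span, interval = c(start, end))
}
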