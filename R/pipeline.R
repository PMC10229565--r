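#' Baseline between-group analysis of a cohort
#'
#' The group-level arm of the pipeline in one call: per-subject baseline
#' person-averages (first 4 weeks, sufficiency-checked), Mann-Whitney
#' comparisons with Cohen's d per quantifier and session, single-predictor
#' logistic models with Nagelkerke R-squared, and the entropy threshold grid
#' search.
#'
#' @param quantifiers tibble of per-assessment quantifier rows covering the
#'   baseline window (e.g. from [cohort_quantifiers()]).
#' @param groups tibble with `subject_id` and `group` (labels `"transition"`
#'   and `"control"`).
#' @param config a [complexity_config()] (echoed into results only).
#' @param sessions sessions analysed.
#' @param quantifier_cols quantifier columns analysed.
#' @return list of class `baseline_analysis`: `averages` (subject x session),
#'   `comparison` (the Mann-Whitney / Cohen's d table), `models` (tibble of
#'   single-predictor logistic fits: predictor, session, estimate, se, z,
#'   p_value, nagelkerke_r2, pct_correct, separation), `thresholds` (grid
#'   search per entropy/session), `excluded`.
#' @export
baseline_analysis <- function(quantifiers, groups,
                              config = complexity_config(),
                              sessions = c("morning", "evening"),
                              quantifier_cols = c("mean_ibi", "sdrr",
                                                  "higuchi_dim", "mse")) {
  avg_rows <- list(); excl <- list()
  for (sid in unique(groups$subject_id)) {
    sub <- quantifiers[quantifiers$subject_id == sid, , drop = FALSE]
    win <- extract_window(sub, kind = "baseline")
    if (!win$sufficient) {
      excl[[length(excl) + 1]] <- tibble::tibble(
        subject_id = sid,
        reason = sprintf("baseline_span_%dd_lt_21d", win$span_days))
      next
    }
    pa <- person_average(win$data, quantifier_cols)
    pa$subject_id <- sid
    pa$group <- groups$group[match(sid, groups$subject_id)]
    avg_rows[[length(avg_rows) + 1]] <- pa
  }
  if (length(avg_rows) == 0) stop("no subject with a sufficient baseline",
                                  call. = FALSE)
  averages <- do.call(rbind, avg_rows)
  averages <- averages[averages$session %in% sessions, , drop = FALSE]
  comparison <- group_compare(averages, quantifier_cols = quantifier_cols)
  model_rows <- list()
  for (sess in sessions) {
    d <- averages[averages$session == sess, , drop = FALSE]
    y <- as.integer(d$group == "transition")
    for (qc in quantifier_cols) {
      ok <- is.finite(d[[qc]])
      fit <- tryCatch(
        fit_logistic(y[ok], stats::setNames(data.frame(x = d[[qc]][ok]), qc)),
        error = function(e) NULL)
      if (is.null(fit)) next
      cf <- fit$coefficients[2, ]
      model_rows[[length(model_rows) + 1]] <- tibble::tibble(
        predictor = qc, session = sess, estimate = cf$estimate, se = cf$se,
        z = cf$z, p_value = cf$p_value,
        nagelkerke_r2 = fit$nagelkerke_r2, pct_correct = fit$pct_correct,
        separation = fit$separation)
    }
  }
  models <- if (length(model_rows)) do.call(rbind, model_rows) else NULL
  thr_rows <- list()
  for (sess in sessions) {
    d <- averages[averages$session == sess, , drop = FALSE]
    ok <- is.finite(d$mse)
    if (sum(ok) >= 2 && length(unique(d$group[ok])) == 2) {
      gs <- grid_search_threshold(d$mse[ok], d$group[ok] == "transition")
      thr_rows[[length(thr_rows) + 1]] <- tibble::tibble(
        quantifier = "mse", session = sess, threshold = gs$threshold,
        n_correct = gs$n_correct, n_total = gs$n_total)
    }
  }
  structure(list(
    averages = averages, comparison = comparison, models = models,
    thresholds = if (length(thr_rows)) do.call(rbind, thr_rows) else NULL,
    excluded = if (length(excl)) do.call(rbind, excl) else NULL,
    config = config), class = "baseline_analysis")
}

#' @export
print.baseline_analysis <- function(x, ...) {
  cat(sprintf("<baseline_analysis> %d subjects x %d sessions\n",
              length(unique(x$averages$subject_id)),
              length(unique(x$averages$session))))
  print(x$comparison)
  invisible(x)
}
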