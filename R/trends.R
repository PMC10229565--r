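#' Mann-Kendall trend test (Kendall tau-b against time)
#'
#' Tie-corrected Kendall correlation between a quantifier and time, with a
#' two-sided p-value. For n <= 10 with no tied values the p-value comes from
#' the exact null distribution of the Kendall statistic; otherwise from the
#' normal approximation with continuity correction and the tie-corrected
#' variance of the Mann-Kendall S statistic (times are required strictly
#' increasing, so only value ties enter the correction).
#'
#' @param values numeric quantifier values.
#' @param times numeric observation times (strictly increasing).
#' @param alpha significance level used only to classify `direction`.
#' @return tibble row: `tau`, `p_value`, `n`, `s` (Mann-Kendall S),
#'   `direction` (`"negative"`, `"none"`, `"positive"`), `degenerate`.
#' @export
kendall_trend <- function(values, times, alpha = 0.05) {
  keep <- is.finite(values) & is.finite(times)
  v <- values[keep]; t <- times[keep]
  n <- length(v)
  if (n < 3) stop("trend test needs at least 3 observations", call. = FALSE)
  if (any(diff(t) <= 0)) stop("times must be strictly increasing", call. = FALSE)
  if (length(unique(v)) == 1) {
    return(tibble::tibble(tau = 0, p_value = 1, n = n, s = 0,
                          direction = "none", degenerate = TRUE))
  }
  sgn <- outer(v, v, function(a, b) sign(b - a))
  s <- sum(sgn[upper.tri(sgn)])
  ties <- table(v)
  ties <- ties[ties > 1]
  n0 <- n * (n - 1) / 2
  nt <- sum(ties * (ties - 1) / 2)
  tau <- s / sqrt((n0 - nt) * n0)   # tau-b; times are untied
  if (n <= 10 && length(ties) == 0) {
    p <- stats::cor.test(v, t, method = "kendall", exact = TRUE)$p.value
  } else {
    var_s <- (n * (n - 1) * (2 * n + 5) -
                sum(ties * (ties - 1) * (2 * ties + 5))) / 18
    z <- if (s > 0) (s - 1) / sqrt(var_s)
         else if (s < 0) (s + 1) / sqrt(var_s) else 0
    p <- 2 * stats::pnorm(-abs(z))
  }
  p <- min(p, 1)
  direction <- if (p < alpha) {
    if (tau > 0) "positive" else "negative"
  } else "none"
  tibble::tibble(tau = tau, p_value = p, n = n, s = s,
                 direction = direction, degenerate = FALSE)
}

#' Scan a cohort for pre-transition time trends
#'
#' For every subject with a (pseudo-)transition anchor, extracts the
#' 8-week pre-transition window, splits it into morning and evening series,
#' and runs [kendall_trend()] of each quantifier against `day_index`.
#' Subjects whose window holds less than 3 weeks of data, or a session
#' series with fewer than 3 usable assessments, are excluded and logged.
#'
#' @param quantifiers tibble of per-assessment quantifier rows (from
#'   [compute_quantifiers()] / [cohort_quantifiers()]) for the whole cohort.
#' @param anchors tibble with columns `subject_id`, `anchor_week`, `group`
#'   (e.g. `"transition"` / `"control"`).
#' @param quantifier_cols quantifier columns to test.
#' @param alpha significance level for the direction classification.
#' @return list: `results` (one row per subject x session x quantifier),
#'   `excluded` (subject, session, reason), `summary` (counts of significant
#'   negative/positive trends per group x session x quantifier).
#' @export
trend_scan <- function(quantifiers, anchors,
                       quantifier_cols = c("mean_ibi", "sdrr", "higuchi_dim", "mse"),
                       alpha = 0.05) {
  res <- list(); excl <- list()
  for (i in seq_len(nrow(anchors))) {
    sid <- anchors$subject_id[i]
    anchor <- anchors$anchor_week[i]
    grp <- anchors$group[i]
    sub <- quantifiers[quantifiers$subject_id == sid, , drop = FALSE]
    win <- extract_window(sub, anchor_week = anchor, kind = "pretransition")
    if (!win$sufficient) {
      excl[[length(excl) + 1]] <- tibble::tibble(
        subject_id = sid, session = NA_character_,
        reason = sprintf("window_span_%dd_lt_21d", win$span_days))
      next
    }
    for (sess in unique(win$data$session)) {
      dat <- win$data[win$data$session == sess & win$data$usable, , drop = FALSE]
      dat <- dat[order(dat$day_index), , drop = FALSE]
      for (qc in quantifier_cols) {
        ok <- is.finite(dat[[qc]])
        if (sum(ok) < 3) {
          excl[[length(excl) + 1]] <- tibble::tibble(
            subject_id = sid, session = sess,
            reason = sprintf("%s_lt_3_usable", qc))
          next
        }
        tr <- kendall_trend(dat[[qc]][ok], dat$day_index[ok], alpha = alpha)
        res[[length(res) + 1]] <- tibble::tibble(
          subject_id = sid, group = grp, session = sess, quantifier = qc, tr)
      }
    }
  }
  results <- if (length(res)) do.call(rbind, res) else
    tibble::tibble(subject_id = character(), group = character(),
                   session = character(), quantifier = character())
  excluded <- if (length(excl)) do.call(rbind, excl) else
    tibble::tibble(subject_id = character(), session = character(),
                   reason = character())
  summary <- NULL
  if (nrow(results) > 0) {
    agg <- stats::aggregate(
      cbind(n_negative = results$direction == "negative",
            n_positive = results$direction == "positive",
            n_tested = rep(1L, nrow(results))),
      by = list(group = results$group, session = results$session,
                quantifier = results$quantifier), FUN = sum)
    summary <- tibble::as_tibble(agg)
  }
  list(results = results, excluded = excluded, summary = summary)
}
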