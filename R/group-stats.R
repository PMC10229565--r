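#' Person-average quantifiers over a window
#'
#' Averages each quantifier over the usable assessments of a window,
#' separately per session, recording how many assessments contributed.
#'
#' @param window_data tibble of per-assessment quantifier rows (the `data`
#'   element of [extract_window()]).
#' @param quantifier_cols columns to average.
#' @return tibble with one row per session present: `session`,
#'   `n_assessments`, and the averaged quantifier columns.
#' @export
person_average <- function(window_data,
                           quantifier_cols = c("mean_ibi", "sdrr",
                                               "higuchi_dim", "mse")) {
  usable <- window_data[window_data$usable %in% TRUE, , drop = FALSE]
  if (nrow(usable) == 0) stop("no usable assessments in window", call. = FALSE)
  out <- lapply(split(usable, usable$session), function(d) {
    row <- tibble::tibble(session = d$session[1], n_assessments = nrow(d))
    for (qc in quantifier_cols) {
      row[[qc]] <- mean(d[[qc]], na.rm = TRUE)
    }
    row
  })
  do.call(rbind, out)
}

#' Mann-Whitney U test
#'
#' Two-sided comparison of two independent samples. The p-value is exact
#' (network enumeration, via [stats::wilcox.test()]) when both groups have
#' at most 8 observations and there are no ties, and otherwise comes from
#' the tie-corrected normal approximation with continuity correction. The
#' z-score is always reported from the normal approximation so that large
#' samples and printed tables can be compared.
#'
#' @param a,b numeric vectors (non-empty).
#' @return list: `U` (statistic for group `a`), `z`, `p_value`, `exact`.
#' @export
mann_whitney <- function(a, b) {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  n1 <- length(a); n2 <- length(b)
  if (n1 == 0 || n2 == 0) stop("both groups must be non-empty", call. = FALSE)
  r <- rank(c(a, b))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  ties <- table(c(a, b))
  tie_term <- sum(ties^3 - ties) / ((n1 + n2) * (n1 + n2 - 1))
  sig2 <- n1 * n2 / 12 * ((n1 + n2 + 1) - tie_term)
  z <- if (sig2 > 0) {
    cc <- if (U > mu) -0.5 else if (U < mu) 0.5 else 0
    (U - mu + cc) / sqrt(sig2)
  } else 0
  no_ties <- length(ties) == n1 + n2
  exact <- n1 <= 8 && n2 <= 8 && no_ties
  p <- if (exact) {
    stats::wilcox.test(a, b, exact = TRUE)$p.value
  } else {
    min(1, 2 * stats::pnorm(-abs(z)))
  }
  list(U = U, z = z, p_value = p, exact = exact)
}

#' Cohen's d from summary statistics (pooled SD)
#'
#' `d = (m1 - m2) / s_p` with the pooled standard deviation
#' `s_p = sqrt(((n1-1) s1^2 + (n2-1) s2^2) / (n1 + n2 - 2))`; for equal
#' group sizes this reduces to `(m1 - m2) / sqrt((s1^2 + s2^2) / 2)`.
#'
#' @param m1,s1,n1 mean, SD, size of group 1.
#' @param m2,s2,n2 mean, SD, size of group 2.
#' @return Cohen's d (sign follows `m1 - m2`); `Inf`-valued with a warning
#'   when both SDs are zero but the means differ.
#' @export
cohens_d <- function(m1, s1, n1, m2, s2, n2) {
  stopifnot(s1 >= 0, s2 >= 0, n1 >= 2, n2 >= 2)
  sp <- sqrt(((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / (n1 + n2 - 2))
  if (sp == 0) {
    if (m1 == m2) return(0)
    warning("zero pooled SD with unequal means: infinite effect size")
    return(sign(m1 - m2) * Inf)
  }
  (m1 - m2) / sp
}

#' Between-group comparison of person-averaged quantifiers
#'
#' For every quantifier and session, compares the two groups with the
#' Mann-Whitney U test and reports group means, SDs and Cohen's d
#' (group 1 minus group 2, pooled SD).
#'
#' @param averages tibble with one row per subject x session: columns
#'   `subject_id`, `session`, `group`, and the quantifier columns.
#' @param group1,group2 the two group labels to compare (defaults
#'   `"transition"` and `"control"`).
#' @param quantifier_cols quantifier columns.
#' @return tibble: `quantifier`, `session`, `m1`, `sd1`, `n1`, `m2`, `sd2`,
#'   `n2`, `U`, `z`, `p_value`, `cohen_d`.
#' @export
group_compare <- function(averages, group1 = "transition", group2 = "control",
                          quantifier_cols = c("mean_ibi", "sdrr",
                                              "higuchi_dim", "mse")) {
  rows <- list()
  for (sess in unique(averages$session)) {
    d <- averages[averages$session == sess, , drop = FALSE]
    for (qc in quantifier_cols) {
      x1 <- d[[qc]][d$group == group1]
      x2 <- d[[qc]][d$group == group2]
      x1 <- x1[is.finite(x1)]; x2 <- x2[is.finite(x2)]
      mw <- mann_whitney(x1, x2)
      rows[[length(rows) + 1]] <- tibble::tibble(
        quantifier = qc, session = sess,
        m1 = mean(x1), sd1 = stats::sd(x1), n1 = length(x1),
        m2 = mean(x2), sd2 = stats::sd(x2), n2 = length(x2),
        U = mw$U, z = mw$z, p_value = mw$p_value,
        cohen_d = cohens_d(mean(x1), stats::sd(x1), length(x1),
                           mean(x2), stats::sd(x2), length(x2)))
    }
  }
  do.call(rbind, rows)
}

#' Spearman correlation table for baseline averages
#'
#' Pairwise-complete Spearman rho and p for every pair of the supplied
#' columns, the rank-based dependence structure among age and the
#' person-averaged quantifiers.
#'
#' @param data tibble/data frame with one row per subject.
#' @param cols columns to correlate (default: all numeric columns).
#' @return tibble: `var1`, `var2`, `rho`, `p_value`, `n` (complete pairs);
#'   `rho` is `NA` for constant columns (flagged in `note`).
#' @export
spearman_matrix <- function(data, cols = NULL) {
  df <- as.data.frame(data)
  if (is.null(cols)) cols <- names(df)[vapply(df, is.numeric, logical(1))]
  rows <- list()
  for (i in seq_along(cols)) {
    for (j in seq_len(i)) {
      x <- df[[cols[i]]]; y <- df[[cols[j]]]
      ok <- is.finite(x) & is.finite(y)
      note <- NA_character_
      if (sum(ok) < 3) {
        rho <- NA_real_; p <- NA_real_; note <- "fewer_than_3_pairs"
      } else if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) {
        rho <- NA_real_; p <- NA_real_; note <- "constant_column"
      } else {
        ct <- suppressWarnings(
          stats::cor.test(x[ok], y[ok], method = "spearman"))
        rho <- unname(ct$estimate); p <- ct$p.value
      }
      rows[[length(rows) + 1]] <- tibble::tibble(
        var1 = cols[i], var2 = cols[j], rho = rho, p_value = p,
        n = sum(ok), note = note)
    }
  }
  do.call(rbind, rows)
}

#' Logistic regression predicting transition status
#'
#' Maximum-likelihood logistic fit (IRLS via [stats::glm()], tolerance 1e-8,
#' up to 100 iterations) of a binary transition flag on baseline predictors.
#' Predictors are standardized internally for numerical stability and the
#' coefficients, standard errors and covariance are reported back on the raw
#' scale. Reports Wald z and p per coefficient, Nagelkerke's
#' \eqn{R^2 = \frac{1 - (L_0/L_1)^{2/n}}{1 - L_0^{2/n}}}, and the share of
#' subjects classified correctly at a fitted-probability cutoff of 0.5.
#' (Quasi-)complete separation is diagnosed (fitted probabilities pinned at
#' 0/1 or exploding standardized coefficients) and reported via
#' `converged = FALSE` rather than as a crash: with strongly discriminating
#' predictors at n = 28 this is an expected outcome.
#'
#' @param y logical/0-1 outcome vector (transition = 1).
#' @param X data frame or matrix of predictors (one column per predictor).
#' @return list of class `logistic_model`: `coefficients` (tibble: `term`,
#'   `estimate`, `se`, `z`, `p_value`), `nagelkerke_r2`, `pct_correct`,
#'   `converged`, `separation`, `n`, `loglik`, `loglik_null`.
#' @export
fit_logistic <- function(y, X) {
  y <- as.integer(y)
  stopifnot(all(y %in% c(0L, 1L)))
  X <- as.data.frame(X)
  if (any(vapply(X, function(c) stats::sd(c) == 0, logical(1)))) {
    stop("constant predictor column", call. = FALSE)
  }
  n <- length(y)
  if (min(table(factor(y, levels = 0:1))) < 2) {
    stop("need at least 2 subjects in each outcome class", call. = FALSE)
  }
  mu <- vapply(X, mean, numeric(1))
  sdv <- vapply(X, stats::sd, numeric(1))
  Z <- as.data.frame(scale(X))
  dat <- cbind(data.frame(.y = y), Z)
  warned_sep <- FALSE
  fit <- withCallingHandlers(
    stats::glm(.y ~ ., data = dat, family = stats::binomial(),
               control = list(epsilon = 1e-8, maxit = 100)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        warned_sep <<- TRUE
      invokeRestart("muffleWarning")
    })
  cf <- stats::coef(fit)
  Vz <- stats::vcov(fit)
  p <- length(sdv)
  # back-transform: raw = A %*% standardized, A maps (b0, b) std -> raw
  A <- diag(c(1, 1 / sdv), nrow = p + 1)
  A[1, -1] <- -mu / sdv
  beta <- drop(A %*% cf)
  V <- A %*% Vz %*% t(A)
  se <- sqrt(diag(V))
  zval <- beta / se
  pval <- 2 * stats::pnorm(-abs(zval))
  ll1 <- as.numeric(stats::logLik(fit))
  fit0 <- stats::glm(y ~ 1, family = stats::binomial())
  ll0 <- as.numeric(stats::logLik(fit0))
  r2 <- (1 - exp(2 / n * (ll0 - ll1))) / (1 - exp(2 / n * ll0))
  pct <- 100 * mean((stats::fitted(fit) >= 0.5) == (y == 1))
  separation <- warned_sep || any(abs(cf[-1]) > 15)
  structure(list(
    coefficients = tibble::tibble(
      term = c("(Intercept)", names(X)), estimate = beta, se = se,
      z = zval, p_value = pval),
    nagelkerke_r2 = min(max(r2, 0), 1), pct_correct = pct,
    converged = fit$converged && !separation, separation = separation,
    n = n, loglik = ll1, loglik_null = ll0,
    vcov = V), class = "logistic_model")
}

#' @export
print.logistic_model <- function(x, ...) {
  cat(sprintf("<logistic_model> n = %d, Nagelkerke R2 = %.3f, %.1f%% correct%s\n",
              x$n, x$nagelkerke_r2, x$pct_correct,
              if (x$separation) " [separation]" else ""))
  print(x$coefficients)
  invisible(x)
}

#' Threshold grid search for single-quantifier discrimination
#'
#' Scans the midpoints between adjacent sorted unique values and returns the
#' threshold that classifies the most subjects correctly, where values
#' *below* the threshold are predicted to transition (the low-entropy ->
#' transition direction). Ties are broken toward the lowest threshold. With
#' all values equal there is no midpoint; the majority class count is
#' returned with a missing threshold.
#'
#' @param values numeric per-subject values (e.g. baseline entropy).
#' @param labels logical: `TRUE` for transition.
#' @return list: `threshold`, `n_correct`, `n_total`.
#' @export
grid_search_threshold <- function(values, labels) {
  labels <- as.logical(labels)
  ok <- is.finite(values) & !is.na(labels)
  values <- values[ok]; labels <- labels[ok]
  if (!any(labels) || all(labels)) stop("both classes required", call. = FALSE)
  u <- sort(unique(values))
  n <- length(values)
  if (length(u) == 1) {
    return(list(threshold = NA_real_,
                n_correct = max(sum(labels), sum(!labels)), n_total = n))
  }
  cand <- (u[-1] + u[-length(u)]) / 2
  correct <- vapply(cand, function(th) {
    sum((values < th) == labels)
  }, numeric(1))
  best <- which.max(correct)   # which.max takes the first (lowest) on ties
  list(threshold = cand[best], n_correct = as.integer(correct[best]),
       n_total = n)
}
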