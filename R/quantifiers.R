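#' Complexity configuration
#'
#' Tunable parameters for the per-assessment quantifiers. Defaults:
#' `kmax = 5` (Higuchi maximum delay time), sample-entropy embedding
#' `m = 2`, tolerance `r_factor = 0.2` (fraction of the raw series' SD,
#' fixed once at scale 1 and reused at all coarse-graining scales),
#' `max_scale = NULL` meaning "largest scale whose coarse-grained series
#' keeps at least `10 * (m + 1)` points, capped at 5", and a usability
#' cutoff of `min_beats = 100`.
#'
#' @param kmax Higuchi maximum delay (>= 2).
#' @param m sample-entropy template length (>= 1).
#' @param r_factor tolerance as a fraction of the series SD, in (0, 1).
#' @param max_scale integer scale cap, or `NULL` for the data-driven default.
#' @param min_beats minimum beats for a series to be usable.
#' @return a list of class `complexity_config`.
#' @export
complexity_config <- function(kmax = 5L, m = 2L, r_factor = 0.2,
                              max_scale = NULL, min_beats = 100L) {
  stopifnot(kmax >= 2, m >= 1, r_factor > 0, r_factor < 1,
            is.null(max_scale) || max_scale >= 1, min_beats >= 1)
  structure(list(kmax = as.integer(kmax), m = as.integer(m),
                 r_factor = r_factor,
                 max_scale = if (is.null(max_scale)) NULL else as.integer(max_scale),
                 min_beats = as.integer(min_beats)),
            class = "complexity_config")
}

# largest scale keeping >= 10*(m+1) coarse-grained points, capped at 5
auto_max_scale <- function(n, m, cap = 5L) {
  s <- max(1L, min(cap, n %/% (10L * (m + 1L))))
  s
}

#' Quality screen for an IBI series
#'
#' Flags a series unusable when it has fewer than `min_beats` intervals or
#' when more than 5% of intervals fall outside the physiological range
#' 300--2000 ms. Intervals are flagged, never modified or removed.
#'
#' @param series an [ibi_series()].
#' @param config a [complexity_config()].
#' @return a list with elements `series` (untouched), `usable`, `reasons`
#'   (character, empty when usable) and `flagged` (indices of out-of-range
#'   intervals).
#' @export
ibi_quality_filter <- function(series, config = complexity_config()) {
  stopifnot(inherits(series, "ibi_series"))
  x <- series$intervals
  flagged <- which(x < 300 | x > 2000)
  reasons <- character(0)
  if (length(x) < config$min_beats) {
    reasons <- c(reasons, sprintf("too_short:%d<%d", length(x), config$min_beats))
  }
  if (length(flagged) / length(x) > 0.05) {
    reasons <- c(reasons, sprintf("out_of_range:%d_of_%d", length(flagged),
                                  length(x)))
  }
  list(series = series, usable = length(reasons) == 0, reasons = reasons,
       flagged = flagged)
}

#' Mean interbeat interval
#' @param x numeric intervals (ms) or an [ibi_series()].
#' @return mean IBI in ms.
#' @export
mean_ibi <- function(x) {
  x <- as_intervals(x)
  if (length(x) == 0) stop("empty series", call. = FALSE)
  mean(x)
}

#' Standard deviation of RR intervals (SDRR)
#'
#' Sample (n - 1) convention, the standard in HRV reporting.
#' @inheritParams mean_ibi
#' @return SDRR in ms.
#' @export
sdrr <- function(x) {
  x <- as_intervals(x)
  if (length(x) < 2) stop("SDRR needs at least 2 beats", call. = FALSE)
  stats::sd(x)
}

as_intervals <- function(x) {
  if (inherits(x, "ibi_series")) x$intervals else as.numeric(x)
}

#' Higuchi fractal dimension
#'
#' Estimates the fractal dimension of a series from the scaling of curve
#' length with delay time. For each delay `k = 1..kmax` and initial time
#' `m = 1..k`, the normalized curve length is
#' \deqn{L_m(k) = \frac{1}{k}\left[\sum_{i=1}^{\lfloor (N-m)/k \rfloor}
#'   |x(m+ik) - x(m+(i-1)k)|\right] \frac{N-1}{\lfloor (N-m)/k \rfloor k},}
#' `L(k)` is the mean over `m`, and the dimension is minus the slope of the
#' unweighted least-squares fit of `ln L(k)` on `ln k`. A smooth curve gives
#' 1, uncorrelated noise approaches 2, and a fractional-Brownian track with
#' Hurst exponent `H` gives `2 - H`.
#'
#' @inheritParams mean_ibi
#' @param kmax maximum delay time (default 5).
#' @return the dimension estimate; `NA` with a `"reason"` attribute when the
#'   log-log fit is degenerate (e.g. a constant series with zero lengths).
#' @export
higuchi_dimension <- function(x, kmax = 5L) {
  x <- as_intervals(x)
  n <- length(x)
  kmax <- as.integer(kmax)
  if (kmax < 2) stop("kmax must be >= 2", call. = FALSE)
  if (n < kmax + 1) stop("series shorter than kmax + 1", call. = FALSE)
  lk <- numeric(kmax)
  for (k in seq_len(kmax)) {
    lm_ <- numeric(k)
    for (m in seq_len(k)) {
      idx <- seq.int(m, n, by = k)
      ni <- (n - m) %/% k
      lm_[m] <- sum(abs(diff(x[idx]))) * (n - 1) / (ni * k) / k
    }
    lk[k] <- mean(lm_)
  }
  if (any(lk <= 0) || !all(is.finite(lk))) {
    return(structure(NA_real_, reason = "degenerate_loglog_fit"))
  }
  -ls_slope(log(seq_len(kmax)), log(lk))
}

#' Coarse-grain a series
#'
#' Non-overlapping window means of width `scale`; any trailing remainder is
#' dropped. Scale 1 is the identity.
#'
#' @inheritParams mean_ibi
#' @param scale integer window width, `1 <= scale <= length(x)`.
#' @return numeric vector of length `floor(length(x) / scale)`.
#' @export
coarse_grain <- function(x, scale) {
  x <- as_intervals(x)
  scale <- as.integer(scale)
  if (scale < 1) stop("scale must be >= 1", call. = FALSE)
  if (scale > length(x)) stop("scale exceeds series length", call. = FALSE)
  if (scale == 1L) return(x)
  n2 <- length(x) %/% scale
  colMeans(matrix(x[seq_len(n2 * scale)], nrow = scale))
}

#' Sample entropy
#'
#' `SampEn(m, r) = -ln(A / B)` where `B` counts template pairs of length `m`
#' within Chebyshev distance `r_abs` and `A` the same for length `m + 1`,
#' self-matches excluded (Richman-Moorman counting over the first `N - m`
#' templates, so a constant series gives exactly 0). Returns `Inf` when no
#' `m + 1` matches exist, and `NA` (flagged) when even `B` is zero.
#'
#' @inheritParams mean_ibi
#' @param m template length.
#' @param r_abs absolute tolerance (same units as `x`).
#' @return sample entropy (dimensionless), with attributes `A` and `B`.
#' @export
sample_entropy <- function(x, m = 2L, r_abs) {
  x <- as_intervals(x)
  if (length(x) <= m + 1) stop("series too short for sample entropy", call. = FALSE)
  if (r_abs <= 0) stop("r_abs must be positive", call. = FALSE)
  cnt <- sampen_counts(x, as.integer(m), r_abs)
  out <- if (cnt$B == 0) {
    structure(NA_real_, reason = "no_m_matches")
  } else if (cnt$A == 0) {
    Inf
  } else {
    -log(cnt$A / cnt$B)
  }
  attr(out, "A") <- cnt$A
  attr(out, "B") <- cnt$B
  out
}

#' Multiscale sample entropy
#'
#' Computes sample entropy on coarse-grained copies of the series at scales
#' `1..max_scale` with a tolerance fixed from the raw (scale-1) series,
#' `r_abs = r_factor * sd(x)`, and returns the mean of the finite per-scale
#' values. Non-finite scales (no template matches) are excluded from the
#' mean and flagged. A constant series has entropy 0 at every scale.
#'
#' @inheritParams mean_ibi
#' @param config a [complexity_config()].
#' @return mean SampEn across scales, with attributes `per_scale`, `r_abs`
#'   and `flagged` (TRUE when any scale was non-finite); `NA` with a reason
#'   when no scale yields a finite value.
#' @export
multiscale_entropy <- function(x, config = complexity_config()) {
  x <- as_intervals(x)
  n <- length(x)
  m <- config$m
  smax <- config$max_scale %||% auto_max_scale(n, m)
  s <- stats::sd(x)
  if (s == 0) {
    per <- rep(0, smax)
    return(structure(0, per_scale = per, r_abs = 0, flagged = FALSE))
  }
  r_abs <- config$r_factor * s
  per <- numeric(smax)
  for (sc in seq_len(smax)) {
    cg <- coarse_grain(x, sc)
    per[sc] <- if (length(cg) > m + 1) {
      as.numeric(sample_entropy(cg, m = m, r_abs = r_abs))
    } else NA_real_
  }
  fin <- is.finite(per)
  if (!any(fin)) {
    return(structure(NA_real_, per_scale = per, r_abs = r_abs, flagged = TRUE,
                     reason = "no_finite_scale"))
  }
  structure(mean(per[fin]), per_scale = per, r_abs = r_abs,
            flagged = !all(fin))
}

#' Compute the four per-assessment quantifiers
#'
#' Applies the quality screen and then the mean IBI, SDRR, Higuchi dimension
#' and multiscale entropy. Unusable series yield a row with `usable = FALSE`
#' and all quantifiers missing.
#'
#' @param series an [ibi_series()].
#' @param config a [complexity_config()].
#' @return a one-row tibble with columns `subject_id`, `day_index`,
#'   `session`, `n_beats`, `usable`, `mean_ibi`, `sdrr`, `higuchi_dim`,
#'   `mse`, `mse_flagged` and `quality_reasons`.
#' @export
compute_quantifiers <- function(series, config = complexity_config()) {
  tibble::as_tibble(quantifier_row(series, config))
}

# plain-list version of compute_quantifiers; the tibble wrapper is built
# once per cohort, not once per assessment
quantifier_row <- function(series, config = complexity_config()) {
  stopifnot(inherits(series, "ibi_series"))
  q <- ibi_quality_filter(series, config)
  row <- list(
    subject_id = series$subject_id, day_index = series$day_index,
    session = series$session, n_beats = length(series$intervals),
    usable = q$usable,
    mean_ibi = NA_real_, sdrr = NA_real_, higuchi_dim = NA_real_,
    mse = NA_real_, mse_flagged = NA,
    quality_reasons = paste(q$reasons, collapse = ";")
  )
  if (!q$usable) return(row)
  x <- series$intervals
  hd <- higuchi_dimension(x, kmax = config$kmax)
  ms <- multiscale_entropy(x, config)
  row$mean_ibi <- mean(x)
  row$sdrr <- stats::sd(x)
  row$higuchi_dim <- as.numeric(hd)
  row$mse <- as.numeric(ms)
  row$mse_flagged <- isTRUE(attr(ms, "flagged"))
  row
}

#' Read a complexity configuration file
#'
#' Accepts either JSON (`{"kmax": 5, ...}`) or simple `key=value` lines;
#' recognized keys are `kmax`, `m`, `r_factor`, `max_scale` and `min_beats`.
#' Unknown keys are an error so typos cannot silently fall back to defaults.
#'
#' @param path configuration file.
#' @return a [complexity_config()].
#' @export
read_complexity_config <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  txt <- readLines(path, warn = FALSE)
  vals <- if (any(grepl("^\\s*\\{", txt))) {
    jsonlite::fromJSON(paste(txt, collapse = "\n"))
  } else {
    kv <- txt[grepl("=", txt, fixed = TRUE)]
    parts <- strsplit(kv, "=", fixed = TRUE)
    stats::setNames(lapply(parts, function(p) as.numeric(trimws(p[2]))),
                    vapply(parts, function(p) trimws(p[1]), character(1)))
  }
  known <- c("kmax", "m", "r_factor", "max_scale", "min_beats")
  bad <- setdiff(names(vals), known)
  if (length(bad) > 0) {
    stop("unknown configuration key(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  do.call(complexity_config, vals)
}
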