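#' IAAFT surrogate of a series
#'
#' Iterated Amplitude Adjusted Fourier Transform: starting from a random
#' shuffle, alternately (i) imposes the original Fourier amplitude spectrum
#' while keeping the current phases and (ii) rank-remaps the values onto the
#' sorted original amplitudes, until the rank ordering stops changing or
#' `max_iter` is reached. The returned series is the rank-remapped iterate,
#' so its sorted values equal the sorted input exactly while the power
#' spectrum matches the original approximately and phases are randomized.
#' Because the phases come from the real-valued iterate itself, conjugate
#' symmetry (including the 0-or-pi Nyquist phase at even lengths) is
#' preserved automatically.
#'
#' A constant series has no defined phases and is returned unchanged with
#' attribute `constant = TRUE`.
#'
#' @param x numeric vector or [ibi_series()].
#' @param seed optional integer seed (the caller's RNG state is preserved).
#' @param max_iter iteration cap (default 100).
#' @return numeric surrogate (or an `ibi_series` when the input was one),
#'   with attribute `iterations`.
#' @export
iaaft_surrogate <- function(x, seed = NULL, max_iter = 100L) {
  is_series <- inherits(x, "ibi_series")
  v <- as_intervals(x)
  n <- length(v)
  if (max_iter < 1) stop("max_iter must be >= 1", call. = FALSE)
  if (stats::sd(v) == 0) {
    out <- structure(v, constant = TRUE, iterations = 0L)
    return(if (is_series) rewrap_series(x, v, constant = TRUE) else out)
  }
  amp_sorted <- sort(v)
  target_mag <- Mod(stats::fft(v))
  surr <- with_seed(seed, {
    s <- sample(v)
    prev_ranks <- integer(0)
    iter <- 0L
    repeat {
      iter <- iter + 1L
      ph <- Arg(stats::fft(s))
      cand <- Re(stats::fft(complex(modulus = target_mag, argument = ph),
                            inverse = TRUE)) / n
      ranks <- rank(cand, ties.method = "first")
      s <- amp_sorted[ranks]  # rank-remap onto the original amplitudes
      if (identical(ranks, prev_ranks) || iter >= max_iter) break
      prev_ranks <- ranks
    }
    structure(s, iterations = iter)
  })
  if (is_series) rewrap_series(x, as.numeric(surr)) else surr
}

rewrap_series <- function(template, intervals, constant = FALSE) {
  out <- ibi_series(intervals, subject_id = template$subject_id,
                    day_index = template$day_index,
                    session = template$session)
  if (constant) attr(out, "constant") <- TRUE
  out
}

#' Surrogate-data test for nonlinearity
#'
#' Computes a quantifier on each assessment and on `n_surrogates` IAAFT
#' surrogates per assessment, then compares the observed values with the
#' surrogate values. Under the null hypothesis that the data arise from a
#' (possibly rescaled) linear Gaussian process, observed and surrogate
#' quantifiers are exchangeable; a significant difference indicates
#' nonlinear structure.
#'
#' Two comparison modes are available. `"pooled"` (default) runs a
#' two-sided Wilcoxon rank-sum test of the observed values against all
#' surrogate values pooled across assessments. `"rank"` uses, for each
#' assessment, the rank of the observed value among its own surrogates --
#' uniform on `1..n_surrogates + 1` under the null -- and refers the summed
#' ranks to their exact null distribution (two-sided, by convolution). The
#' rank mode is calibrated per assessment and is insensitive to
#' between-assessment heterogeneity.
#'
#' @param assessments list of [ibi_series()] (or numeric vectors).
#' @param quantifier_fn function mapping a numeric series to a scalar, e.g.
#'   `function(x) multiscale_entropy(x)` or `higuchi_dimension`.
#' @param n_surrogates surrogates per assessment (default 39, giving a
#'   1-in-40 per-assessment rank resolution).
#' @param seed integer seed; surrogate seeds are derived deterministically
#'   from it per assessment and replicate.
#' @param mode `"pooled"` or `"rank"`.
#' @param max_iter IAAFT iteration cap.
#' @return a list of class `surrogate_test`: `quantifier`, `observed`,
#'   `surrogate` (matrix, assessments x surrogates), `statistic`, `p_value`,
#'   `n_surrogates`, `mode`, `seed`.
#' @export
surrogate_nonlinearity_test <- function(assessments, quantifier_fn,
                                        n_surrogates = 39L, seed = 1L,
                                        mode = c("pooled", "rank"),
                                        max_iter = 100L) {
  mode <- match.arg(mode)
  if (n_surrogates < 1) stop("n_surrogates must be >= 1", call. = FALSE)
  if (length(assessments) < 2) stop("need at least 2 assessments", call. = FALSE)
  qname <- deparse(substitute(quantifier_fn))[1]
  obs <- vapply(assessments, function(a) as.numeric(quantifier_fn(as_intervals(a))),
                numeric(1))
  keep <- is.finite(obs)
  if (!any(keep)) stop("quantifier missing for all assessments", call. = FALSE)
  idx <- which(keep)
  surr <- matrix(NA_real_, nrow = length(idx), ncol = n_surrogates)
  for (r in seq_along(idx)) {
    a <- as_intervals(assessments[[idx[r]]])
    for (s in seq_len(n_surrogates)) {
      sg <- iaaft_surrogate(a, seed = derive_seed(seed, paste0("a", idx[r], "s", s)),
                            max_iter = max_iter)
      surr[r, s] <- as.numeric(quantifier_fn(as.numeric(sg)))
    }
  }
  obs_use <- obs[keep]
  if (mode == "pooled") {
    pool <- as.vector(surr)
    pool <- pool[is.finite(pool)]
    wt <- stats::wilcox.test(obs_use, pool, exact = FALSE, correct = TRUE)
    statistic <- unname(wt$statistic)
    p <- wt$p.value
  } else {
    # per-assessment rank of the observed value among its own surrogates;
    # exact null by convolution of n iid uniform{1..k} rank distributions
    ok <- apply(is.finite(surr), 1, all)
    ranks <- vapply(which(ok), function(r) {
      sum(surr[r, ] < obs_use[r]) + 0.5 * sum(surr[r, ] == obs_use[r]) + 1
    }, numeric(1))
    k <- n_surrogates + 1
    statistic <- sum(ranks)
    p <- rank_sum_exact_p(statistic, length(ranks), k)
  }
  structure(list(quantifier = qname, observed = obs, surrogate = surr,
                 statistic = statistic, p_value = max(p, .Machine$double.xmin),
                 n_surrogates = as.integer(n_surrogates), mode = mode,
                 seed = seed),
            class = "surrogate_test")
}

#' @export
print.surrogate_test <- function(x, ...) {
  cat(sprintf("<surrogate_test> %s: %d assessments x %d IAAFT surrogates (%s)\n",
              x$quantifier, length(x$observed), x$n_surrogates, x$mode))
  cat(sprintf("  statistic = %.4g, p = %.4g\n", x$statistic, x$p_value))
  invisible(x)
}

# two-sided exact tail probability of the sum of n iid uniform{1..k} ranks
rank_sum_exact_p <- function(S, n, k) {
  pmf <- rep(1 / k, k)
  dist <- pmf
  if (n > 1) {
    for (i in 2:n) dist <- stats::convolve(dist, rev(pmf), type = "o")
  }
  vals <- n:(n * k)
  mu <- n * (k + 1) / 2
  dev <- abs(S - mu)
  min(1, sum(dist[abs(vals - mu) >= dev - 1e-9]))
}
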