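#' Fractional Gaussian noise by circulant embedding
#'
#' Exact simulation of stationary fGn with Hurst exponent `H` via the
#' Davies-Harte circulant-embedding construction: the autocovariance
#' `gamma(k) = (|k+1|^{2H} - 2|k|^{2H} + |k-1|^{2H}) / 2` is embedded in a
#' circulant matrix whose eigenvalues are obtained by FFT, and a Gaussian
#' vector with exactly that covariance is synthesized in the spectral
#' domain. Unit marginal variance. The cumulative sum of fGn is a
#' fractional-Brownian (fBm) track whose graph has fractal dimension
#' `2 - H`, which anchors the Higuchi-dimension validation.
#'
#' @param n length of the series.
#' @param hurst Hurst exponent in (0, 1).
#' @param seed optional integer seed.
#' @return numeric vector of length `n`.
#' @export
fgn <- function(n, hurst, seed = NULL) {
  stopifnot(n >= 1, hurst > 0, hurst < 1)
  if (abs(hurst - 0.5) < 1e-12) {
    return(with_seed(seed, stats::rnorm(n)))
  }
  m <- 2^ceiling(log2(2 * max(n - 1, 1)))
  k <- 0:(m / 2)
  g <- (abs(k + 1)^(2 * hurst) - 2 * abs(k)^(2 * hurst) +
          abs(k - 1)^(2 * hurst)) / 2
  row1 <- c(g, rev(g[2:(m / 2)]))
  lambda <- Re(stats::fft(row1))
  lambda[lambda < 0] <- 0  # clip tiny negative eigenvalues (roundoff)
  with_seed(seed, {
    half <- m / 2
    u <- stats::rnorm(half - 1); v <- stats::rnorm(half - 1)
    w <- complex(length.out = m)
    w[1] <- stats::rnorm(1)
    w[half + 1] <- stats::rnorm(1)
    w[2:half] <- complex(real = u, imaginary = v) / sqrt(2)
    w[(half + 2):m] <- Conj(rev(w[2:half]))
    x <- stats::fft(sqrt(lambda) * w) / sqrt(m)
    Re(x)[seq_len(n)]
  })
}

#' Simulate one IBI assessment
#'
#' Builds a short RR-interval series as target mean plus a scaled mixture of
#' (i) a predictable respiratory-like oscillation -- a primary sinusoid of
#' period ~6.5 beats plus a faster harmonic (period ~3.25 beats) whose share
#' is `fast_fraction` -- and (ii) a fractional-Brownian track (cumulated
#' fGn), the slowly wandering aperiodic part of RR dynamics. The
#' `complexity_level` knob in \[0, 1\] shifts weight from the periodic
#' component to the track and simultaneously roughens the track
#' (`hurst = 0.65 - 0.3 * complexity_level`), so higher levels give higher
#' multiscale entropy; the harmonic raises the Higuchi dimension while
#' staying perfectly predictable, decoupling the two complexity measures
#' the way person-level data show (higher dimension with lower entropy).
#' The zero-mean fluctuation is rescaled so the realized mean and SDRR hit
#' the targets exactly.
#'
#' @param target_mean_ibi target mean RR interval, ms (500--1200).
#' @param target_sdrr target SDRR, ms (> 0).
#' @param complexity_level in \[0, 1\].
#' @param n_beats number of intervals (>= 16).
#' @param seed optional integer seed.
#' @param hurst Hurst exponent of the fGn driving the aperiodic track;
#'   default follows `complexity_level` as above.
#' @param fast_fraction share of the harmonic within the periodic component,
#'   in \[0, 1\] (default 0.15).
#' @return numeric vector of intervals (ms).
#' @export
simulate_ibi_assessment <- function(target_mean_ibi, target_sdrr,
                                    complexity_level, n_beats = 350L,
                                    seed = NULL, hurst = NULL,
                                    fast_fraction = 0.15) {
  stopifnot(target_mean_ibi >= 500, target_mean_ibi <= 1200,
            target_sdrr > 0, complexity_level >= 0, complexity_level <= 1,
            fast_fraction >= 0, fast_fraction <= 1, n_beats >= 16)
  hurst <- hurst %||% (0.65 - 0.3 * complexity_level)
  with_seed(seed, {
    t <- seq_len(n_beats)
    period <- 6.5 + stats::runif(1, -0.3, 0.3)
    s1 <- sin(2 * pi * t / period + stats::runif(1, 0, 2 * pi))
    s2 <- sin(2 * pi * t / (period / 2) + stats::runif(1, 0, 2 * pi))
    periodic <- (1 - fast_fraction) * s1 / stats::sd(s1) +
      fast_fraction * s2 / stats::sd(s2)
    track <- cumsum(fgn(n_beats, hurst))
    w_per <- 1 - complexity_level
    w_noise <- complexity_level
    if (w_noise == 0) {
      s <- periodic
    } else if (w_per == 0) {
      s <- track
    } else {
      s <- w_per * periodic / stats::sd(periodic) +
        w_noise * track / stats::sd(track)
    }
    s <- (s - mean(s)) / stats::sd(s)
    x <- target_mean_ibi + target_sdrr * s
    if (any(x <= 0)) {
      stop("infeasible target combination: intervals would be non-positive",
           call. = FALSE)
    }
    x
  })
}

#' Simulate a weekly symptom series
#'
#' Flat baseline plus i.i.d. Gaussian noise; transitioning subjects get a
#' sustained step increase from their transition week onward (a step, not a
#' ramp, keeps label recovery unambiguous). Scores are floored at 0.
#'
#' @param n_weeks number of weekly scores (weeks `0..n_weeks-1`).
#' @param base baseline subscale level, points.
#' @param noise_sd weekly measurement noise SD, points.
#' @param transition_week 0-based week of the step, or `NULL` for none.
#' @param step step height, points (default 10, above the 8.5 criterion).
#' @param seed optional integer seed.
#' @param subject_id subject id for the returned series.
#' @return a [symptom_series()].
#' @export
simulate_symptoms <- function(n_weeks, base = 10, noise_sd = 2,
                              transition_week = NULL, step = 10,
                              seed = NULL, subject_id = "anonymous") {
  with_seed(seed, {
    sc <- base + stats::rnorm(n_weeks, sd = noise_sd)
    if (!is.null(transition_week) && !is.na(transition_week) &&
        transition_week < n_weeks) {
      idx <- (transition_week + 1):n_weeks
      sc[idx] <- sc[idx] + step
    }
    symptom_series(0:(n_weeks - 1), pmax(sc, 0), subject_id = subject_id)
  })
}

#' Specification of a synthetic cohort
#'
#' Parameter bundle for [simulate_cohort()]. The defaults encode the study
#' conditions the pipeline is built for: two groups of 14 subjects, ~5-min
#' assessments twice daily over 120 days, ~350 +/- 40 beats per assessment,
#' 10% of assessments missing completely at random, transition weeks uniform
#' over weeks 5--14, weekly symptom noise SD of 2 points with a +10-point
#' sustained step at transition. Group-level quantifier structure follows
#' the published baseline contrasts: the transition group has a higher mean
#' IBI, a higher Higuchi dimension and a lower multiscale entropy. Mean-IBI
#' and SDRR targets per group/session are drawn from Gaussian between-
#' subject distributions matching the published person-averaged M +/- SD;
#' the entropy contrast is carried by the per-subject `complexity_level`
#' (transition 0.30, control 0.46, between-subject SD 0.07), calibrated once
#' so the person-averaged baseline MSE separates with Cohen's d near -2,
#' and the modest positive Higuchi contrast by a larger fast-oscillation
#' share in the transition group (`fast_fraction` mean 0.25 vs 0.10,
#' between-subject SD 0.12).
#'
#' @param n_transition,n_control group sizes.
#' @param days study length in days.
#' @param beats_mean,beats_sd per-assessment beat-count distribution.
#' @param missingness probability an assessment is missing, in \[0, 1).
#' @param transition_week_range inclusive 0-based week range of transitions.
#' @param mean_ibi_targets,sdrr_targets named lists of `c(mean, sd)` per
#'   `transition_morning` etc.; between-subject target distributions in ms.
#' @param complexity named list per group: `c(mean, sd)` of the latent
#'   complexity level.
#' @param fast_fraction named list per group: `c(mean, sd)` of the
#'   per-subject share of the fast harmonic in the periodic component
#'   (controls the Higuchi-dimension level and contrast).
#' @param trend_slope per-day pre-transition drift added to the transition
#'   group's complexity level (0 = no injected trend).
#' @param symptom_base,symptom_noise_sd,symptom_step symptom-model
#'   parameters, points.
#' @param seed master seed; all per-subject and per-assessment seeds derive
#'   from it by stable hashing.
#' @return a list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_transition = 14L, n_control = 14L, days = 120L,
                        beats_mean = 350, beats_sd = 40,
                        missingness = 0.1,
                        transition_week_range = c(5L, 14L),
                        mean_ibi_targets = list(
                          transition_morning = c(852, 71.5),
                          transition_evening = c(853, 51.1),
                          control_morning = c(798, 30.4),
                          control_evening = c(837, 28.2)),
                        sdrr_targets = list(
                          transition_morning = c(54.7, 9.0),
                          transition_evening = c(45.5, 8.4),
                          control_morning = c(58.8, 4.9),
                          control_evening = c(43.7, 4.9)),
                        complexity = list(transition = c(0.30, 0.07),
                                          control = c(0.46, 0.07)),
                        fast_fraction = list(transition = c(0.25, 0.12),
                                             control = c(0.10, 0.12)),
                        trend_slope = 0,
                        symptom_base = 10, symptom_noise_sd = 2,
                        symptom_step = 10,
                        seed = 1L) {
  stopifnot(n_transition >= 1, n_control >= 1, days >= 7,
            missingness >= 0, missingness < 1, beats_mean > 50)
  structure(as.list(environment()), class = "cohort_spec")
}

subject_latents <- function(spec, sid, group) {
  with_seed(derive_seed(spec$seed, paste0("latent_", sid)), {
    cl <- spec$complexity[[group]]
    ff <- spec$fast_fraction[[group]]
    lat <- list(
      complexity = min(max(stats::rnorm(1, cl[1], cl[2]), 0.02), 0.98),
      fast_fraction = min(max(stats::rnorm(1, ff[1], ff[2]), 0), 0.9),
      mean_ibi = sapply(c("morning", "evening"), function(sess) {
        tg <- spec$mean_ibi_targets[[paste0(group, "_", sess)]]
        min(max(stats::rnorm(1, tg[1], tg[2]), 550), 1150)
      }),
      sdrr = sapply(c("morning", "evening"), function(sess) {
        tg <- spec$sdrr_targets[[paste0(group, "_", sess)]]
        max(stats::rnorm(1, tg[1], tg[2]), 5)
      }),
      transition_week = if (group == "transition") {
        sample(spec$transition_week_range[1]:spec$transition_week_range[2], 1)
      } else NA_integer_
    )
    lat
  })
}

#' Simulate a synthetic cohort
#'
#' Generates the full cohort implied by a [cohort_spec()]: per subject,
#' twice-daily IBI assessments with missing-completely-at-random dropout,
#' a weekly symptom series (with the sustained step for transitioning
#' subjects), and a ground-truth table recording every latent parameter.
#' All randomness derives from the master seed by stable per-subject /
#' per-assessment hashing, so adding a subject never reshuffles the others.
#'
#' @param spec a [cohort_spec()].
#' @param out_dir optional directory; when given, IBI files, symptom files,
#'   `manifest.csv`, `truth.csv` and `spec.json` are written in the formats
#'   [read_ibi_file()] / [read_symptom_file()] / [read_manifest()] read.
#' @param assessment_days optional integer vector restricting which study
#'   days get IBI assessments (e.g. `0:27` to generate only the baseline
#'   window); symptoms always cover the whole study.
#' @param sessions sessions to generate (default both). Per-assessment seeds
#'   are keyed by subject, day and session, so restricting days or sessions
#'   never changes the series generated for the remaining assessments.
#' @return a list of class `ibi_cohort`: `subjects` (per subject: list of
#'   `ibi_series`, a `symptom_series`, group, latents), `truth` (tibble),
#'   `manifest` (tibble, paths filled only when written), `spec`.
#' @export
simulate_cohort <- function(spec = cohort_spec(), out_dir = NULL,
                            assessment_days = NULL,
                            sessions = c("morning", "evening")) {
  ids <- c(sprintf("t%02d", seq_len(spec$n_transition)),
           sprintf("c%02d", seq_len(spec$n_control)))
  groups <- rep(c("transition", "control"),
                c(spec$n_transition, spec$n_control))
  n_weeks <- ceiling(spec$days / 7) + 3L
  days_use <- assessment_days %||% (0:(spec$days - 1L))
  subjects <- list()
  truth <- list()
  manifest <- list()
  for (i in seq_along(ids)) {
    sid <- ids[i]; group <- groups[i]
    lat <- subject_latents(spec, sid, group)
    series <- list()
    for (day in days_use) {
      for (sess in sessions) {
        tag <- paste0(sid, "_", day, "_", sess)
        aseed <- derive_seed(spec$seed, tag)
        miss <- with_seed(derive_seed(spec$seed, paste0("miss_", tag)),
                          stats::runif(1)) < spec$missingness
        if (miss) next
        nb <- with_seed(derive_seed(spec$seed, paste0("nb_", tag)),
                        max(120L, round(stats::rnorm(1, spec$beats_mean,
                                                     spec$beats_sd))))
        cl <- lat$complexity
        if (group == "transition" && spec$trend_slope != 0 &&
            !is.na(lat$transition_week)) {
          # drift toward the transition: slope per day, anchored at transition
          dt <- day - 7 * lat$transition_week
          cl <- min(max(cl + spec$trend_slope * dt, 0.02), 0.98)
        }
        x <- simulate_ibi_assessment(lat$mean_ibi[[sess]], lat$sdrr[[sess]],
                                     cl, n_beats = nb, seed = aseed,
                                     fast_fraction = lat$fast_fraction)
        series[[tag]] <- structure(
          list(subject_id = sid, day_index = as.integer(day), session = sess,
               intervals = x), class = "ibi_series")
        manifest[[length(manifest) + 1]] <- list(
          subject_id = sid, ibi_path = paste0(tag, ".csv"),
          day_index = as.integer(day), session = sess, group = group,
          symptom_path = paste0(sid, "_scl90.csv"))
      }
    }
    symptoms <- simulate_symptoms(
      n_weeks, base = spec$symptom_base, noise_sd = spec$symptom_noise_sd,
      transition_week = lat$transition_week, step = spec$symptom_step,
      seed = derive_seed(spec$seed, paste0("sym_", sid)), subject_id = sid)
    subjects[[sid]] <- list(subject_id = sid, group = group,
                            ibi = series, symptoms = symptoms, latents = lat)
    truth[[i]] <- list(
      subject_id = sid, group = group,
      transition_week = lat$transition_week,
      complexity = lat$complexity,
      fast_fraction = lat$fast_fraction,
      mean_ibi_morning = lat$mean_ibi[["morning"]],
      mean_ibi_evening = lat$mean_ibi[["evening"]],
      sdrr_morning = lat$sdrr[["morning"]],
      sdrr_evening = lat$sdrr[["evening"]],
      seed = derive_seed(spec$seed, paste0("latent_", sid)))
  }
  cohort <- structure(list(subjects = subjects,
                           truth = bind_rows_list(truth),
                           manifest = bind_rows_list(manifest),
                           spec = spec),
                      class = "ibi_cohort")
  if (!is.null(out_dir)) write_cohort(cohort, out_dir)
  cohort
}

#' @export
print.ibi_cohort <- function(x, ...) {
  n_ass <- sum(vapply(x$subjects, function(s) length(s$ibi), numeric(1)))
  cat(sprintf("<ibi_cohort> %d subjects (%d transition / %d control), %d assessments\n",
              length(x$subjects), sum(x$truth$group == "transition"),
              sum(x$truth$group == "control"), n_ass))
  invisible(x)
}

#' Write a simulated cohort to disk
#'
#' Materializes the cohort in the plain-text formats the readers consume:
#' one CSV per assessment, one symptom CSV per subject, `manifest.csv`,
#' `truth.csv` and `spec.json`.
#'
#' @param cohort an `ibi_cohort`.
#' @param out_dir output directory (created).
#' @return `out_dir`, invisibly.
#' @export
write_cohort <- function(cohort, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  for (s in cohort$subjects) {
    for (ser in s$ibi) write_ibi_file(ser, out_dir)
    write_symptom_file(s$symptoms, out_dir)
  }
  utils::write.csv(as.data.frame(cohort$manifest),
                   file.path(out_dir, "manifest.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(cohort$truth),
                   file.path(out_dir, "truth.csv"), row.names = FALSE)
  sp <- cohort$spec
  jsonlite::write_json(sp[setdiff(names(sp), character(0))],
                       file.path(out_dir, "spec.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(out_dir)
}

#' Per-assessment quantifiers for a whole cohort
#'
#' Runs [compute_quantifiers()] over every assessment of a simulated (or
#' loaded) cohort, optionally restricted to a day range.
#'
#' @param cohort an `ibi_cohort`.
#' @param config a [complexity_config()].
#' @param day_range optional `c(first, last)` day filter (inclusive).
#' @param sessions sessions to include (default both).
#' @return tibble with one row per assessment.
#' @export
cohort_quantifiers <- function(cohort, config = complexity_config(),
                               day_range = NULL,
                               sessions = c("morning", "evening")) {
  rows <- list()
  for (s in cohort$subjects) {
    for (ser in s$ibi) {
      if (!is.null(day_range) &&
          (ser$day_index < day_range[1] || ser$day_index > day_range[2])) next
      if (!ser$session %in% sessions) next
      rows[[length(rows) + 1]] <- quantifier_row(ser, config)
    }
  }
  bind_rows_list(rows)
}

#' Label every subject of a cohort from its symptom series
#'
#' Applies [detect_transition()] per subject and pair-matches pseudo-
#' transition weeks onto the non-transitioning subjects with
#' [assign_pseudo_transitions()].
#'
#' @param cohort an `ibi_cohort`.
#' @param ... passed to [detect_transition()].
#' @return tibble: `subject_id`, `group`, `transitioned`, `anchor_week`,
#'   `pseudo`.
#' @export
label_cohort <- function(cohort, ...) {
  labs <- lapply(cohort$subjects, function(s) detect_transition(s$symptoms, ...))
  transitioned <- vapply(labs, function(l) isTRUE(l$transitioned), logical(1))
  ids <- names(labs)
  out <- tibble::tibble(
    subject_id = ids,
    group = vapply(cohort$subjects, function(s) s$group, character(1)),
    transitioned = transitioned,
    anchor_week = vapply(labs, function(l)
      as.integer(l$transition_week %||% NA_integer_), integer(1)),
    pseudo = FALSE)
  if (any(transitioned) && any(!transitioned)) {
    tw <- stats::setNames(out$anchor_week[transitioned], ids[transitioned])
    last_wk <- vapply(cohort$subjects[!transitioned],
                      function(s) max(s$symptoms$week_index), integer(1))
    ps <- assign_pseudo_transitions(tw, ids[!transitioned], last_wk)
    m <- match(ps$subject_id, out$subject_id)
    out$anchor_week[m] <- ps$pseudo_week
    out$pseudo[m] <- TRUE
  }
  out
}
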