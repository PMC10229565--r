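sym <- function(scores, weeks = seq_along(scores) - 1L, id = "s01") {
  symptom_series(weeks, scores, subject_id = id)
}

test_that("the transition rule needs both the 8.5-point rise and persistence", {
  # sustained step of +10 from week 4: transition at week 4
  tl <- detect_transition(sym(c(10, 10, 10, 10, 20, 20, 20, 20)))
  expect_true(tl$transitioned)
  expect_equal(tl$transition_week, 4L)
  expect_true(tl$criteria[["persistence"]])

  # 2-week elevation only: no transition without the clinical override
  tl <- detect_transition(sym(c(10, 10, 10, 10, 20, 20, 10, 10)))
  expect_false(tl$transitioned)
  tl <- detect_transition(sym(c(10, 10, 10, 10, 20, 20, 10, 10)),
                          override = TRUE)
  expect_true(tl$transitioned)
  expect_equal(tl$transition_week, 4L)

  # +8 rise misses the 8.5-point criterion
  tl <- detect_transition(sym(c(10, 10, 10, 10, 18, 18, 18, 18)))
  expect_false(tl$transitioned)
  expect_false(tl$criteria[["increase"]])
})

test_that("missing weeks break the persistence run", {
  # weeks 4,5,6 elevated but week 5 unobserved: runs of 1 and 2 only
  tl <- detect_transition(sym(c(10, 10, 10, 10, 20, 20, 20),
                              weeks = c(0, 1, 2, 3, 4, 6, 7)))
  expect_false(tl$transitioned)
  # same scores fully observed: transition
  tl <- detect_transition(sym(c(10, 10, 10, 10, 20, 20, 20)))
  expect_true(tl$transitioned)
})

test_that("too-short series are unlabelable with a reason", {
  tl <- detect_transition(sym(c(10, 12, 11)))
  expect_true(is.na(tl$transitioned))
  expect_match(tl$reason, "fewer_than_4")
})

test_that("raising the threshold never creates a transition", {
  set.seed(61)
  for (i in 1:25) {
    scores <- pmax(0, 12 + cumsum(rnorm(16, 0.3, 3)))
    lo <- detect_transition(sym(scores), threshold = 8.5)
    hi <- detect_transition(sym(scores), threshold = 10.5)
    if (isTRUE(hi$transitioned)) {
      expect_true(isTRUE(lo$transitioned))
      # and the stricter criterion can only date it later
      expect_gte(hi$transition_week, lo$transition_week)
    }
  }
})

test_that("pseudo-transition weeks are pair-matched, capped and cycled", {
  m <- assign_pseudo_transitions(c(s2 = 12L, s1 = 8L), c("c2", "c1"),
                                 c(c1 = 20L, c2 = 10L))
  # sorted by id on both sides: c1 <- s1 (8), c2 <- s2 (12, capped at 10)
  expect_equal(m$subject_id, c("c1", "c2"))
  expect_equal(m$pseudo_week, c(8L, 10L))
  expect_equal(m$source_subject, c("s1", "s2"))
  expect_equal(m$capped, c(FALSE, TRUE))

  # shorter transition list cycles
  m <- assign_pseudo_transitions(c(s1 = 8L), c("c1", "c2", "c3"),
                                 c(c1 = 20L, c2 = 20L, c3 = 20L))
  expect_equal(m$pseudo_week, c(8L, 8L, 8L))
  expect_equal(m$cycled, c(FALSE, TRUE, TRUE))

  # deterministic: identical inputs, identical mapping
  m1 <- assign_pseudo_transitions(c(s2 = 12L, s1 = 8L), c("c2", "c1"),
                                  c(c1 = 20L, c2 = 10L))
  m2 <- assign_pseudo_transitions(c(s2 = 12L, s1 = 8L), c("c2", "c1"),
                                  c(c1 = 20L, c2 = 10L))
  expect_identical(m1, m2)
  expect_error(assign_pseudo_transitions(integer(0), "c1", c(c1 = 5L)),
               "no transition weeks")
})

test_that("window extraction follows the half-open day arithmetic", {
  ass <- tibble::tibble(day_index = 0:120, session = "morning",
                        usable = TRUE)
  w <- extract_window(ass, anchor_week = 10, kind = "pretransition")
  expect_equal(range(w$data$day_index), c(14, 69))
  expect_equal(w$interval, c(14, 70))
  expect_true(w$sufficient)

  # anchor at week 5: truncated at day 0, 5 weeks of data, sufficient
  w <- extract_window(ass, anchor_week = 5, kind = "pretransition")
  expect_equal(w$interval, c(0, 35))
  expect_true(w$sufficient)

  # baseline window is the first 4 weeks
  w <- extract_window(ass, kind = "baseline")
  expect_equal(range(w$data$day_index), c(0, 27))
})

test_that("windows flag spans shorter than 3 weeks as insufficient", {
  ass <- tibble::tibble(day_index = c(0:20), session = "morning",
                        usable = TRUE)  # weeks 0-2 only
  w <- extract_window(ass, kind = "baseline")
  expect_false(w$sufficient)
  # days 0 and 21 span exactly 3 weeks
  ass <- tibble::tibble(day_index = c(0L, 21L), session = "morning",
                        usable = TRUE)
  expect_true(extract_window(ass, kind = "baseline")$sufficient)
})

test_that("window extraction never leaks assessments or drops sessions", {
  set.seed(67)
  for (i in 1:10) {
    days <- sort(sample(0:119, 60))
    ass <- tibble::tibble(day_index = days,
                          session = sample(c("morning", "evening"), 60,
                                           replace = TRUE),
                          usable = TRUE)
    anchor <- sample(5:14, 1)
    w <- extract_window(ass, anchor_week = anchor, kind = "pretransition")
    expect_true(all(w$data$day_index >= w$interval[1] &
                      w$data$day_index < w$interval[2]))
    inside <- ass$day_index >= w$interval[1] & ass$day_index < w$interval[2]
    expect_identical(w$data$session, ass$session[inside])
  }
})
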