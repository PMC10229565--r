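make_series <- function(x, ...) ibi_series(x, "s01", 0L, "morning")

test_that("quality filter applies the length and range rules", {
  cfg <- complexity_config()
  ok <- make_series(runif(350, 700, 900))
  expect_true(ibi_quality_filter(ok, cfg)$usable)
  expect_identical(ibi_quality_filter(ok, cfg)$series$intervals, ok$intervals)

  short <- make_series(runif(50, 700, 900))
  q <- ibi_quality_filter(short, cfg)
  expect_false(q$usable)
  expect_match(q$reasons, "too_short", all = FALSE)

  x <- runif(300, 700, 900); x[1:30] <- 50
  q <- ibi_quality_filter(make_series(x), cfg)
  expect_false(q$usable)
  expect_match(q$reasons, "out_of_range", all = FALSE)
  expect_equal(q$flagged, 1:30)
  # flagged but under the 5% budget: still usable
  x <- runif(300, 700, 900); x[1:10] <- 250
  expect_true(ibi_quality_filter(make_series(x), cfg)$usable)
})

test_that("mean and SDRR match closed forms and a naive oracle", {
  expect_equal(mean_ibi(c(800, 800, 800)), 800)
  expect_equal(mean_ibi(c(700, 900)), 800)
  expect_equal(sdrr(c(790, 790, 790)), 0)
  expect_equal(sdrr(c(790, 810)), sqrt(((790 - 800)^2 + (810 - 800)^2) / 1))
  expect_equal(round(sdrr(c(790, 810)), 3), 14.142)

  set.seed(7)
  x <- rnorm(1000, 800, 50)
  naive_mean <- sum(x) / length(x)
  naive_var <- sum((x - naive_mean)^2) / (length(x) - 1)  # two-pass
  expect_equal(mean_ibi(x), naive_mean, tolerance = 1e-9)
  expect_equal(sdrr(x), sqrt(naive_var), tolerance = 1e-9)
})

test_that("Higuchi dimension matches the literal curve-length formula", {
  set.seed(11)
  for (i in 1:5) {
    x <- rnorm(200 + 30 * i)
    expect_equal(higuchi_dimension(x, kmax = 5), higuchi_brute(x, 5),
                 tolerance = 1e-12)
  }
})

test_that("Higuchi dimension hits its analytic anchors", {
  expect_equal(higuchi_dimension(1:1000), 1, tolerance = 0.01)
  set.seed(3)
  d_noise <- mean(replicate(20, higuchi_dimension(rnorm(1000))))
  expect_equal(d_noise, 2, tolerance = 0.1)
  expect_error(higuchi_dimension(1:4, kmax = 5), "shorter")
  # constant series: zero curve lengths, degenerate log fit
  expect_true(is.na(higuchi_dimension(rep(5, 100))))
})

test_that("Higuchi dimension is affine-invariant", {
  set.seed(5)
  x <- rnorm(500)
  d0 <- higuchi_dimension(x)
  expect_equal(higuchi_dimension(3.7 * x - 120), d0, tolerance = 1e-9)
  expect_equal(higuchi_dimension(-0.2 * x + 9), d0, tolerance = 1e-9)
})

test_that("coarse-graining takes non-overlapping window means", {
  expect_equal(coarse_grain(c(1, 2, 3, 4, 5, 6), 2), c(1.5, 3.5, 5.5))
  expect_equal(coarse_grain(c(1, 2, 3, 4, 5, 6, 7), 3), c(2, 5))
  x <- rnorm(37)
  expect_identical(coarse_grain(x, 1), x)
  expect_error(coarse_grain(x, 38), "exceeds")
})

test_that("sample entropy handles degenerate and periodic series", {
  expect_equal(as.numeric(sample_entropy(rep(700, 120), 2, 1)), 0)
  alt <- rep(c(1, 0), 25) * 100 + 700
  expect_equal(as.numeric(sample_entropy(alt, 2, 0.2 * 100)), 0)
  expect_error(sample_entropy(c(1, 2, 3), 2, 0.5), "too short")
  expect_error(sample_entropy(rnorm(50), 2, -1), "positive")
})

test_that("sample entropy equals brute-force template counting", {
  set.seed(13)
  for (i in 1:6) {
    x <- rnorm(60)
    r <- 0.2 * sd(x)
    got <- sample_entropy(x, 2, r)
    want <- sampen_brute(x, 2, r)
    expect_identical(attr(got, "A"), as.numeric(want$A))
    expect_identical(attr(got, "B"), as.numeric(want$B))
    expect_equal(as.numeric(got), want$sampen)
  }
})

test_that("sample entropy is shift-invariant and jointly scale-invariant", {
  set.seed(17)
  x <- rnorm(150)
  r <- 0.25 * sd(x)
  s0 <- as.numeric(sample_entropy(x, 2, r))
  expect_equal(as.numeric(sample_entropy(x + 1000, 2, r)), s0)
  expect_equal(as.numeric(sample_entropy(50 * x, 2, 50 * r)), s0)
})

test_that("multiscale entropy composes coarse_grain and sample_entropy", {
  set.seed(19)
  x <- rnorm(350, 800, 50)
  cfg <- complexity_config()
  ms <- multiscale_entropy(x, cfg)
  r_abs <- cfg$r_factor * sd(x)
  per <- sapply(1:5, function(sc)
    as.numeric(sample_entropy(coarse_grain(x, sc), 2, r_abs)))
  expect_equal(attr(ms, "per_scale"), per)
  expect_equal(as.numeric(ms), mean(per[is.finite(per)]))
  # a constant series is maximally predictable at every scale
  expect_equal(as.numeric(multiscale_entropy(rep(800, 350))), 0)
})

test_that("multiscale entropy at max_scale 1 reduces to raw sample entropy", {
  set.seed(23)
  x <- rnorm(200, 800, 40)
  cfg <- complexity_config(max_scale = 1)
  expect_equal(as.numeric(multiscale_entropy(x, cfg)),
               as.numeric(sample_entropy(x, 2, 0.2 * sd(x))))
})

test_that("white noise carries more multiscale entropy than a sine", {
  cfg <- complexity_config()
  for (s in 1:10) {
    set.seed(s)
    noise <- rnorm(400, 800, 50)
    sine <- 800 + 50 * sin(2 * pi * (1:400) / 20 + runif(1, 0, 2 * pi))
    expect_gt(as.numeric(multiscale_entropy(noise, cfg)),
              as.numeric(multiscale_entropy(sine, cfg)))
  }
})

test_that("the scale cap follows the coarse-grained length rule", {
  # 350 beats, m = 2: floor(350 / 5) = 70 >= 30 -> full 5 scales
  set.seed(29)
  expect_length(attr(multiscale_entropy(rnorm(350, 800, 50)), "per_scale"), 5)
  # 120 beats: scale 4 keeps 30 points, scale 5 only 24 -> capped at 4
  expect_length(attr(multiscale_entropy(rnorm(120, 800, 50)), "per_scale"), 4)
})

test_that("compute_quantifiers composes the individual operations", {
  set.seed(31)
  x <- 800 + 50 * fgn(350, 0.4)
  s <- make_series(x)
  row <- compute_quantifiers(s)
  expect_true(row$usable)
  expect_equal(row$mean_ibi, mean_ibi(x))
  expect_equal(row$sdrr, sdrr(x))
  expect_equal(row$higuchi_dim, as.numeric(higuchi_dimension(x, 5)))
  expect_equal(row$mse, as.numeric(multiscale_entropy(x)))
  expect_identical(row$subject_id, "s01")

  # deterministic: identical input, identical output
  expect_identical(compute_quantifiers(s), row)
})

test_that("constant and unusable series yield flagged rows", {
  const <- make_series(rep(800, 350))
  row <- compute_quantifiers(const)
  expect_true(row$usable)
  expect_equal(row$mean_ibi, 800)
  expect_equal(row$sdrr, 0)
  expect_equal(row$mse, 0)
  expect_true(is.na(row$higuchi_dim))  # degenerate log-log fit

  short <- make_series(runif(40, 700, 900))
  row <- compute_quantifiers(short)
  expect_false(row$usable)
  expect_true(all(is.na(c(row$mean_ibi, row$sdrr, row$higuchi_dim, row$mse))))
})

test_that("configuration files load from JSON and key=value formats", {
  dir <- withr::local_tempdir()
  j <- file.path(dir, "cfg.json")
  writeLines('{"kmax": 4, "r_factor": 0.15}', j)
  cfg <- read_complexity_config(j)
  expect_equal(cfg$kmax, 4L)
  expect_equal(cfg$r_factor, 0.15)
  expect_equal(cfg$m, 2L)            # unspecified keys keep defaults

  k <- file.path(dir, "cfg.txt")
  writeLines(c("kmax = 6", "min_beats = 150"), k)
  cfg <- read_complexity_config(k)
  expect_equal(cfg$kmax, 6L)
  expect_equal(cfg$min_beats, 150L)

  writeLines("kmaxx = 6", k)
  expect_error(read_complexity_config(k), "unknown configuration key")
})
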