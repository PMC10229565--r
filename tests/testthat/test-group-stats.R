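test_that("person averages are idempotent and skip unusable rows", {
  w <- tibble::tibble(
    subject_id = "s01", day_index = rep(0:3, each = 2),
    session = rep(c("morning", "evening"), 4),
    usable = c(TRUE, TRUE, TRUE, TRUE, FALSE, TRUE, TRUE, TRUE),
    mean_ibi = c(800, 820, 802, 818, 9999, 822, 804, 824),
    sdrr = 50, higuchi_dim = 1.6, mse = 1.5)
  pa <- person_average(w)
  m <- pa[pa$session == "morning", ]
  expect_equal(m$n_assessments, 3L)          # the unusable row is excluded
  expect_equal(m$mean_ibi, mean(c(800, 802, 804)))
  e <- pa[pa$session == "evening", ]
  expect_equal(e$mean_ibi, mean(c(820, 818, 822, 824)))

  # averaging identical values reproduces them
  w2 <- w[w$usable & w$session == "morning", ]
  w2$mean_ibi <- 808
  expect_equal(person_average(w2)$mean_ibi, 808)

  expect_error(person_average(w[!w$usable, ]), "no usable")
})

test_that("Mann-Whitney matches exact enumeration on small groups", {
  mw <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(mw$U, 0)
  expect_equal(mw$p_value, 0.1)              # 2/20 assignments as extreme
  expect_equal(mw$p_value, mw_enum_p(c(1, 2, 3), c(4, 5, 6)))

  set.seed(79)
  a <- rnorm(4); b <- rnorm(5) + 0.5
  expect_equal(mann_whitney(a, b)$p_value, mw_enum_p(a, b))
})

test_that("Mann-Whitney symmetry and degenerate behaviour", {
  set.seed(83)
  a <- rnorm(6); b <- rnorm(7)
  m1 <- mann_whitney(a, b); m2 <- mann_whitney(b, a)
  expect_equal(m1$U, length(a) * length(b) - m2$U)
  expect_equal(m1$p_value, m2$p_value)
  expect_equal(m1$z, -m2$z)

  ident <- mann_whitney(c(1, 2, 3), c(1, 2, 3))
  expect_equal(ident$z, 0)
  expect_equal(ident$p_value, 1)
})

test_that("normal-approximation p agrees with the exact p for n 8-20", {
  set.seed(89)
  for (n in c(8, 12, 20)) {
    for (i in 1:4) {
      a <- rnorm(n); b <- rnorm(n) + runif(1, -0.8, 0.8)
      exact <- wilcox.test(a, b, exact = TRUE)$p.value
      approx <- mann_whitney(a, b)$p_value
      if (n == 8) approx <- {     # force the normal branch for comparison
        r <- rank(c(a, b)); U <- sum(r[1:n]) - n * (n + 1) / 2
        mu <- n * n / 2; sig <- sqrt(n * n * (2 * n + 1) / 12)
        2 * pnorm(-abs(U - mu + 0.5 * sign(mu - U)) / sig)
      }
      expect_lt(abs(exact - approx), 0.02)
    }
  }
})

test_that("Cohen's d reproduces the published mean-IBI effect sizes", {
  expect_equal(cohens_d(852.161, 71.537, 14, 797.921, 30.415, 14), 0.987,
               tolerance = 0.005)
  expect_equal(cohens_d(853.034, 51.104, 14, 837.026, 28.159, 14), 0.388,
               tolerance = 0.005)
  expect_equal(cohens_d(5, 1, 10, 5, 2, 10), 0)
  expect_equal(cohens_d(7, 1, 10, 5, 1, 10), -cohens_d(5, 1, 10, 7, 1, 10))
})

test_that("Spearman table is rank-invariant and matches a rank oracle", {
  set.seed(97)
  df <- tibble::tibble(a = rnorm(5), b = rnorm(5), c = rnorm(5))
  sm <- spearman_matrix(df)
  self <- sm[sm$var1 == "a" & sm$var2 == "a", ]
  expect_equal(self$rho, 1)

  ab <- sm[sm$var1 == "b" & sm$var2 == "a", ]
  oracle <- cor(rank(df$a), rank(df$b))      # rank-then-Pearson
  expect_equal(ab$rho, oracle)

  df2 <- df; df2$a <- exp(3 * df$a)          # strictly monotone transform
  sm2 <- spearman_matrix(df2)
  expect_equal(sm2$rho, sm$rho)

  dfc <- df; dfc$c <- 1
  smc <- spearman_matrix(dfc)
  expect_true(is.na(smc$rho[smc$var1 == "c" & smc$var2 == "a"]))
})

test_that("logistic fit recovers the null when the predictor is noise", {
  set.seed(101)
  y <- rep(0:1, each = 100)
  x <- rnorm(200)
  fit <- fit_logistic(y, data.frame(x = x))
  expect_lt(fit$nagelkerke_r2, 0.05)
  expect_false(fit$separation)
  expect_gt(fit$coefficients$p_value[2], 0.01)
})

test_that("logistic log-likelihood is the global optimum (grid oracle)", {
  y <- c(0, 0, 0, 1, 1, 1)
  x <- c(-1.2, 0.3, -0.5, 0.8, 1.5, 0.1)
  fit <- fit_logistic(y, data.frame(x = x))
  xs <- (x - mean(x)) / sd(x)
  ll <- function(b0, b1) {
    eta <- b0 + b1 * xs
    sum(y * eta - log(1 + exp(eta)))
  }
  grid <- expand.grid(b0 = seq(-4, 4, 0.05), b1 = seq(-1, 8, 0.05))
  best <- max(mapply(ll, grid$b0, grid$b1))
  expect_gte(fit$loglik + 1e-4, best)
  # Nagelkerke identities: null likelihood gives R2 = 0
  n <- length(y)
  r2 <- (1 - exp(2 / n * (fit$loglik_null - fit$loglik_null))) /
    (1 - exp(2 / n * fit$loglik_null))
  expect_equal(r2, 0)
})

test_that("separation is diagnosed, not crashed on", {
  y <- rep(c(0, 1), each = 6)
  x <- c(rnorm(6, -3, 0.2), rnorm(6, 3, 0.2))
  fit <- suppressWarnings(fit_logistic(y, data.frame(x = x)))
  expect_true(fit$separation)
  expect_false(fit$converged)
  expect_equal(fit$pct_correct, 100)
})

test_that("threshold grid search maximizes correct classification", {
  gs <- grid_search_threshold(c(1, 2, 3), c(TRUE, TRUE, FALSE))
  expect_equal(gs$threshold, 2.5)
  expect_equal(gs$n_correct, 3L)

  # interleaved values: compare against brute force over all midpoints
  set.seed(103)
  v <- rnorm(20); lab <- rep(c(TRUE, FALSE), 10)
  gs <- grid_search_threshold(v, lab)
  u <- sort(unique(v)); mids <- (u[-1] + u[-length(u)]) / 2
  brute <- max(sapply(mids, function(th) sum((v < th) == lab)))
  expect_equal(gs$n_correct, brute)

  # degenerate: all values equal -> majority class
  gs <- grid_search_threshold(rep(1.5, 5), c(TRUE, TRUE, TRUE, FALSE, FALSE))
  expect_true(is.na(gs$threshold))
  expect_equal(gs$n_correct, 3L)
})
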