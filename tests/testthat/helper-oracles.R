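# Independent oracles used across the suite. These deliberately use the
# slowest, most literal formulation of each definition so they stay
# independent of the package's optimized code paths.

# O(N^2) brute-force sample entropy by explicit template enumeration
sampen_brute <- function(x, m, r) {
  n <- length(x)
  nt <- n - m
  A <- 0L; B <- 0L
  for (i in seq_len(nt - 1)) {
    for (j in (i + 1):nt) {
      dm <- max(abs(x[i:(i + m - 1)] - x[j:(j + m - 1)]))
      if (dm <= r) {
        B <- B + 1L
        if (max(dm, abs(x[i + m] - x[j + m])) <= r) A <- A + 1L
      }
    }
  }
  list(A = A, B = B,
       sampen = if (B == 0) NA_real_ else if (A == 0) Inf else -log(A / B))
}

# Literal Higuchi curve-length implementation (plain loops, lm fit)
higuchi_brute <- function(x, kmax) {
  n <- length(x)
  lk <- numeric(kmax)
  for (k in 1:kmax) {
    lengths_m <- numeric(k)
    for (m in 1:k) {
      imax <- floor((n - m) / k)
      tot <- 0
      for (i in 1:imax) tot <- tot + abs(x[m + i * k] - x[m + (i - 1) * k])
      lengths_m[m] <- (tot * (n - 1) / (imax * k)) / k
    }
    lk[k] <- mean(lengths_m)
  }
  fit <- stats::lm(log(lk) ~ log(1:kmax))
  -unname(stats::coef(fit)[2])
}

# Kendall tau and exact two-sided p by full permutation enumeration
kendall_enum <- function(values, times) {
  n <- length(values)
  s_of <- function(v) {
    s <- 0
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      s <- s + sign(v[j] - v[i]) * sign(times[j] - times[i])
    }
    s
  }
  s_obs <- s_of(values)
  perms <- perm_all(values)
  s_all <- apply(perms, 1, s_of)
  n_pairs <- n * (n - 1) / 2
  list(tau = s_obs / n_pairs,
       p = mean(abs(s_all) >= abs(s_obs) - 1e-12))
}

perm_all <- function(v) {
  n <- length(v)
  if (n == 1) return(matrix(v, 1, 1))
  out <- NULL
  for (i in seq_len(n)) {
    rest <- perm_all(v[-i])
    out <- rbind(out, cbind(v[i], rest))
  }
  out
}

# Exact two-sided Mann-Whitney p by enumerating all group assignments
mw_enum_p <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  pooled <- c(a, b)
  u_of <- function(idx) {
    r <- rank(pooled)
    sum(r[idx]) - n1 * (n1 + 1) / 2
  }
  u_obs <- u_of(seq_len(n1))
  combs <- utils::combn(n1 + n2, n1)
  u_all <- apply(combs, 2, u_of)
  mu <- n1 * n2 / 2
  mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-12)
}

# periodogram by direct DFT (no FFT library call in the check itself)
periodogram_direct <- function(x) {
  n <- length(x)
  freqs <- seq_len(floor(n / 2))
  vapply(freqs, function(k) {
    w <- 2 * pi * k * (0:(n - 1)) / n
    (sum(x * cos(w))^2 + sum(x * sin(w))^2) / n
  }, numeric(1))
}

# total periodogram power per octave band (bins 1, 2-3, 4-7, ...); a
# trailing partial octave is merged into the last full band so no band is a
# lone high-frequency bin with negligible power
octave_power <- function(x) {
  p <- periodogram_direct(x)
  n <- length(p)
  lo <- 1
  out <- c()
  while (lo <= n) {
    hi <- 2 * lo - 1
    if (2 * hi + 1 > n) hi <- n   # absorb the remainder
    out <- c(out, sum(p[lo:hi]))
    lo <- hi + 1
  }
  out
}

# small helper: quantifier tibble for a list of series without the cohort
quantify_list <- function(series_list, config = complexity_config()) {
  do.call(rbind, lapply(series_list, compute_quantifiers, config = config))
}
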