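#' @useDynLib hrvtrans, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats sd fft rnorm runif cor pnorm wilcox.test glm binomial
#'   coef vcov logLik cor.test complete.cases
#' @importFrom utils write.csv read.csv
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so seeded internals never disturb the
#' caller's RNG stream. With `seed = NULL` the expression runs on the current
#' stream.
#' @noRd
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Stable 31-bit hash of a seed plus a string tag
#'
#' Used to derive per-subject and per-assessment seeds from a master seed so
#' that adding a subject to a cohort never reshuffles the draws of the others.
#' Polynomial rolling hash mod (2^31 - 1), deterministic across platforms.
#' @noRd
derive_seed <- function(seed, tag) {
  mod <- 2147483647
  h <- as.numeric(seed %% mod)
  for (code in utf8ToInt(as.character(tag))) {
    h <- (h * 131 + code) %% mod
  }
  as.integer(h)
}

# least-squares slope of y on x (closed form, no lm overhead)
ls_slope <- function(x, y) {
  xm <- mean(x); ym <- mean(y)
  sum((x - xm) * (y - ym)) / sum((x - xm)^2)
}

# rbind a list of same-shaped plain lists into one tibble
bind_rows_list <- function(rows) {
  if (length(rows) == 0) return(tibble::tibble())
  nm <- names(rows[[1]])
  cols <- lapply(nm, function(f) unlist(lapply(rows, `[[`, f), use.names = FALSE))
  names(cols) <- nm
  tibble::as_tibble(cols)
}
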