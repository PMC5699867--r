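## Internal helpers shared across modules.

stopf <- function(...) stop(sprintf(...), call. = FALSE)

warnf <- function(...) warning(sprintf(...), call. = FALSE)

## Evaluate `expr` under a fixed RNG seed without disturbing the caller's RNG
## stream. seed = NULL leaves the stream untouched.
withSeed <- function(seed, expr) {
  if (is.null(seed) || is.na(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  expr
}

## Derive a stream of child seeds (< 2^31) from one integer seed.
childSeeds <- function(seed, n) {
  withSeed(seed, sample.int(.Machine$integer.max, n))
}

## Two-sample Kolmogorov-Smirnov D without the p-value machinery (fast path
## for large vectors; ties handled as in the classical definition).
ksStatistic <- function(x, y) {
  n.x <- length(x); n.y <- length(y)
  w <- c(x, y)
  z <- cumsum(ifelse(order(w) <= n.x, 1 / n.x, -1 / n.y))
  w.s <- sort(w)
  keep <- c(diff(w.s) != 0, TRUE)
  max(abs(z[keep]))
}

## K-S distance between an empirical sample and a binned distribution,
## evaluated at bin edges (the binned CDF is exact there).
ksToBinned <- function(x, dme) {
  edges <- binEdges(expressionGridOf(dme))
  cdf <- c(0, cumsum(probabilities(dme)))
  emp <- ecdf(x)(edges)
  max(abs(emp - cdf))
}

## Draw per-cell log10 fluorescence around true log10 levels with constant
## CV on the linear scale (log-normal, centred so the log10 mean is the true
## level, i.e. the true level is the geometric mean of the cells).
drawLog10Cells <- function(trueLog10Mean, cv) {
  sdlog <- sqrt(log1p(cv^2))
  rlnorm(length(trueLog10Mean), meanlog = log(10) * trueLog10Mean,
         sdlog = sdlog) |> log10()
}

## Validated three-category frequency vector.
asCategoryFrequencies <- function(no, intermediate, high) {
  v <- c(no = no, intermediate = intermediate, high = high)
  if (any(!is.finite(v)) || any(v < -1e-12))
    stopf("category frequencies must be finite and non-negative")
  if (abs(sum(v) - 1) > 1e-9)
    stopf("category frequencies must sum to 1 (got %.12f)", sum(v))
  v
}
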