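#' Construct an expression grid
#'
#' @param lower,upper grid limits, log10 fluorescence units.
#' @param binWidth bin width, log10 units; 0.05 throughout the analysis.
#' @return an [ExpressionGrid].
#' @export
expressionGrid <- function(lower, upper, binWidth = 0.05) {
  new("ExpressionGrid", lower = lower, upper = upper, binWidth = binWidth)
}

#' Build the shared grid from the full dataset
#'
#' The range of possible phenotypes is defined by the minimum and maximum
#' measurement across every library and condition that will be compared, so
#' that all DMEs share one binning. Edges are aligned to `lower + k * binWidth`.
#'
#' @param ... numeric vectors (or lists of vectors) of log10 values.
#' @param binWidth bin width in log10 units.
#' @return an [ExpressionGrid] covering all supplied values.
#' @export
gridFromSamples <- function(..., binWidth = 0.05) {
  v <- unlist(list(...), use.names = FALSE)
  v <- v[is.finite(v)]
  if (!length(v)) stopf("no finite samples supplied")
  lo <- min(v)
  hi <- lo + binWidth * ceiling((max(v) - lo) / binWidth + 1e-9)
  expressionGrid(lo, hi, binWidth)
}

## Bin index of each value on a grid; values exactly at the top edge go to
## the last bin. Errors on out-of-grid values, reporting the offending range.
binIndex <- function(values, grid) {
  nb <- nBins(grid)
  if (any(!is.finite(values))) stopf("samples must be finite")
  out <- values < grid@lower - 1e-9 | values > grid@upper + 1e-9
  if (any(out))
    stopf(paste0("samples outside the grid [%g, %g]: offending range ",
                 "[%g, %g]; build the grid from the full dataset first"),
          grid@lower, grid@upper, min(values[out]), max(values[out]))
  idx <- floor((values - grid@lower) / grid@binWidth) + 1L
  pmin.int(pmax.int(idx, 1L), nb)
}

#' Bin per-cell samples into a DME
#'
#' Histograms log10 expression values on half-open bins `[edge_k, edge_{k+1})`
#' (top edge closed) and normalizes to a probability distribution.
#'
#' @param values numeric vector of per-cell log10 fluorescence, or a
#'   data.frame with a `value` column as produced by [generateLibrary()].
#' @param grid the shared [ExpressionGrid].
#' @param label free-text label ("library / condition").
#' @return a [DME].
#' @export
buildDME <- function(values, grid, label = "") {
  if (is.data.frame(values)) values <- values$value
  if (!length(values)) stopf("no samples supplied")
  counts <- tabulate(binIndex(values, grid), nbins = nBins(grid))
  new("DME", grid = grid, probabilities = counts / sum(counts),
      nSamples = length(values), label = label)
}

#' Phenotype category bounds from wildtype distributions
#'
#' The no-expression category is defined to contain `coverage` (one-sided) of
#' the repressed wildtype distribution, and the high-expression category
#' `coverage` of the unrepressed wildtype distribution; everything between is
#' the intermediate category, i.e. expression levels the wildtype cannot
#' produce.
#'
#' @param wtPlus per-cell log10 values of the wildtype with repressor.
#' @param wtMinus per-cell log10 values of the wildtype without repressor.
#' @param coverage one-sided wildtype coverage of each outer category.
#' @return a [CategoryBounds].
#' @export
categoryBounds <- function(wtPlus, wtMinus, coverage = 0.999) {
  if (is.data.frame(wtPlus)) wtPlus <- wtPlus$value
  if (is.data.frame(wtMinus)) wtMinus <- wtMinus$value
  if (!length(wtPlus) || !length(wtMinus))
    stopf("both wildtype sample sets must be non-empty")
  low <- unname(quantile(wtPlus, coverage, type = 7))
  high <- unname(quantile(wtMinus, 1 - coverage, type = 7))
  if (low >= high)
    stopf(paste("category bounds overlap (lowCut %.3f >= highCut %.3f):",
                "wildtype not tightly repressed"), low, high)
  new("CategoryBounds", lowCut = low, highCut = high)
}

#' Fraction of samples in each phenotype category
#'
#' Categories are `(-Inf, lowCut]` (no expression), `(lowCut, highCut)`
#' (intermediate) and `[highCut, Inf)` (high expression); boundary values
#' belong to the outer categories.
#'
#' @param values per-cell log10 values (or a data.frame with `value`).
#' @param bounds a [CategoryBounds].
#' @return named numeric `c(no=, intermediate=, high=)` summing to 1.
#' @export
categoryFrequencies <- function(values, bounds) {
  if (is.data.frame(values)) values <- values$value
  if (!length(values)) stopf("no samples supplied")
  no <- mean(values <= bounds@lowCut)
  high <- mean(values >= bounds@highCut)
  asCategoryFrequencies(no, 1 - no - high, high)
}

#' Category frequencies of a binned DME
#'
#' Sums bin probabilities by bin centre; agrees with direct sample counting
#' up to bin-boundary quantization.
#'
#' @param dme a [DME].
#' @param bounds a [CategoryBounds].
#' @return named numeric `c(no=, intermediate=, high=)`.
#' @export
dmeCategoryFrequencies <- function(dme, bounds) {
  ctr <- binCenters(expressionGridOf(dme))
  p <- probabilities(dme)
  no <- sum(p[ctr <= bounds@lowCut])
  high <- sum(p[ctr >= bounds@highCut])
  asCategoryFrequencies(no, max(1 - no - high, 0), high)
}

## Entropy of a probability vector on bins of width dx, natural log,
## 0 * log 0 := 0.
entropyFromProbs <- function(p, dx) {
  nz <- p > 0
  -sum(p[nz] * log(p[nz])) + log(dx)
}

#' Shannon entropy of a DME
#'
#' `S = -sum_k P_k ln P_k + ln(dx)`: the discrete Shannon entropy of the
#' binned distribution plus the bin-width term that makes S an estimate of
#' differential entropy (in nats), so that values are comparable across bin
#' widths. The standard deviation is obtained by bootstrap: resampling the
#' underlying per-cell values with replacement, re-binning and recomputing S.
#'
#' @param values per-cell log10 values (or a data.frame with `value`).
#' @param grid the shared [ExpressionGrid].
#' @param B number of bootstrap resamples (0 skips the bootstrap, sd = NA).
#' @param seed optional RNG seed for the bootstrap.
#' @return list with `S` (nats), `sd` (nats) and the [DME] used.
#' @examples
#' g <- expressionGrid(0, 2, 0.05)
#' x <- runif(1e4, 0, 2)
#' shannonEntropy(x, g, B = 50, seed = 1)$S  # about ln 2
#' @export
shannonEntropy <- function(values, grid, B = 200, seed = NULL) {
  if (is.data.frame(values)) values <- values$value
  dme <- buildDME(values, grid)
  S <- entropyFromProbs(probabilities(dme), binWidth(grid))
  sdS <- NA_real_
  if (B > 0) {
    if (length(values) < 2) stopf("need >= 2 samples to bootstrap entropy")
    idx <- binIndex(values, grid)
    nb <- nBins(grid)
    n <- length(idx)
    sdS <- withSeed(seed, {
      boot <- vapply(seq_len(B), function(b) {
        cnt <- tabulate(idx[sample.int(n, n, replace = TRUE)], nbins = nb)
        entropyFromProbs(cnt / n, binWidth(grid))
      }, numeric(1))
      sd(boot)
    })
  }
  list(S = S, sd = sdS, dme = dme)
}

#' Entropy of an existing DME (no bootstrap)
#'
#' @param dme a [DME].
#' @return S in nats.
#' @export
entropyOfDME <- function(dme) {
  entropyFromProbs(probabilities(dme), binWidth(expressionGridOf(dme)))
}

#' Permutation test for an entropy difference
#'
#' Nonparametric test of whether two sample sets differ in the Shannon
#' entropy of their binned distributions: labels are permuted over the pooled
#' samples preserving group sizes, the statistic is `|S_a - S_b|`, and
#' `p = (1 + #{permuted >= observed}) / (nPerm + 1)`.
#'
#' @param samplesA,samplesB per-cell log10 values.
#' @param grid the shared [ExpressionGrid].
#' @param nPerm number of permutations (>= 100).
#' @param seed optional RNG seed.
#' @return list with `statistic` (observed |S_a - S_b|) and `p`.
#' @export
entropyPermutationTest <- function(samplesA, samplesB, grid,
                                   nPerm = 1000, seed = NULL) {
  if (is.data.frame(samplesA)) samplesA <- samplesA$value
  if (is.data.frame(samplesB)) samplesB <- samplesB$value
  if (nPerm < 100) stopf("nPerm must be >= 100")
  nb <- nBins(grid)
  dx <- binWidth(grid)
  idx <- binIndex(c(samplesA, samplesB), grid)
  nA <- length(samplesA); nTot <- length(idx)
  ent <- function(i) entropyFromProbs(tabulate(i, nbins = nb) / length(i), dx)
  obs <- abs(ent(idx[seq_len(nA)]) - ent(idx[-seq_len(nA)]))
  perm <- withSeed(seed, vapply(seq_len(nPerm), function(b) {
    sh <- sample.int(nTot)
    abs(ent(idx[sh[seq_len(nA)]]) - ent(idx[sh[-seq_len(nA)]]))
  }, numeric(1)))
  list(statistic = obs, p = (1 + sum(perm >= obs - 1e-12)) / (nPerm + 1))
}

#' Subsampling robustness of a distribution (K-S)
#'
#' Checks that an observed distribution is not sensitive to the number of
#' sampled cells: for each subsample size, random subsamples (without
#' replacement) are compared to the full sample by a two-sample
#' Kolmogorov-Smirnov test.
#'
#' @param values per-cell log10 values.
#' @param sizes subsample sizes, each < length(values).
#' @param nRep random subsamples per size.
#' @param seed optional RNG seed.
#' @return data.frame with columns `size`, `mean_D`, `mean_p`.
#' @export
ksSubsampleStability <- function(values, sizes, nRep = 50, seed = NULL) {
  if (is.data.frame(values)) values <- values$value
  n <- length(values)
  if (any(sizes >= n))
    stopf("every subsample size must be < n_samples (%d)", n)
  if (any(sizes < 1)) stopf("subsample sizes must be positive")
  withSeed(seed, {
    rows <- lapply(sizes, function(sz) {
      res <- vapply(seq_len(nRep), function(r) {
        sub <- values[sample.int(n, sz)]
        kt <- suppressWarnings(ks.test(sub, values))
        c(kt$statistic, kt$p.value)
      }, numeric(2))
      data.frame(size = sz, mean_D = mean(res[1, ]), mean_p = mean(res[2, ]))
    })
    do.call(rbind, rows)
  })
}
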