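#' Construct a gamma component distribution
#'
#' @param shape,scale,location gamma parameters; support starts at
#'   `location` (log10 units).
#' @param sse optional fit SSE to record.
#' @return a [GammaComponent].
#' @export
gammaComponent <- function(shape, scale, location, sse = NA_real_) {
  new("GammaComponent", shape = shape, scale = scale, location = location,
      sse = sse)
}

## Discretize a (location-shifted) gamma density onto offset bins of width
## dx centred at multiples of dx (offset bin j covers (j -/+ 0.5) * dx), so
## that index addition during discrete convolution carries no half-bin
## shift: mass_j = CDF(e_{j+1}) - CDF(e_j). `span` caps the represented
## range (log10 units) beyond the location; tail mass past the cap is
## lumped into the final offset bin (it would land above any practical grid
## anyway). Returns masses and the first offset index j0.
discretizeGamma <- function(gc, dx, span = Inf) {
  hi <- gc@location +
    min(qgamma(1 - 1e-12, shape = gc@shape, scale = gc@scale), span)
  j0 <- floor(gc@location / dx + 0.5)
  j1 <- ceiling(hi / dx + 0.5)
  edges <- ((j0:(j1 + 1L)) - 0.5) * dx
  cdf <- pgamma(edges - gc@location, shape = gc@shape, scale = gc@scale)
  mass <- diff(cdf)
  n <- length(mass)
  mass[n] <- mass[n] + 1 - cdf[n + 1L]  # capped tail
  s <- sum(mass)
  if (s <= 0) { # degenerate near-delta: all mass in the location bin
    mass <- c(1, numeric(n - 1L))
  } else mass <- mass / s
  list(mass = mass, j0 = as.integer(j0))
}

## Discrete convolution of an on-grid density `p` (nb bins) with offset
## masses (first offset j0 bins): effect j shifts bin i to i + j. Returns the
## on-grid part plus the total mass falling above / below the grid.
convolveOffsets <- function(p, mass, j0, nb) {
  # open convolution via FFT: full[m] = sum_{i+j-1=m} p_i mass_j, so source
  # bin i lands at grid bin m + j0
  full <- convolve(p, rev(mass), type = "open")
  full[full < 0] <- 0  # FFT round-off
  m <- seq_along(full)
  tgt <- m + j0
  ok <- tgt >= 1L & tgt <= nb
  out <- numeric(nb)
  out[tgt[ok]] <- full[ok]
  list(p = out, above = sum(full[tgt > nb]), below = sum(full[tgt < 1L]))
}

#' Infer the "true" component DME by forward-fit deconvolution
#'
#' An observed library DME is the convolution of the noise-free distribution
#' of mutational effects f with the measured wildtype distribution
#' (`F = f * F_wt`), because measurement noise is constant across genotypes.
#' Direct numerical deconvolution is unstable, so f is reverse-engineered:
#' assuming f belongs to the three-parameter gamma family, the parameters
#' (shape, scale, location) are optimized so that the discrete grid
#' convolution of f with the wildtype DME matches the observed DME in least
#' squares. Derivative-free simplex optimization from a deterministic lattice
#' of starting points (shape in {0.5, 1, 2, 5}, scale in {0.1, 0.5}, location
#' in {0, observed mean shift}); the best of all starts is returned.
#'
#' @param observed the observed component [DME] (e.g. the cis library with
#'   repressor).
#' @param wildtype the wildtype [DME] in the same condition, same grid.
#' @return a [GammaComponent] with the fit SSE recorded.
#' @export
fitTrueComponent <- function(observed, wildtype) {
  go <- expressionGridOf(observed); gw <- expressionGridOf(wildtype)
  if (!isTRUE(all.equal(binEdges(go), binEdges(gw))))
    stopf("observed and wildtype DMEs must share one grid")
  dx <- binWidth(go); nb <- nBins(go)
  pw <- probabilities(wildtype); po <- probabilities(observed)
  ctr <- binCenters(go)
  shift <- sum(ctr * po) - sum(ctr * pw)
  objective <- function(par) {
    gc <- gammaComponent(max(exp(par[1]), 1e-3), max(exp(par[2]), 1e-3),
                         par[3])
    dg <- discretizeGamma(gc, dx, span = (nb + 2) * dx)
    cv <- convolveOffsets(pw, dg$mass, dg$j0, nb)
    # fold out-of-grid mass into the edge bins so the model stays normalized
    pm <- cv$p
    pm[nb] <- pm[nb] + cv$above
    pm[1] <- pm[1] + cv$below
    sum((po - pm)^2)
  }
  starts <- expand.grid(shape = c(0.5, 1, 2, 5), scale = c(0.1, 0.5),
                        loc = unique(c(0, max(shift, 0))))
  best <- NULL
  fails <- character(0)
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      optim(c(log(starts$shape[i]), log(starts$scale[i]), starts$loc[i]),
            objective, method = "Nelder-Mead",
            control = list(maxit = 2000, reltol = 1e-10)),
      error = function(e) e)
    if (inherits(fit, "error")) { fails <- c(fails, conditionMessage(fit)); next }
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best))
    stopf("gamma component fit failed at every start: %s",
          paste(unique(fails), collapse = "; "))
  gammaComponent(max(exp(best$par[1]), 1e-3), max(exp(best$par[2]), 1e-3),
                 best$par[3], sse = best$value)
}

#' Fit the high-expression peak fraction of a trans DME
#'
#' Fits the fraction alpha of the unrepressed wildtype distribution that
#' accounts for the high-expression (loss-of-function) peak of a trans
#' library DME, by least squares over the right-hand part of the peak: the
#' bins at or above the mode of the unrepressed wildtype (the left flank is
#' contaminated by intermediate phenotypes). Closed form, clipped to [0, 1].
#'
#' @param transDME the trans-library [DME] (with repressor).
#' @param wtMinus the unrepressed wildtype [DME], same grid.
#' @return alpha in [0, 1].
#' @export
fitAlpha <- function(transDME, wtMinus) {
  if (!isTRUE(all.equal(binEdges(expressionGridOf(transDME)),
                        binEdges(expressionGridOf(wtMinus)))))
    stopf("transDME and wtMinus must share one grid")
  pw <- probabilities(wtMinus); pt. <- probabilities(transDME)
  modeIdx <- which.max(pw)
  idx <- seq(modeIdx, length(pw))
  denom <- sum(pw[idx]^2)
  if (denom <= 0)
    stopf("unrepressed wildtype DME has no mass at or above its mode")
  min(max(sum(pt.[idx] * pw[idx]) / denom, 0), 1)
}

#' Additive null prediction of the system DME by convolution
#'
#' Builds the expected system DME under additivity of log10 effects:
#' (i) the high-expression peak (fraction `alpha` of the unrepressed
#' wildtype) is removed from the trans DME; (ii) the remainder is convolved
#' with the inferred true cis component `fCis`; (iii) a smooth logistic
#' cutoff at the maximal attainable expression reassigns mass predicted
#' above the ceiling; (iv) the removed peak plus ceiling-excess mass is added
#' back as the unrepressed wildtype DME (`mode = "naive"`) or, accounting for
#' the genetic regulatory structure (loss-of-function trans mutants make the
#' promoter constitutive, so their expression follows the cis-element's
#' RNAP-binding effects), as the unrepressed cis DME
#' (`mode = "structured"`).
#'
#' @param transDME observed trans-library [DME] (with repressor).
#' @param fCis inferred true cis component, a [GammaComponent].
#' @param wtMinus unrepressed wildtype [DME].
#' @param cisMinus unrepressed cis-library [DME]; required for
#'   `mode = "structured"`.
#' @param mode "naive" or "structured".
#' @param cutoffLevel ceiling centre in log10 units; default the 99.9th
#'   percentile of the unrepressed wildtype DME.
#' @param alpha peak fraction; default fitted by [fitAlpha()].
#' @param tau logistic cutoff width; default `2 * binWidth`.
#' @return a [ConvolutionResult].
#' @export
predictSystem <- function(transDME, fCis, wtMinus, cisMinus = NULL,
                          mode = c("naive", "structured"),
                          cutoffLevel = NULL, alpha = NULL, tau = NULL) {
  mode <- match.arg(mode)
  grid <- expressionGridOf(transDME)
  sameGrid <- function(d) isTRUE(all.equal(binEdges(expressionGridOf(d)),
                                           binEdges(grid)))
  if (!sameGrid(wtMinus)) stopf("all DMEs must share one grid")
  if (mode == "structured") {
    if (is.null(cisMinus))
      stopf("mode = 'structured' requires the unrepressed cis DME (cisMinus)")
    if (!sameGrid(cisMinus)) stopf("all DMEs must share one grid")
  }
  dx <- binWidth(grid); nb <- nBins(grid); ctr <- binCenters(grid)
  if (is.null(tau)) tau <- 2 * dx
  pw <- probabilities(wtMinus)
  if (is.null(cutoffLevel)) {
    # centre of the unrepressed wildtype DME: the ceiling acts on true
    # expression, and measurement noise spreads ceiling-capped mutants over
    # the whole wildtype-high distribution, so the keep-probability of
    # convolved (noisy) mass crosses 1/2 at the wildtype's central level
    cutoffLevel <- sum(binCenters(grid) * pw)
  }
  if (cutoffLevel < grid@lower)
    stopf("cutoffLevel %.3f lies below the grid lower edge %.3f",
          cutoffLevel, grid@lower)
  if (is.null(alpha)) alpha <- fitAlpha(transDME, wtMinus)
  addback <- if (mode == "naive") pw else probabilities(cisMinus)

  remainder <- pmax(probabilities(transDME) - alpha * pw, 0)
  rmass <- sum(remainder)
  if (rmass < 1e-12) {
    warnf("empty remainder after peak removal: prediction is pure add-back")
    kept <- numeric(nb); removed <- 0; wConv <- 1
  } else {
    remainder <- remainder / rmass
    dg <- discretizeGamma(fCis, dx, span = (nb + 2) * dx)
    cv <- convolveOffsets(remainder, dg$mass, dg$j0, nb)
    pconv <- cv$p
    pconv[1] <- pconv[1] + cv$below  # instrument floor
    w <- 1 / (1 + exp((ctr - cutoffLevel) / tau))
    kept <- pconv * w
    removed <- 1 - sum(kept)        # ceiling excess incl. above-grid spill
  }
  predicted <- (1 - alpha) * kept + (alpha + (1 - alpha) * removed) * addback
  predicted <- predicted / sum(predicted)
  new("ConvolutionResult",
      predicted = new("DME", grid = grid, probabilities = predicted,
                      nSamples = nSamples(transDME),
                      label = sprintf("%s convolution prediction", mode)),
      alpha = alpha, mode = mode, cutoffLevel = cutoffLevel,
      removedMass = (1 - alpha) * removed, fitSSE = fCis@sse)
}

#' Categorical additive null prediction
#'
#' The additive model's prediction for the phenotype category of a system
#' double mutant given the categories of its component mutations, for a
#' tightly repressed wildtype. Pairings whose summed effects exceed the
#' biologically meaningful ceiling (the unrepressed promoter) are collapsed
#' to "high"; the intermediate-intermediate pairing can fall either side of
#' the ceiling and is reported as the composite class "intermediate-or-high".
#'
#' @param cisCat,transCat character vectors with values "no", "intermediate"
#'   or "high".
#' @return character vector of predicted system categories.
#' @examples
#' categoricalAdditivePrediction("no", "intermediate")    # "intermediate"
#' categoricalAdditivePrediction("high", "intermediate")  # "high"
#' @export
categoricalAdditivePrediction <- function(cisCat, transCat) {
  levs <- c("no", "intermediate", "high")
  if (!all(cisCat %in% levs) || !all(transCat %in% levs))
    stopf("categories must be one of %s", paste(levs, collapse = ", "))
  tab <- matrix(c("no", "intermediate", "high",
                  "intermediate", "intermediate-or-high", "high",
                  "high", "high", "high"),
                nrow = 3, byrow = TRUE, dimnames = list(levs, levs))
  tab[cbind(match(cisCat, levs), match(transCat, levs))]
}

#' Pearson chi-squared comparison of category frequencies
#'
#' Compares observed vs predicted frequencies of mutants in the three
#' phenotype categories. Printed library frequencies do not carry a sample
#' size, so the effective count entering the statistic is an explicit
#' parameter (the number of distinct mutants per library, 30,000, is the
#' natural choice).
#'
#' @param observed,predicted three-category frequency vectors (see
#'   [categoryFrequencies()]).
#' @param nEffective effective count (>= 1).
#' @return list with `chi2`, `df` (= 2) and `p`.
#' @export
compareCategoryFrequencies <- function(observed, predicted,
                                       nEffective = 30000) {
  if (length(observed) != 3L || length(predicted) != 3L)
    stopf("observed and predicted must have three categories")
  if (nEffective < 1) stopf("nEffective must be >= 1")
  if (any(predicted <= 0 & observed > 0)) {
    warnf("predicted category with zero mass but nonzero observations")
    return(list(chi2 = Inf, df = 2L, p = 0))
  }
  keep <- predicted > 0
  chi2 <- nEffective * sum((observed[keep] - predicted[keep])^2 /
                             predicted[keep])
  list(chi2 = chi2, df = 2L, p = pchisq(chi2, df = 2, lower.tail = FALSE))
}
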