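## Shared fixtures and independent oracles for the suite. Everything is
## generated in code; no stored data.

## Per-cell draws around a fixed true level with the constant-CV noise model.
cellsAt <- function(level, n, cv = 0.4, seed = NULL) {
  DMEpistasis:::withSeed(seed, DMEpistasis:::drawLog10Cells(rep(level, n), cv))
}

## Wildtype sample pair (minus/plus) under default reference levels.
wildtypeCells <- function(n, cv = 0.4, lo = 2.0, hi = 4.5, seed = 1) {
  list(minus = cellsAt(hi, n, cv, seed), plus = cellsAt(lo, n, cv, seed + 1))
}

## Default category bounds used across tests (fixed seed, large n).
defaultBounds <- function() {
  wt <- wildtypeCells(2e5, seed = 1000)
  categoryBounds(wt$plus, wt$minus)
}

## K-S distance between the binned CDFs of two DMEs on one grid.
dmeKS <- function(a, b) {
  max(abs(cumsum(probabilities(a)) - cumsum(probabilities(b))))
}

## Monte-Carlo sampler of the prediction pipeline's generative steps, at the
## bin level: draw from the trans remainder, add a gamma effect, apply the
## smooth ceiling by rejection into the add-back distribution. Independent
## route against predictSystem's deterministic convolution arithmetic.
mcPredictionBins <- function(transDME, fCis, wtMinus, addbackDME, alpha,
                             cutoffLevel, tau, nDraw, seed) {
  grid <- expressionGridOf(transDME)
  nb <- nBins(grid); ctr <- binCenters(grid)
  pw <- probabilities(wtMinus)
  rem <- pmax(probabilities(transDME) - alpha * pw, 0)
  rem <- rem / sum(rem)
  dg <- DMEpistasis:::discretizeGamma(fCis, binWidth(grid))
  pAdd <- probabilities(addbackDME)
  DMEpistasis:::withSeed(seed, {
    isPeak <- runif(nDraw) < alpha
    n1 <- sum(!isPeak)
    j <- sample.int(nb, n1, TRUE, prob = rem)
    m <- sample.int(length(dg$mass), n1, TRUE, prob = dg$mass) + dg$j0 - 1L
    s <- pmin(pmax(j + m, 1L), nb)
    keep <- runif(n1) < 1 / (1 + exp((ctr[s] - cutoffLevel) / tau))
    nAdd <- sum(isPeak) + sum(!keep)
    c(s[keep], sample.int(nb, nAdd, TRUE, prob = pAdd))
  })
}

## Empirical binned DME from bin-index draws.
binsToDME <- function(bins, grid) {
  new("DME", grid = grid,
      probabilities = tabulate(bins, nBins(grid)) / length(bins),
      nSamples = length(bins), label = "mc")
}

## Build a small synthetic scenario (components + observed system) and the
## fitted naive/structured predictions; used by convolution and acceptance
## tests.
fitScenario <- function(cfg, coupling = "regulatory", wtSeed = 7,
                        includeSystem = TRUE) {
  n <- as.integer(cfg@cellsPerLibrary)
  wtp <- cellsAt(cfg@log10ELo, n, cfg@noiseCV, wtSeed)
  wtm <- cellsAt(cfg@log10EHi, n, cfg@noiseCV, wtSeed + 1)
  tr <- generateLibrary(cfg, "trans", coupling = coupling)
  ci <- generateLibrary(cfg, "cis", coupling = coupling)
  sys <- if (includeSystem)
    generateLibrary(cfg, "system", coupling = coupling,
                    seed = cfg@seed + 13) else NULL
  g <- gridFromSamples(wtp, wtm, tr$samples$plus$value,
                       ci$samples$plus$value, ci$samples$minus$value,
                       if (includeSystem) sys$samples$plus$value)
  d <- list(wtPlus = buildDME(wtp, g, "wt/plus"),
            wtMinus = buildDME(wtm, g, "wt/minus"),
            cisPlus = buildDME(ci$samples$plus, g, "cis/plus"),
            cisMinus = buildDME(ci$samples$minus, g, "cis/minus"),
            transPlus = buildDME(tr$samples$plus, g, "trans/plus"),
            systemPlus = if (includeSystem)
              buildDME(sys$samples$plus, g, "system/plus"))
  fCis <- fitTrueComponent(d$cisPlus, d$wtPlus)
  list(grid = g, dmes = d, fCis = fCis, wtp = wtp, wtm = wtm,
       trans = tr, cis = ci, system = sys)
}

## Plate-reader style replicate set around a fixed log10 level.
plateReps <- function(level, n = 6, cv = 0.1) {
  10^level * stats::rlnorm(n, 0, sqrt(log1p(cv^2)))
}
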