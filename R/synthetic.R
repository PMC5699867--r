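#' Configure the synthetic mutant-library generator
#'
#' Returns a validated [SyntheticConfig]. The defaults describe the assayed
#' repression system: an 84-nt cis-element (promoter plus two operator sites)
#' and a 714-nt trans-element (the repressor gene); a tightly repressed
#' wildtype spanning about 2.5 decades of fluorescence between the repressed
#' (background) and unrepressed states; constant-CV log-normal per-cell noise;
#' graded cis-mutation effects acting independently on RNA-polymerase activity
#' and on operator binding; and bimodal trans-mutation effects (functional
#' with a small Beta-distributed perturbation, or loss-of-function). The
#' loss-of-function probability and perturbation shape are set so that a
#' low-mutation-probability trans library (about 7 mutations per mutant)
#' splits into roughly 69% no-expression, 10% intermediate and 22%
#' high-expression phenotypes.
#'
#' @param mutationRate per-nucleotide mutation probability in (0, 1).
#' @param cisLength,transLength element lengths in nt.
#' @param log10EHi,log10ELo wildtype mean log10 expression without / with
#'   repressor (arbitrary fluorescence units).
#' @param log10Background instrument floor; defaults to the repressed
#'   wildtype level (autofluorescence).
#' @param log10RepressionFold true wildtype fold-repression in decades. The
#'   default (3.5) exceeds the measured 2.5-decade range, so the repressed
#'   wildtype sits at the autofluorescence floor and moderate losses of
#'   repressor function stay phenotypically silent on the wildtype
#'   cis-element (cryptic variation) until cis mutations reveal them --
#'   the mechanism behind positive intermolecular epistasis.
#' @param noiseCV per-cell coefficient of variation on the linear scale.
#' @param plateNoiseCV replicate CV of plate-reader population means.
#' @param cisRnapEffect,cisOperatorEffect named numerics `c(neutral=, mean=)`:
#'   per-mutation probability of a zero effect, and the mean of the
#'   exponential magnitude of negative log10 effects otherwise.
#' @param transLofProb per-mutation loss-of-function probability.
#' @param transPerturb named numeric `c(shape1=, shape2=)` of the Beta law of
#'   residual repressor functionality phi for functional mutants.
#' @param religationFraction fraction of exact-wildtype plasmid in a library.
#' @param nMutants uniquely transformed genotypes per library.
#' @param cellsPerLibrary per-cell measurements per library and condition.
#' @param seed default RNG seed for generating functions (NA = none).
#' @return a [SyntheticConfig].
#' @examples
#' cfg <- syntheticConfig(nMutants = 200, cellsPerLibrary = 1e4)
#' cfg
#' @export
syntheticConfig <- function(mutationRate = 0.01,
                            cisLength = 84, transLength = 714,
                            log10EHi = 4.5, log10ELo = 2.0,
                            log10Background = log10ELo,
                            log10RepressionFold = 3.5,
                            noiseCV = 0.4, plateNoiseCV = 0.1,
                            cisRnapEffect = c(neutral = 0.5, mean = 0.5),
                            cisOperatorEffect = c(neutral = 0.5, mean = 0.7),
                            transLofProb = 0.035,
                            transPerturb = c(shape1 = 1, shape2 = 4.5),
                            religationFraction = 0,
                            nMutants = 30000, cellsPerLibrary = 1e6,
                            seed = NA_real_) {
  new("SyntheticConfig", mutationRate = mutationRate, cisLength = cisLength,
      transLength = transLength, log10EHi = log10EHi, log10ELo = log10ELo,
      log10Background = log10Background,
      log10RepressionFold = log10RepressionFold, noiseCV = noiseCV,
      plateNoiseCV = plateNoiseCV, cisRnapEffect = cisRnapEffect,
      cisOperatorEffect = cisOperatorEffect, transLofProb = transLofProb,
      transPerturb = transPerturb, religationFraction = religationFraction,
      nMutants = nMutants, cellsPerLibrary = cellsPerLibrary, seed = seed)
}

#' Sample per-mutant mutation counts
#'
#' Mutation counts per mutant are Poisson with mean `rate * length`, matching
#' the error-prone-PCR mutagenesis the libraries emulate.
#'
#' @param rate per-nucleotide mutation probability in (0, 1).
#' @param length element length in nt (>= 1).
#' @param n number of mutants.
#' @param seed optional RNG seed (local; the caller's stream is untouched).
#' @return integer vector of counts.
#' @examples
#' mean(sampleMutationCounts(0.01, 714, 1e4, seed = 1))  # about 7
#' @export
sampleMutationCounts <- function(rate, length, n, seed = NULL) {
  if (!is.numeric(rate) || length(rate) != 1L || rate < 0 || rate >= 1)
    stopf("rate must be a single probability in [0, 1)")
  if (!is.numeric(length) || length(length) != 1L || length < 1)
    stopf("length must be a positive number of nucleotides, got %s",
          deparse(length))
  if (!is.numeric(n) || length(n) != 1L || n < 1)
    stopf("n must be a positive count, got %s", deparse(n))
  withSeed(seed, rpois(n, lambda = rate * length))
}

## Per-mutant summed cis effects for one channel (RNAP or operator): each
## mutation is neutral with probability `neutral`, otherwise contributes an
## Exp(mean) decrease on the log10 scale. Returns values <= 0.
drawCisChannel <- function(nMutations, params) {
  nonNeutral <- rbinom(length(nMutations), nMutations,
                       1 - params[["neutral"]])
  eff <- numeric(length(nMutations))
  idx <- nonNeutral > 0L
  if (any(idx))
    eff[idx] <- -vapply(nonNeutral[idx], function(k)
      sum(rexp(k, rate = 1 / params[["mean"]])), numeric(1))
  eff
}

## Residual repressor functionality phi per mutant: loss of function with
## per-mutation escalation, otherwise a Beta-perturbed value (once per
## mutant); zero mutations leave phi = 1.
drawTransFunctionality <- function(nMutations, config) {
  n <- length(nMutations)
  pLof <- 1 - (1 - config@transLofProb)^nMutations
  lof <- runif(n) < pLof
  phi <- rep(1, n)
  phi[lof] <- 0
  perturbed <- !lof & nMutations > 0L
  phi[perturbed] <- rbeta(sum(perturbed),
                          config@transPerturb[["shape1"]],
                          config@transPerturb[["shape2"]])
  phi
}

#' True mean expression of a genotype
#'
#' Computes the noise-free mean log10 expression of genotypes under the
#' repressible-promoter model. Without repressor, expression is set by RNAP
#' binding alone: `log10EHi + log10_rnap_factor`, floored at background. With
#' repressor, occupancy competition gives
#' `log10( Emax * A / (1 + rho0 * phi * B) )`, floored at background, where
#' `A = 10^log10_rnap_factor`, `B = 10^log10_operator_factor`, `phi` is
#' residual repressor functionality and `rho0 = 10^log10RepressionFold - 1`
#' is the wildtype's true repression strength. Because the true repression
#' exceeds the measured dynamic range, the wildtype (`A = B = phi = 1`)
#' lands on the floor, i.e. exactly at `log10ELo`, and part of the
#' repression range is cryptic.
#'
#' With `coupling = "additive"` the repressed-condition mean is instead the
#' additive (log10) combination of each component's observed single-mutant
#' effect on the wildtype background (each individually floored), capped at
#' the expression ceiling: the coupling-free world in which convolution null
#' models are exact.
#'
#' @param truth data.frame with columns `log10_rnap_factor`,
#'   `log10_operator_factor`, `trans_functionality`.
#' @param config a [SyntheticConfig].
#' @param repressorPresent logical(1).
#' @param coupling "regulatory" (the mechanistic model) or "additive".
#' @return numeric vector of mean log10 expression values.
#' @export
trueExpression <- function(truth, config, repressorPresent,
                           coupling = c("regulatory", "additive")) {
  coupling <- match.arg(coupling)
  A <- 10^truth$log10_rnap_factor
  B <- 10^truth$log10_operator_factor
  phi <- truth$trans_functionality
  bg <- config@log10Background
  if (!repressorPresent)
    return(pmax(config@log10EHi + truth$log10_rnap_factor, bg))
  rho0 <- 10^config@log10RepressionFold - 1
  occupancy <- function(A, B, phi)
    pmax(config@log10EHi + log10(A) - log10(1 + rho0 * phi * B), bg)
  if (coupling == "regulatory") {
    e <- occupancy(A, B, phi)
  } else {
    # coupling-free world: the system phenotype is the sum of each
    # component's observed single-mutant effect on the repressed wildtype
    # background (each individually floored at background, hence >= 0 for a
    # tightly repressed wildtype), capped at the expression ceiling -- the
    # additive null made exact by construction
    wt <- occupancy(1, 1, 1)
    eCis <- occupancy(A, B, 1) - wt
    eTrans <- occupancy(1, 1, phi) - wt
    e <- pmin(wt + eCis + eTrans, config@log10EHi)
  }
  e
}

## Genotype table for one library. `which` selects which element carries
## mutations; system libraries pair independently drawn cis and trans
## genotypes. A religationFraction of rows is exact wildtype.
generateGenotypes <- function(config, which = c("cis", "trans", "system")) {
  which <- match.arg(which)
  n <- as.integer(config@nMutants)
  nCis <- if (which != "trans")
    rpois(n, config@mutationRate * config@cisLength) else integer(n)
  nTrans <- if (which != "cis")
    rpois(n, config@mutationRate * config@transLength) else integer(n)
  relig <- runif(n) < config@religationFraction
  nCis[relig] <- 0L
  nTrans[relig] <- 0L
  truth <- data.frame(
    mutant_id = sprintf("%s_%05d", which, seq_len(n)),
    n_mutations_cis = nCis,
    n_mutations_trans = nTrans,
    log10_rnap_factor = drawCisChannel(nCis, config@cisRnapEffect),
    log10_operator_factor = drawCisChannel(nCis, config@cisOperatorEffect),
    trans_functionality = drawTransFunctionality(nTrans, config))
  truth
}

#' Generate a synthetic mutant library with per-cell measurements
#'
#' Draws `nMutants` genotypes (cis-only, trans-only, or paired cis+trans
#' "system" genotypes), computes each genotype's true mean expression in both
#' conditions, and samples `cellsPerLibrary` per-cell log10 fluorescence
#' values per condition by assigning cells to genotypes uniformly at random
#' and adding constant-CV log-normal measurement noise.
#'
#' @param config a [SyntheticConfig].
#' @param which "cis", "trans" or "system".
#' @param coupling "regulatory" or "additive"; see [trueExpression()].
#' @param seed optional RNG seed; defaults to the config's seed slot.
#' @return list with `truth` (genotype table including true means
#'   `true_log10_E_minus`, `true_log10_E_plus`) and `samples`, a list of two
#'   data.frames `minus` and `plus` with columns `mutant_id`, `value`
#'   (per-cell log10 fluorescence).
#' @examples
#' cfg <- syntheticConfig(nMutants = 100, cellsPerLibrary = 5000, seed = 1)
#' lib <- generateLibrary(cfg, "trans")
#' head(lib$truth)
#' @export
generateLibrary <- function(config, which = c("cis", "trans", "system"),
                            coupling = c("regulatory", "additive"),
                            seed = config@seed) {
  which <- match.arg(which)
  coupling <- match.arg(coupling)
  if (config@nMutants < 1 || config@cellsPerLibrary < 1)
    stopf("nMutants and cellsPerLibrary must be positive")
  withSeed(seed, {
    truth <- generateGenotypes(config, which)
    truth$true_log10_E_minus <- trueExpression(truth, config, FALSE, coupling)
    truth$true_log10_E_plus <- trueExpression(truth, config, TRUE, coupling)
    nc <- as.integer(config@cellsPerLibrary)
    samples <- lapply(c(minus = "true_log10_E_minus",
                        plus = "true_log10_E_plus"), function(col) {
      g <- sample.int(nrow(truth), nc, replace = TRUE)
      data.frame(mutant_id = truth$mutant_id[g],
                 value = drawLog10Cells(truth[[col]][g], config@noiseCV))
    })
    list(truth = truth, samples = samples)
  })
}

## One point mutation in the chosen element; used for double-mutant panels.
drawPointMutant <- function(config, element) {
  if (element == "cis") {
    data.frame(n_mutations_cis = 1L, n_mutations_trans = 0L,
               log10_rnap_factor = drawCisChannel(1L, config@cisRnapEffect),
               log10_operator_factor =
                 drawCisChannel(1L, config@cisOperatorEffect),
               trans_functionality = 1)
  } else {
    data.frame(n_mutations_cis = 0L, n_mutations_trans = 1L,
               log10_rnap_factor = 0, log10_operator_factor = 0,
               trans_functionality = drawTransFunctionality(1L, config))
  }
}

## log10-sd of the constant-CV noise model; used for analytic category cuts.
log10NoiseSD <- function(cv) sqrt(log1p(cv^2)) / log(10)

#' Generate a double-mutant plate-reader panel
#'
#' Emulates panels of system double mutants: each pair combines one cis and
#' one trans point mutation, and the panel carries replicate population-mean
#' fluorescence measurements (linear scale, constant-CV replicate noise) for
#' the double mutant and both singles in both conditions, plus one shared
#' wildtype replicate set per condition. `selection = "designed"` keeps only
#' cis singles whose no-repressor expression is unimpaired (no RNAP effect)
#' and trans singles that fully repress the wildtype cis-element (true
#' repressed mean inside the wildtype no-expression category).
#'
#' @param config a [SyntheticConfig].
#' @param nPairs number of double mutants (the assayed panels used 150).
#' @param replicates replicate measurements per mutant and condition (>= 2;
#'   the assayed panels used 6).
#' @param selection "random" or "designed".
#' @param seed optional RNG seed; defaults to the config's seed slot.
#' @return list with `panel`, a data.frame with columns `pair_id`, `role`
#'   ("wildtype", "cis", "trans", "double"), `location_label`, `condition`
#'   ("minus"/"plus"), `replicate`, `fluorescence` (linear scale); and
#'   `truth`, one row per pair with the underlying effects, true means and
#'   the ground-truth epistasis `epsilon_true` (log10, repressed condition).
#' @export
generateDoubleMutantPanel <- function(config, nPairs = 150, replicates = 6,
                                      selection = c("random", "designed"),
                                      seed = config@seed) {
  selection <- match.arg(selection)
  if (replicates < 2) stopf("replicates must be >= 2")
  if (nPairs < 1) stopf("nPairs must be >= 1")
  withSeed(seed, {
    lowCut <- config@log10ELo +
      3.09 * log10NoiseSD(config@noiseCV)   # 99.9% of repressed wildtype
    draw <- function(element) {
      maxTries <- 1000L
      for (i in seq_len(maxTries)) {
        g <- drawPointMutant(config, element)
        if (selection == "random") return(g)
        if (element == "cis" && g$log10_rnap_factor == 0) return(g)
        if (element == "trans") {
          rep. <- trueExpression(g, config, TRUE)
          if (rep. <= lowCut) return(g)
        }
      }
      stopf(paste0("designed selection infeasible: no %s single satisfying ",
                   "the phenotype filter in %d draws (check %s)"),
            element, maxTries,
            if (element == "cis") "cisRnapEffect neutral mass"
            else "transLofProb / transPerturb")
    }
    if (selection == "designed" && config@transLofProb >= 1)
      stopf(paste("designed selection infeasible: transLofProb = 1 means no",
                  "trans single can fully repress the wildtype cis"))
    transRegions <- c("N-terminal", "linker", "C-terminal")
    cisRegions <- c("operator", "RNAP-contact", "both", "neither")
    pairs <- lapply(seq_len(nPairs), function(i) {
      cis <- draw("cis"); trans <- draw("trans")
      dbl <- data.frame(n_mutations_cis = 1L, n_mutations_trans = 1L,
                        log10_rnap_factor = cis$log10_rnap_factor,
                        log10_operator_factor = cis$log10_operator_factor,
                        trans_functionality = trans$trans_functionality)
      list(cis = cis, trans = trans, double = dbl,
           cisLoc = sample(cisRegions, 1, prob = c(0.3, 0.2, 0.3, 0.2)),
           transLoc = sample(transRegions, 1, prob = c(0.39, 0.17, 0.44)))
    })
    wt <- data.frame(n_mutations_cis = 0L, n_mutations_trans = 0L,
                     log10_rnap_factor = 0, log10_operator_factor = 0,
                     trans_functionality = 1)
    measure <- function(truthRow, pairId, role, locLabel) {
      do.call(rbind, lapply(c(minus = FALSE, plus = TRUE), function(rp) {
        m <- trueExpression(truthRow, config, rp)
        lin <- 10^m * rlnorm(replicates, meanlog = 0,
                             sdlog = sqrt(log1p(config@plateNoiseCV^2)))
        data.frame(pair_id = pairId, role = role, location_label = locLabel,
                   condition = if (rp) "plus" else "minus",
                   replicate = seq_len(replicates), fluorescence = lin)
      }))
    }
    panel <- rbind(
      measure(wt, "batch", "wildtype", NA_character_),
      do.call(rbind, lapply(seq_len(nPairs), function(i) {
        p <- pairs[[i]]
        id <- sprintf("pair_%03d", i)
        rbind(measure(p$cis, id, "cis", p$cisLoc),
              measure(p$trans, id, "trans", p$transLoc),
              measure(p$double, id, "double",
                      paste(p$cisLoc, p$transLoc, sep = "|")))
      })))
    rownames(panel) <- NULL
    wtPlus <- trueExpression(wt, config, TRUE)
    truth <- do.call(rbind, lapply(seq_len(nPairs), function(i) {
      p <- pairs[[i]]
      mCis <- trueExpression(p$cis, config, TRUE) - wtPlus
      mTrans <- trueExpression(p$trans, config, TRUE) - wtPlus
      mSys <- trueExpression(p$double, config, TRUE) - wtPlus
      data.frame(pair_id = sprintf("pair_%03d", i),
                 log10_rnap_factor = p$cis$log10_rnap_factor,
                 log10_operator_factor = p$cis$log10_operator_factor,
                 trans_functionality = p$double$trans_functionality,
                 cis_location = p$cisLoc, trans_location = p$transLoc,
                 m_cis_true = mCis, m_trans_true = mTrans, m_sys_true = mSys,
                 epsilon_true = mSys - (mCis + mTrans))
    }))
    list(panel = panel, truth = truth)
  })
}
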