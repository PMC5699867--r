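#' @import methods
#' @importFrom stats aov chisq.test convolve ecdf ks.test optim p.adjust
#'   pchisq pf pgamma pt qgamma qnorm quantile rbeta rbinom rexp rlnorm
#'   rnorm rpois runif sd var
NULL

#' Expression grid for binned distributions of mutational effects
#'
#' A shared binning of the log10 expression axis. Every DME that is compared,
#' convolved or subtracted must live on one grid, built once from the full
#' dataset so that bin edges are identical across libraries and conditions.
#' Edges are `lower + k * binWidth`; the last bin is extended to cover `upper`.
#'
#' @slot lower numeric(1), lower edge in log10 fluorescence units.
#' @slot upper numeric(1), upper edge in log10 fluorescence units.
#' @slot binWidth numeric(1), bin width in log10 units (default 0.05).
#' @export
setClass("ExpressionGrid",
  representation(lower = "numeric", upper = "numeric", binWidth = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (length(object@lower) != 1L || length(object@upper) != 1L ||
        length(object@binWidth) != 1L)
      msg <- c(msg, "lower, upper and binWidth must be scalars")
    else {
      if (!is.finite(object@lower) || !is.finite(object@upper) ||
          !is.finite(object@binWidth))
        msg <- c(msg, "grid limits must be finite")
      else {
        if (object@upper <= object@lower)
          msg <- c(msg, "upper must exceed lower")
        if (object@binWidth <= 0)
          msg <- c(msg, "binWidth must be positive")
      }
    }
    if (is.null(msg)) TRUE else msg
  })

#' Distribution of mutational effects (DME)
#'
#' A normalized, binned probability distribution of log10 expression across a
#' mutant library (or a wildtype population) on a shared [ExpressionGrid].
#'
#' @slot grid an [ExpressionGrid].
#' @slot probabilities numeric vector of per-bin frequencies P_k, summing to 1.
#' @slot nSamples integer(1), number of underlying per-cell measurements.
#' @slot label character(1), free-text "library / condition" tag.
#' @export
setClass("DME",
  representation(grid = "ExpressionGrid", probabilities = "numeric",
                 nSamples = "integer", label = "character"),
  validity = function(object) {
    msg <- NULL
    nb <- nBins(object@grid)
    if (length(object@probabilities) != nb)
      msg <- c(msg, sprintf("probabilities must have %d bins, got %d",
                            nb, length(object@probabilities)))
    if (any(!is.finite(object@probabilities)) || any(object@probabilities < 0))
      msg <- c(msg, "probabilities must be finite and non-negative")
    else if (abs(sum(object@probabilities) - 1) > 1e-9)
      msg <- c(msg, "probabilities must sum to 1 (tolerance 1e-9)")
    if (length(object@nSamples) != 1L || is.na(object@nSamples) ||
        object@nSamples < 1L)
      msg <- c(msg, "nSamples must be a positive count")
    if (is.null(msg)) TRUE else msg
  })

#' Phenotype category bounds
#'
#' The two cuts on the log10 expression axis separating "no expression"
#' (indistinguishable from the repressed wildtype), "intermediate" and
#' "high expression" (indistinguishable from the unrepressed wildtype)
#' phenotypes. Defined so that each outer category contains a stated coverage
#' (by default >99.9%) of the corresponding wildtype distribution.
#'
#' @slot lowCut numeric(1), upper edge of the no-expression category.
#' @slot highCut numeric(1), lower edge of the high-expression category.
#' @export
setClass("CategoryBounds",
  representation(lowCut = "numeric", highCut = "numeric"),
  validity = function(object) {
    if (length(object@lowCut) != 1L || length(object@highCut) != 1L)
      return("lowCut and highCut must be scalars")
    if (!is.finite(object@lowCut) || !is.finite(object@highCut))
      return("bounds must be finite")
    if (object@lowCut >= object@highCut)
      return("lowCut must be below highCut (wildtype not tightly repressed?)")
    TRUE
  })

#' Three-parameter gamma component distribution
#'
#' The inferred "true" DME f of a component: the distribution of mutational
#' effects on log10 expression free of measurement noise, parameterized as a
#' gamma distribution with shape, scale and a location shift (support starts
#' at `location`).
#'
#' @slot shape numeric(1) > 0, dimensionless.
#' @slot scale numeric(1) > 0, log10 units.
#' @slot location numeric(1), log10 units.
#' @slot sse numeric(1), squared error of the deconvolution fit that produced
#'   this component (NA for hand-constructed components).
#' @export
setClass("GammaComponent",
  representation(shape = "numeric", scale = "numeric", location = "numeric",
                 sse = "numeric"),
  prototype(sse = NA_real_),
  validity = function(object) {
    if (length(object@shape) != 1L || length(object@scale) != 1L ||
        length(object@location) != 1L)
      return("shape, scale and location must be scalars")
    if (!is.finite(object@shape) || object@shape <= 0)
      return("shape must be positive")
    if (!is.finite(object@scale) || object@scale <= 0)
      return("scale must be positive")
    if (!is.finite(object@location))
      return("location must be finite")
    TRUE
  })

#' Result of a convolution-based additive null prediction
#'
#' @slot predicted the predicted system [DME].
#' @slot alpha numeric(1) in [0, 1]: fitted fraction of the trans DME assigned
#'   to the high-expression (loss-of-function) peak and added back unconvolved.
#' @slot mode "naive" (adds back the unrepressed wildtype) or "structured"
#'   (adds back the unrepressed cis DME, encoding that loss-of-function trans
#'   mutants render the promoter constitutive).
#' @slot cutoffLevel numeric(1), log10 units: centre of the smooth expression
#'   ceiling.
#' @slot removedMass numeric(1): probability mass reassigned from above the
#'   ceiling into the add-back component.
#' @slot fitSSE numeric(1): SSE of the gamma component fit used (NA if the
#'   component was supplied directly).
#' @export
setClass("ConvolutionResult",
  representation(predicted = "DME", alpha = "numeric", mode = "character",
                 cutoffLevel = "numeric", removedMass = "numeric",
                 fitSSE = "numeric"),
  validity = function(object) {
    if (!object@mode %in% c("naive", "structured"))
      return("mode must be 'naive' or 'structured'")
    if (object@alpha < -1e-12 || object@alpha > 1 + 1e-12)
      return("alpha must lie in [0, 1]")
    TRUE
  })

#' Configuration of the synthetic mutant-library generator
#'
#' Encodes the mechanistic and statistical structure the analysis assumes:
#' a tightly repressed wildtype with two reference expression levels, cis
#' mutations with independent graded effects on RNA-polymerase activity and on
#' operator (repressor) binding, trans mutations that are bimodally either
#' functional (with small perturbations) or loss-of-function, Poisson mutation
#' counts, constant-CV log-normal measurement noise, and a hard expression
#' ceiling at the unrepressed wildtype level.
#'
#' @slot mutationRate per-nucleotide mutation probability (the assayed
#'   libraries used 0.01, 0.04 and 0.07).
#' @slot cisLength,transLength element lengths in nt (84 and 714).
#' @slot log10EHi,log10ELo wildtype mean log10 expression without / with
#'   repressor.
#' @slot log10Background instrument background floor, log10 units.
#' @slot log10RepressionFold true wildtype fold-repression in decades; when
#'   it exceeds `log10EHi - log10Background` the repressed wildtype sits at
#'   the floor and part of the repression range is hidden (cryptic).
#' @slot noiseCV per-cell coefficient of variation of linear-scale
#'   fluorescence (constant across genotypes and conditions).
#' @slot plateNoiseCV replicate-to-replicate CV of plate-reader population
#'   means.
#' @slot cisRnapEffect named numeric: `neutral` (point mass at zero effect)
#'   and `mean` (mean of the negative-exponential log10 effect on RNAP
#'   activity) per cis mutation.
#' @slot cisOperatorEffect same structure, for log10 operator-binding effects.
#' @slot transLofProb per-mutation probability that a trans mutation abolishes
#'   repressor function (escalates per mutation).
#' @slot transPerturb named numeric `shape1`, `shape2`: Beta parameters of the
#'   residual functionality phi of mutated-but-functional repressors.
#' @slot religationFraction fraction of the library that is re-ligated
#'   wildtype plasmid.
#' @slot nMutants number of uniquely transformed genotypes per library.
#' @slot cellsPerLibrary number of per-cell measurements per library and
#'   condition.
#' @slot seed default RNG seed used when a generating function is not given
#'   one explicitly.
#' @export
setClass("SyntheticConfig",
  representation(mutationRate = "numeric", cisLength = "numeric",
                 transLength = "numeric", log10EHi = "numeric",
                 log10ELo = "numeric", log10Background = "numeric",
                 log10RepressionFold = "numeric",
                 noiseCV = "numeric", plateNoiseCV = "numeric",
                 cisRnapEffect = "numeric", cisOperatorEffect = "numeric",
                 transLofProb = "numeric", transPerturb = "numeric",
                 religationFraction = "numeric", nMutants = "numeric",
                 cellsPerLibrary = "numeric", seed = "numeric"),
  validity = function(object) {
    msg <- NULL
    p1 <- function(x) length(x) == 1L && is.finite(x)
    if (!p1(object@mutationRate) || object@mutationRate <= 0 ||
        object@mutationRate >= 1)
      msg <- c(msg, "mutationRate must lie in (0, 1)")
    if (!p1(object@cisLength) || object@cisLength < 1 ||
        !p1(object@transLength) || object@transLength < 1)
      msg <- c(msg, "element lengths must be >= 1 nt")
    if (!p1(object@log10EHi) || !p1(object@log10ELo) ||
        object@log10EHi <= object@log10ELo)
      msg <- c(msg, "log10EHi must exceed log10ELo")
    if (!p1(object@log10RepressionFold) || object@log10RepressionFold <= 0)
      msg <- c(msg, "log10RepressionFold must be positive")
    else if (object@log10RepressionFold <
             object@log10EHi - object@log10ELo - 1e-9)
      msg <- c(msg, paste("log10RepressionFold below the measured dynamic",
                          "range: wildtype would not be tightly repressed"))
    if (!p1(object@noiseCV) || object@noiseCV <= 0)
      msg <- c(msg, "noiseCV must be positive")
    if (!p1(object@plateNoiseCV) || object@plateNoiseCV <= 0)
      msg <- c(msg, "plateNoiseCV must be positive")
    for (nm in c("cisRnapEffect", "cisOperatorEffect")) {
      v <- slot(object, nm)
      if (!all(c("neutral", "mean") %in% names(v)))
        msg <- c(msg, sprintf("%s needs named entries 'neutral' and 'mean'", nm))
      else if (v[["neutral"]] < 0 || v[["neutral"]] > 1 || v[["mean"]] <= 0)
        msg <- c(msg, sprintf("%s: neutral in [0,1], mean > 0", nm))
    }
    if (!all(c("shape1", "shape2") %in% names(object@transPerturb)) ||
        any(object@transPerturb[c("shape1", "shape2")] <= 0))
      msg <- c(msg, "transPerturb needs positive 'shape1' and 'shape2'")
    if (!p1(object@transLofProb) || object@transLofProb < 0 ||
        object@transLofProb > 1)
      msg <- c(msg, "transLofProb must lie in [0, 1]")
    if (!p1(object@religationFraction) || object@religationFraction < 0 ||
        object@religationFraction > 1)
      msg <- c(msg, "religationFraction must lie in [0, 1]")
    if (!p1(object@nMutants) || object@nMutants < 1)
      msg <- c(msg, "nMutants must be a positive count")
    if (!p1(object@cellsPerLibrary) || object@cellsPerLibrary < 1)
      msg <- c(msg, "cellsPerLibrary must be a positive count")
    if (is.null(msg)) TRUE else msg
  })
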