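#' @rdname ExpressionGrid-class
#' @param object,x an object.
#' @export
setGeneric("nBins", function(x) standardGeneric("nBins"))

#' @rdname ExpressionGrid-class
#' @export
setGeneric("binWidth", function(x) standardGeneric("binWidth"))

#' @rdname ExpressionGrid-class
#' @export
setGeneric("binEdges", function(x) standardGeneric("binEdges"))

#' @rdname ExpressionGrid-class
#' @export
setGeneric("binCenters", function(x) standardGeneric("binCenters"))

#' @rdname DME-class
#' @export
setGeneric("probabilities", function(x) standardGeneric("probabilities"))

#' @rdname DME-class
#' @export
setGeneric("nSamples", function(x) standardGeneric("nSamples"))

#' @rdname DME-class
#' @export
setGeneric("expressionGridOf", function(x) standardGeneric("expressionGridOf"))

## ---- ExpressionGrid accessors -------------------------------------------

#' @rdname ExpressionGrid-class
#' @export
setMethod("nBins", "ExpressionGrid", function(x) {
  as.integer(ceiling((x@upper - x@lower) / x@binWidth - 1e-9))
})

#' @rdname ExpressionGrid-class
#' @export
setMethod("binWidth", "ExpressionGrid", function(x) x@binWidth)

#' @rdname ExpressionGrid-class
#' @export
setMethod("binEdges", "ExpressionGrid", function(x) {
  x@lower + x@binWidth * seq.int(0L, nBins(x))
})

#' @rdname ExpressionGrid-class
#' @export
setMethod("binCenters", "ExpressionGrid", function(x) {
  x@lower + x@binWidth * (seq_len(nBins(x)) - 0.5)
})

setMethod("show", "ExpressionGrid", function(object) {
  cat(sprintf("ExpressionGrid: [%.4g, %.4g] log10 units, %d bins of width %g\n",
              object@lower, object@upper, nBins(object), object@binWidth))
})

## ---- DME accessors -------------------------------------------------------

#' @rdname DME-class
#' @export
setMethod("probabilities", "DME", function(x) x@probabilities)

#' @rdname DME-class
#' @export
setMethod("nSamples", "DME", function(x) x@nSamples)

#' @rdname DME-class
#' @export
setMethod("expressionGridOf", "DME", function(x) x@grid)

setMethod("show", "DME", function(object) {
  cat(sprintf("DME '%s': %d bins, n = %d samples\n",
              object@label, nBins(object@grid), object@nSamples))
  ctr <- binCenters(object@grid)
  m <- sum(ctr * object@probabilities)
  cat(sprintf("  mean log10 expression %.3f; mode bin at %.3f\n",
              m, ctr[which.max(object@probabilities)]))
})

setMethod("show", "CategoryBounds", function(object) {
  cat(sprintf(
    "CategoryBounds: no expression <= %.3f < intermediate < %.3f <= high\n",
    object@lowCut, object@highCut))
})

setMethod("show", "GammaComponent", function(object) {
  cat(sprintf(
    "GammaComponent: shape %.4g, scale %.4g, location %.4g (mean effect %.4g)\n",
    object@shape, object@scale, object@location,
    object@location + object@shape * object@scale))
  if (is.finite(object@sse)) cat(sprintf("  deconvolution SSE %.3e\n", object@sse))
})

setMethod("show", "ConvolutionResult", function(object) {
  cat(sprintf("ConvolutionResult (%s): alpha = %.3f, cutoff %.3f, removed %.4f\n",
              object@mode, object@alpha, object@cutoffLevel, object@removedMass))
  show(object@predicted)
})

setMethod("show", "SyntheticConfig", function(object) {
  cat("SyntheticConfig\n")
  cat(sprintf("  mutation rate %.3g per nt; cis %d nt, trans %d nt\n",
              object@mutationRate, as.integer(object@cisLength),
              as.integer(object@transLength)))
  cat(sprintf("  wildtype log10 expression: %.2f (no CI) / %.2f (CI); CV %.2f\n",
              object@log10EHi, object@log10ELo, object@noiseCV))
  cat(sprintf("  %d mutants, %g cells per library\n",
              as.integer(object@nMutants), object@cellsPerLibrary))
})
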