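#' Sort a library into phenotype partitions (FACS emulation)
#'
#' Each cell of the library is assigned to the no-expression, intermediate or
#' high-expression bin of its single observed sort-time draw (true genotype
#' mean plus constant-CV measurement noise), so genotypes spill across bins
#' exactly as measurement noise dictates — the entire mechanism behind
#' imperfect sorting accuracy.
#'
#' @param truth genotype table carrying true mean columns
#'   `true_log10_E_minus` / `true_log10_E_plus` (see [generateLibrary()]).
#' @param config the [SyntheticConfig] (noise model).
#' @param condition "minus" or "plus": the condition the sort is run in.
#' @param bounds a [CategoryBounds].
#' @param nCells number of sorted cells.
#' @param seed optional RNG seed.
#' @return list with `pools` (named list no/intermediate/high of genotype row
#'   indices, one entry per sorted cell) and `weights`, the realized fraction
#'   of cells per partition. Empty partitions are reported with a warning.
#' @export
sortLibrary <- function(truth, config, condition = c("plus", "minus"),
                        bounds, nCells = config@cellsPerLibrary,
                        seed = NULL) {
  condition <- match.arg(condition)
  col <- paste0("true_log10_E_", condition)
  if (!col %in% names(truth))
    stopf("truth table lacks column %s; generate the library first", col)
  withSeed(seed, {
    g <- sample.int(nrow(truth), as.integer(nCells), replace = TRUE)
    v <- drawLog10Cells(truth[[col]][g], config@noiseCV)
    bin <- ifelse(v <= bounds@lowCut, "no",
                  ifelse(v >= bounds@highCut, "high", "intermediate"))
    pools <- split(g, factor(bin, levels = c("no", "intermediate", "high")))
    empty <- names(pools)[lengths(pools) == 0L]
    if (length(empty))
      warnf("empty partition(s): %s; downstream weights renormalize",
            paste(empty, collapse = ", "))
    list(pools = pools, weights = lengths(pools) / length(g))
  })
}

#' Sorting accuracy: re-measure sorted partitions
#'
#' Draws a fresh, independent measurement for every sorted cell (emulating
#' regrowth and re-assay of each partition) and re-categorizes it. The
#' resulting per-partition category frequencies quantify FACS
#' misclassification, and their partition-weighted mixture is the
#' sorting-accuracy null prediction of the system category frequencies.
#'
#' @param sorted result of [sortLibrary()].
#' @param truth,config,condition,bounds as in [sortLibrary()].
#' @param seed optional RNG seed.
#' @return named list (no/intermediate/high partitions) of three-category
#'   frequency vectors; empty partitions yield NULL entries.
#' @export
sortingAccuracy <- function(sorted, truth, config,
                            condition = c("plus", "minus"), bounds,
                            seed = NULL) {
  condition <- match.arg(condition)
  col <- paste0("true_log10_E_", condition)
  withSeed(seed, {
    lapply(sorted$pools, function(g) {
      if (!length(g)) return(NULL)
      v <- drawLog10Cells(truth[[col]][g], config@noiseCV)
      categoryFrequencies(v, bounds)
    })
  })
}

#' Build the nine partition-combination libraries
#'
#' Crosses each partition of the trans library (sorted with repressor) with
#' each partition of the cis library (sorted without repressor, i.e. by RNAP
#' binding alone): every combined library pairs random trans genotypes from
#' one trans pool with random cis genotypes from one cis pool, and its DME is
#' measured in the repressor-present condition.
#'
#' @param transSorted,cisSorted results of [sortLibrary()] for the two
#'   component libraries.
#' @param transTruth,cisTruth the corresponding genotype tables.
#' @param config the [SyntheticConfig].
#' @param bounds a [CategoryBounds].
#' @param nCellsPerCombo measured cells per combined library.
#' @param coupling "regulatory" or "additive" (see [trueExpression()]).
#' @param seed optional RNG seed.
#' @return a partition grid: list with `cells` (3x3 list-matrix of
#'   three-category frequency vectors, rows = trans partitions, cols = cis
#'   partitions, NULL where a pool was empty), `transWeights` and
#'   `cisWeights` (realized partition fractions).
#' @export
combinePartitions <- function(transSorted, cisSorted, transTruth, cisTruth,
                              config, bounds, nCellsPerCombo = 1e5,
                              coupling = c("regulatory", "additive"),
                              seed = NULL) {
  coupling <- match.arg(coupling)
  parts <- c("no", "intermediate", "high")
  withSeed(seed, {
    cells <- matrix(vector("list", 9L), 3, 3, dimnames = list(parts, parts))
    for (t. in parts) for (p in parts) {
      gt <- transSorted$pools[[t.]]
      gc. <- cisSorted$pools[[p]]
      if (!length(gt) || !length(gc.)) next
      it <- gt[sample.int(length(gt), nCellsPerCombo, replace = TRUE)]
      ic <- gc.[sample.int(length(gc.), nCellsPerCombo, replace = TRUE)]
      combo <- data.frame(
        log10_rnap_factor = cisTruth$log10_rnap_factor[ic],
        log10_operator_factor = cisTruth$log10_operator_factor[ic],
        trans_functionality = transTruth$trans_functionality[it])
      m <- trueExpression(combo, config, TRUE, coupling)
      v <- drawLog10Cells(m, config@noiseCV)
      cells[[t., p]] <- categoryFrequencies(v, bounds)
    }
    list(cells = cells, transWeights = transSorted$weights,
         cisWeights = cisSorted$weights)
  })
}

#' Weighted mixture of category-frequency vectors
#'
#' @param freqs list of three-category frequency vectors (NULL entries are
#'   dropped, with their weight renormalized away).
#' @param weights numeric weights of the same length, summing to 1.
#' @return a three-category frequency vector.
#' @export
weightedCategoryMix <- function(freqs, weights) {
  if (length(freqs) != length(weights))
    stopf("freqs and weights must have equal length")
  if (abs(sum(weights) - 1) > 1e-6)
    stopf("weights must sum to 1 (got %.6f)", sum(weights))
  keep <- !vapply(freqs, is.null, logical(1))
  if (!any(keep)) stopf("all frequency vectors are empty")
  if (!all(keep)) {
    warnf("empty partition(s) dropped; weights renormalized")
    weights <- weights[keep] / sum(weights[keep])
    freqs <- freqs[keep]
  }
  out <- Reduce(`+`, Map(`*`, freqs, weights))
  asCategoryFrequencies(out[["no"]], out[["intermediate"]], out[["high"]])
}

#' Partition-weighted experimental prediction of the system DME categories
#'
#' Predicts the category frequencies of the full system library from the
#' nine partition-combination libraries: within each trans partition the
#' three cis-combination libraries are pooled (by default with equal weight,
#' the realized-material convention of the experiment; optionally weighted by
#' the realized cis partition fractions), and the pooled frequencies are then
#' weighted by the fraction of the original trans library in that partition.
#'
#' @param grid partition grid from [combinePartitions()].
#' @param cisWeighting "equal" pools each trans partition's three cis cells
#'   uniformly; "realized" weights them by the realized cis partition
#'   fractions (flagged extension).
#' @return a three-category frequency vector summing to 1.
#' @export
weightedPrediction <- function(grid, cisWeighting = c("equal", "realized")) {
  cisWeighting <- match.arg(cisWeighting)
  parts <- c("no", "intermediate", "high")
  rowMix <- lapply(parts, function(t.) {
    freqs <- lapply(parts, function(p) grid$cells[[t., p]])
    keep <- !vapply(freqs, is.null, logical(1))
    if (!any(keep)) return(NULL)
    w <- if (cisWeighting == "equal") rep(1 / 3, 3) else grid$cisWeights
    w <- w[keep] / sum(w[keep])
    suppressWarnings(weightedCategoryMix(freqs[keep], w))
  })
  weightedCategoryMix(rowMix, grid$transWeights)
}
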