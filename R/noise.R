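#' Gene-expression noise of one mutant (subsampled CV)
#'
#' Noise is the coefficient of variation of linear-scale fluorescence,
#' estimated on repeated random subsamples (without replacement within each
#' subsample) of the mutant's pooled per-cell measurements; subsampling puts
#' every mutant's estimate on the same footing regardless of pool size.
#' When the pool is large enough the subsamples are drawn as disjoint blocks
#' of a random permutation, so the CV replicates are independent and the
#' downstream ANOVA is exactly calibrated; otherwise subsamples are drawn
#' independently and share pool members (which inflates between-mutant F
#' statistics slightly).
#'
#' @param values per-cell linear-scale fluorescence (pooled replicates), or a
#'   data.frame with a `value` column of log10 values (converted back).
#' @param log10Input set TRUE if `values` are log10 fluorescence.
#' @param nSub number of subsamples (default 10).
#' @param subSize reads per subsample (default 5000).
#' @param seed optional RNG seed.
#' @return numeric vector of `nSub` CV values.
#' @export
cvNoise <- function(values, log10Input = FALSE, nSub = 10, subSize = 5000,
                    seed = NULL) {
  if (is.data.frame(values)) { values <- values$value; log10Input <- TRUE }
  if (log10Input) values <- 10^values
  n <- length(values)
  if (n < subSize)
    stopf("pool of %d reads is smaller than the subsample size %d", n, subSize)
  withSeed(seed, {
    if (n >= nSub * subSize) {
      idx <- sample.int(n, nSub * subSize)
      vapply(seq_len(nSub), function(i) {
        x <- values[idx[((i - 1) * subSize + 1):(i * subSize)]]
        sd(x) / mean(x)
      }, numeric(1))
    } else {
      vapply(seq_len(nSub), function(i) {
        x <- values[sample.int(n, subSize)]
        sd(x) / mean(x)
      }, numeric(1))
    }
  })
}

#' Classify a mutant as non-expressing
#'
#' A mutant is treated as non-expressing when at least `threshold` of its
#' pooled cells fall in the no-expression category; noise estimates of
#' expressing and non-expressing mutants are not comparable (the fluorescence
#' channel reads autofluorescence in the latter) and are analyzed in separate
#' strata.
#'
#' @param log10Values per-cell log10 fluorescence.
#' @param bounds a [CategoryBounds].
#' @param threshold fraction of cells required in the no-expression category.
#' @return logical(1): TRUE if non-expressing.
#' @export
isNonExpressing <- function(log10Values, bounds, threshold = 0.99) {
  if (is.data.frame(log10Values)) log10Values <- log10Values$value
  mean(log10Values <= bounds@lowCut) >= threshold
}

#' ANOVA for constancy of gene-expression noise
#'
#' One-way ANOVA of the subsampled CV values with mutants as groups, run
#' separately for the expressing and non-expressing strata. Under constant
#' noise the test rejects at its nominal level only.
#'
#' @param records data.frame with columns `mutant_id`, `expressing`
#'   (logical) and `cv` (one row per subsample CV value).
#' @return data.frame with one row per analyzed stratum: `stratum`, `F`,
#'   `df1`, `df2`, `p`. Strata with fewer than two mutants are skipped with
#'   a message.
#' @export
noiseAnova <- function(records) {
  need <- c("mutant_id", "expressing", "cv")
  if (!all(need %in% names(records)))
    stopf("records lack columns: %s",
          paste(setdiff(need, names(records)), collapse = ", "))
  out <- lapply(c(FALSE, TRUE), function(expr.) {
    sub <- records[records$expressing == expr., , drop = FALSE]
    stratum <- if (expr.) "expressing" else "non-expressing"
    if (length(unique(sub$mutant_id)) < 2) {
      message(sprintf("stratum '%s' has < 2 mutants: skipped", stratum))
      return(NULL)
    }
    fit <- aov(cv ~ factor(mutant_id), data = sub)
    s <- summary(fit)[[1]]
    data.frame(stratum = stratum, F = s$`F value`[1],
               df1 = s$Df[1], df2 = s$Df[2], p = s$`Pr(>F)`[1])
  })
  out <- do.call(rbind, out)
  if (is.null(out)) stopf("no stratum with >= 2 mutants")
  out
}

#' Noise records for a set of mutant isolates
#'
#' Convenience wrapper: draws (or takes) per-cell pools per mutant, gates
#' replicate agreement by a two-sample K-S test, computes subsampled CVs and
#' the expressing/non-expressing stratum.
#'
#' @param pools named list of per-cell log10 fluorescence vectors (one per
#'   mutant isolate; two replicate halves are compared by K-S before
#'   pooling).
#' @param bounds a [CategoryBounds].
#' @param nSub,subSize see [cvNoise()].
#' @param ksAlpha significance level of the replicate-agreement gate; pools
#'   failing it are flagged, not dropped.
#' @param seed optional RNG seed.
#' @return data.frame with columns `mutant_id`, `expressing`,
#'   `replicates_agree` and `cv` (nSub rows per mutant).
#' @export
noiseRecords <- function(pools, bounds, nSub = 10, subSize = 5000,
                         ksAlpha = 0.01, seed = NULL) {
  if (is.null(names(pools))) names(pools) <- sprintf("m%03d", seq_along(pools))
  seeds <- childSeeds(seed, length(pools))
  out <- Map(function(v, id, s) {
    half <- seq_len(length(v) %/% 2)
    agree <- suppressWarnings(ks.test(v[half], v[-half])$p.value) >= ksAlpha
    cvs <- cvNoise(v, log10Input = TRUE, nSub = nSub, subSize = subSize,
                   seed = s)
    data.frame(mutant_id = id, expressing = !isNonExpressing(v, bounds),
               replicates_agree = agree, cv = cvs)
  }, pools, names(pools), seeds)
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}
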