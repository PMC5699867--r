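#' Run the full synthetic-data analysis pipeline
#'
#' Executes every stage of the analysis on one synthetic scenario: library
#' generation (wildtype, cis, trans, system), shared-grid DME estimation,
#' Shannon entropies with bootstrap errors, naive and structure-aware
#' convolution predictions with category chi-squared tests, the FACS
#' partition-combination prediction with its sorting-accuracy null, the
#' double-mutant epistasis panel, and the gene-expression-noise ANOVA.
#' Tabular outputs and a key-value summary of every statistic are written to
#' `outDir`; the run is deterministic for a fixed config seed.
#'
#' @param config a [SyntheticConfig]; its `seed` slot drives all randomness.
#' @param outDir output directory (created if needed); NULL skips writing.
#' @param nPairs double mutants in the epistasis panel.
#' @param nIsolates mutant isolates in the noise analysis.
#' @param nEffective effective count for category chi-squared tests.
#' @param partitionCells cells per sorted partition / combined library.
#' @return (invisibly) a list with all stage results and the `summary`
#'   data.frame of statistics.
#' @export
runPipeline <- function(config, outDir = NULL, nPairs = 150, nIsolates = 20,
                        nEffective = 30000, partitionCells = 1e5) {
  if (is.na(config@seed))
    stopf("runPipeline requires a config with an explicit seed")
  seeds <- childSeeds(config@seed, 12)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
  }

  ## generation
  libs <- stage("generate", {
    wtTruth <- data.frame(log10_rnap_factor = 0, log10_operator_factor = 0,
                          trans_functionality = 1)
    wt <- withSeed(seeds[1], {
      n <- as.integer(config@cellsPerLibrary)
      list(minus = drawLog10Cells(rep(trueExpression(wtTruth, config, FALSE),
                                      n), config@noiseCV),
           plus = drawLog10Cells(rep(trueExpression(wtTruth, config, TRUE),
                                     n), config@noiseCV))
    })
    list(wt = wt,
         cis = generateLibrary(config, "cis", seed = seeds[2]),
         trans = generateLibrary(config, "trans", seed = seeds[3]),
         system = generateLibrary(config, "system", seed = seeds[4]))
  })

  ## DMEs on one shared grid
  dmes <- stage("dme", {
    grid <- gridFromSamples(libs$wt$minus, libs$wt$plus,
                            lapply(libs[c("cis", "trans", "system")],
                                   function(l) lapply(l$samples,
                                                      `[[`, "value")))
    bounds <- categoryBounds(libs$wt$plus, libs$wt$minus)
    d <- list(
      wtMinus = buildDME(libs$wt$minus, grid, "wildtype/minus"),
      wtPlus = buildDME(libs$wt$plus, grid, "wildtype/plus"),
      cisMinus = buildDME(libs$cis$samples$minus, grid, "cis/minus"),
      cisPlus = buildDME(libs$cis$samples$plus, grid, "cis/plus"),
      transPlus = buildDME(libs$trans$samples$plus, grid, "trans/plus"),
      systemPlus = buildDME(libs$system$samples$plus, grid, "system/plus"))
    list(grid = grid, bounds = bounds, dmes = d)
  })

  ## entropy table
  entropy <- stage("entropy", {
    sets <- list(cis = libs$cis$samples$plus$value,
                 trans = libs$trans$samples$plus$value,
                 system = libs$system$samples$plus$value)
    es <- childSeeds(seeds[5], length(sets))
    do.call(rbind, Map(function(v, nm, s) {
      e <- shannonEntropy(v, dmes$grid, B = 200, seed = s)
      data.frame(library = nm, S = e$S, sd = e$sd)
    }, sets, names(sets), es))
  })

  ## convolution predictions
  conv <- stage("convolution", {
    fCis <- fitTrueComponent(dmes$dmes$cisPlus, dmes$dmes$wtPlus)
    naive <- predictSystem(dmes$dmes$transPlus, fCis, dmes$dmes$wtMinus,
                           mode = "naive")
    structured <- predictSystem(dmes$dmes$transPlus, fCis, dmes$dmes$wtMinus,
                                cisMinus = dmes$dmes$cisMinus,
                                mode = "structured")
    obsCat <- dmeCategoryFrequencies(dmes$dmes$systemPlus, dmes$bounds)
    chi <- lapply(list(naive = naive, structured = structured), function(cr)
      compareCategoryFrequencies(
        obsCat, dmeCategoryFrequencies(cr@predicted, dmes$bounds),
        nEffective = nEffective))
    list(fCis = fCis, naive = naive, structured = structured,
         observedCategories = obsCat, chi2 = chi)
  })

  ## partition-combination prediction + sorting-accuracy null
  partition <- stage("partition", {
    ts <- sortLibrary(libs$trans$truth, config, "plus", dmes$bounds,
                      nCells = partitionCells, seed = seeds[6])
    cs <- sortLibrary(libs$cis$truth, config, "minus", dmes$bounds,
                      nCells = partitionCells, seed = seeds[7])
    grid9 <- combinePartitions(ts, cs, libs$trans$truth, libs$cis$truth,
                               config, dmes$bounds,
                               nCellsPerCombo = partitionCells,
                               seed = seeds[8])
    acc <- sortingAccuracy(ts, libs$trans$truth, config, "plus",
                           dmes$bounds, seed = seeds[9])
    pred <- weightedPrediction(grid9)
    null <- weightedCategoryMix(acc, ts$weights)
    obs <- dmeCategoryFrequencies(dmes$dmes$systemPlus, dmes$bounds)
    list(prediction = pred, sortingNull = null, observed = obs,
         chi2Prediction = compareCategoryFrequencies(obs, pred, nEffective),
         chi2Null = compareCategoryFrequencies(obs, null, nEffective))
  })

  ## epistasis panel
  epistasis <- stage("epistasis", {
    pan <- generateDoubleMutantPanel(config, nPairs = nPairs,
                                     seed = seeds[10])
    records <- epistasisPanel(pan$panel)
    list(panel = pan, records = records,
         nSignificant = sum(records$sign != "none"),
         nPositive = sum(records$sign == "positive"))
  })

  ## noise analysis
  noise <- stage("noise", {
    iso <- withSeed(seeds[11], {
      truth <- libs$system$truth
      pick <- sample.int(nrow(truth), nIsolates)
      lapply(pick, function(i)
        drawLog10Cells(rep(truth$true_log10_E_plus[i], 2e4), config@noiseCV))
    })
    names(iso) <- sprintf("iso_%03d", seq_along(iso))
    rec <- noiseRecords(iso, dmes$bounds, seed = seeds[12])
    list(records = rec, anova = noiseAnova(rec))
  })

  summary <- rbind(
    data.frame(statistic = paste0("entropy_", entropy$library),
               value = entropy$S),
    data.frame(statistic = c("chi2_naive", "chi2_structured",
                             "chi2_partition_prediction", "chi2_sorting_null"),
               value = c(conv$chi2$naive$chi2, conv$chi2$structured$chi2,
                         partition$chi2Prediction$chi2,
                         partition$chi2Null$chi2)),
    data.frame(statistic = c("epistasis_significant", "epistasis_positive"),
               value = c(epistasis$nSignificant, epistasis$nPositive)),
    data.frame(statistic = paste0("noise_anova_p_", noise$anova$stratum),
               value = noise$anova$p))

  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    w <- function(x, f) utils::write.table(
      x, file.path(outDir, f), sep = "\t", quote = FALSE, row.names = FALSE)
    edges <- binEdges(dmes$grid)
    dmeTab <- data.frame(bin_lower = edges[-length(edges)],
                         sapply(dmes$dmes, probabilities))
    w(dmeTab, "dme_table.tsv")
    w(entropy, "entropy_table.tsv")
    w(data.frame(bin_lower = edges[-length(edges)],
                 naive = probabilities(conv$naive@predicted),
                 structured = probabilities(conv$structured@predicted)),
      "prediction_table.tsv")
    w(epistasis$records, "epistasis_table.tsv")
    w(noise$records, "noise_table.tsv")
    w(summary, "summary.tsv")
  }
  invisible(list(libraries = libs, dme = dmes, entropy = entropy,
                 convolution = conv, partition = partition,
                 epistasis = epistasis, noise = noise, summary = summary))
}
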