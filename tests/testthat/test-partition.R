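test_that("sorting assigns cells by their single noisy draw", {
  b <- new("CategoryBounds", lowCut = 2.5, highCut = 4.0)
  truth <- data.frame(true_log10_E_plus = c(2.0, 3.2, 4.5),
                      true_log10_E_minus = 4.5)
  # vanishing noise: every cell lands in the bin of its true mean
  cfg0 <- syntheticConfig(noiseCV = 1e-4, nMutants = 3,
                          cellsPerLibrary = 3000)
  s0 <- sortLibrary(truth, cfg0, "plus", b, seed = 1)
  expect_equal(sort(unique(truth$true_log10_E_plus[s0$pools$no])), 2.0)
  expect_equal(sort(unique(truth$true_log10_E_plus[s0$pools$intermediate])),
               3.2)
  expect_equal(sort(unique(truth$true_log10_E_plus[s0$pools$high])), 4.5)

  # a genotype exactly at the cut splits about half and half
  cfg <- syntheticConfig(noiseCV = 0.4, nMutants = 1, cellsPerLibrary = 2e4)
  tEdge <- data.frame(true_log10_E_plus = 2.5, true_log10_E_minus = 4.5)
  sE <- suppressWarnings(sortLibrary(tEdge, cfg, "plus", b, seed = 2))
  expect_equal(length(sE$pools$no) / 2e4, 0.5, tolerance = 0.03)

  # spillover matches the Gaussian-tail oracle of the noise model
  tMid <- data.frame(true_log10_E_plus = 2.8, true_log10_E_minus = 4.5)
  sM <- suppressWarnings(sortLibrary(tMid, cfg, "plus", b, nCells = 4e4, seed = 3))
  sdl <- sqrt(log1p(0.4^2)) / log(10)
  expect_equal(length(sM$pools$no) / 4e4, stats::pnorm(2.5, 2.8, sdl),
               tolerance = 0.05)
  expect_warning(sortLibrary(tMid, cfg, "plus", b, nCells = 100, seed = 4),
                 "empty partition")
})

test_that("sorting accuracy reflects re-measurement purity", {
  b <- new("CategoryBounds", lowCut = 2.5, highCut = 4.0)
  truth <- data.frame(true_log10_E_plus = c(2.0, 3.2, 4.5),
                      true_log10_E_minus = 4.5)
  cfg0 <- syntheticConfig(noiseCV = 1e-4, nMutants = 3,
                          cellsPerLibrary = 3000)
  s0 <- sortLibrary(truth, cfg0, "plus", b, seed = 5)
  acc <- sortingAccuracy(s0, truth, cfg0, "plus", b, seed = 6)
  # zero noise: every re-measured partition is pure
  expect_equal(acc$no[["no"]], 1)
  expect_equal(acc$intermediate[["intermediate"]], 1)
  expect_equal(acc$high[["high"]], 1)
  # weights (1, 0, 0): the null prediction is the no-expression partition
  expect_equal(weightedCategoryMix(acc, c(1, 0, 0)), acc$no)

  # noisy case: purity equals one minus the tail mass, per the same oracle
  cfg <- syntheticConfig(noiseCV = 0.4, nMutants = 1, cellsPerLibrary = 4e4)
  tMid <- data.frame(true_log10_E_plus = 2.2, true_log10_E_minus = 4.5)
  sM <- suppressWarnings(sortLibrary(tMid, cfg, "plus", b, seed = 7))
  accM <- sortingAccuracy(sM, tMid, cfg, "plus", b, seed = 8)
  sdl <- sqrt(log1p(0.4^2)) / log(10)
  expect_equal(accM$no[["no"]], stats::pnorm(2.5, 2.2, sdl),
               tolerance = 0.02)
})

test_that("weighted prediction mixes the nine cells as the workflow does", {
  parts <- c("no", "intermediate", "high")
  v <- c(no = 0.2, intermediate = 0.5, high = 0.3)
  cells <- matrix(rep(list(v), 9), 3, 3, dimnames = list(parts, parts))
  grid <- list(cells = cells, transWeights = c(0.686, 0.097, 0.217),
               cisWeights = c(1, 1, 1) / 3)
  expect_equal(weightedPrediction(grid), v)

  # with all trans weight on the no-expression partition, the prediction is
  # that row alone; its no-expression cell contributes its measured 93.4
  # percent of no-expression phenotypes
  row <- list(c(no = 0.934, intermediate = 0.066, high = 0),
              c(no = 0.8, intermediate = 0.2, high = 0),
              c(no = 0.5, intermediate = 0.4, high = 0.1))
  cells2 <- cells
  for (i in 1:3) cells2[[1, i]] <- row[[i]]
  grid2 <- list(cells = cells2, transWeights = c(1, 0, 0),
                cisWeights = c(1, 1, 1) / 3)
  expect_equal(weightedPrediction(grid2),
               (row[[1]] + row[[2]] + row[[3]]) / 3)
  expect_error(weightedPrediction(list(cells = cells2,
                                       transWeights = c(1, 0.2, 0),
                                       cisWeights = rep(1 / 3, 3))),
               "sum to 1")
})

test_that("partition prediction is self-consistent in the coupling-free world", {
  cfg <- syntheticConfig(mutationRate = 0.04, nMutants = 3000,
                         cellsPerLibrary = 5e4, seed = 9)
  b <- defaultBounds()
  tr <- generateLibrary(cfg, "trans", coupling = "additive")
  ci <- generateLibrary(cfg, "cis", coupling = "additive")
  ts <- sortLibrary(tr$truth, cfg, "plus", b, nCells = 5e4, seed = 10)
  cs <- sortLibrary(ci$truth, cfg, "minus", b, nCells = 5e4, seed = 11)
  g9 <- combinePartitions(ts, cs, tr$truth, ci$truth, cfg, b,
                          nCellsPerCombo = 5e4, coupling = "additive",
                          seed = 12)
  pred <- weightedPrediction(g9, cisWeighting = "realized")
  # direct simulation of the combined library from the same materials
  obs <- DMEpistasis:::withSeed(13, {
    it <- sample.int(nrow(tr$truth), 1e5, TRUE)
    ic <- sample.int(nrow(ci$truth), 1e5, TRUE)
    combo <- data.frame(
      log10_rnap_factor = ci$truth$log10_rnap_factor[ic],
      log10_operator_factor = ci$truth$log10_operator_factor[ic],
      trans_functionality = tr$truth$trans_functionality[it])
    m <- trueExpression(combo, cfg, TRUE, "additive")
    categoryFrequencies(DMEpistasis:::drawLog10Cells(m, cfg@noiseCV), b)
  })
  expect_lt(max(abs(pred - obs)), 0.02)
})

test_that("the partition prediction beats the sorting-accuracy null", {
  # the high-mutation cis x low-mutation trans design, regulatory mechanism
  cfgC <- syntheticConfig(mutationRate = 0.07, nMutants = 3000,
                          cellsPerLibrary = 5e4, seed = 14)
  cfgT <- syntheticConfig(mutationRate = 0.01, nMutants = 3000,
                          cellsPerLibrary = 5e4, seed = 15)
  b <- defaultBounds()
  ci <- generateLibrary(cfgC, "cis")
  tr <- generateLibrary(cfgT, "trans")
  ts <- sortLibrary(tr$truth, cfgT, "plus", b, nCells = 5e4, seed = 16)
  cs <- sortLibrary(ci$truth, cfgC, "minus", b, nCells = 5e4, seed = 17)
  g9 <- combinePartitions(ts, cs, tr$truth, ci$truth, cfgC, b,
                          nCellsPerCombo = 5e4, seed = 18)
  pred <- weightedPrediction(g9)
  null <- weightedCategoryMix(
    sortingAccuracy(ts, tr$truth, cfgT, "plus", b, seed = 19), ts$weights)
  obs <- DMEpistasis:::withSeed(20, {
    it <- sample.int(nrow(tr$truth), 1e5, TRUE)
    ic <- sample.int(nrow(ci$truth), 1e5, TRUE)
    combo <- data.frame(
      log10_rnap_factor = ci$truth$log10_rnap_factor[ic],
      log10_operator_factor = ci$truth$log10_operator_factor[ic],
      trans_functionality = tr$truth$trans_functionality[it])
    m <- trueExpression(combo, cfgC, TRUE)
    categoryFrequencies(DMEpistasis:::drawLog10Cells(m, cfgC@noiseCV), b)
  })
  chiPred <- compareCategoryFrequencies(obs, pred, 1000)$chi2
  chiNull <- compareCategoryFrequencies(obs, null, 1000)$chi2
  expect_lt(chiPred, chiNull)
})
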