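test_that("mutation counts follow the Poisson law of the mutagenesis model", {
  # trans element at the low mutation probability: mean about 7 per mutant
  cts <- sampleMutationCounts(0.01, 714, 1e5, seed = 1)
  expect_equal(mean(cts), 7.14, tolerance = 0.02)

  # degenerate rate: no mutations at all
  expect_true(all(sampleMutationCounts(0, 500, 100, seed = 1) == 0))

  # zero-class frequency matches the closed-form Poisson mass
  cts <- sampleMutationCounts(0.04, 84, 1e5, seed = 2)
  expect_equal(mean(cts == 0), exp(-3.36), tolerance = 0.05)

  expect_error(sampleMutationCounts(0.01, 0, 10), "length")
  expect_error(sampleMutationCounts(0.01, 84, 0), "positive count")
})

test_that("true expression reproduces the wildtype calibration identities", {
  cfg <- syntheticConfig(log10EHi = 4.5, log10ELo = 2.0)
  wt <- data.frame(log10_rnap_factor = 0, log10_operator_factor = 0,
                   trans_functionality = 1)
  expect_equal(trueExpression(wt, cfg, TRUE), 2.0)
  expect_equal(trueExpression(wt, cfg, FALSE), 4.5)

  # loss-of-function repressor: any cis background becomes constitutive
  g <- data.frame(log10_rnap_factor = c(0, -0.8, -0.3),
                  log10_operator_factor = c(0, -1, -2),
                  trans_functionality = 0)
  expect_equal(trueExpression(g, cfg, TRUE), trueExpression(g, cfg, FALSE))

  # hand evaluation of the occupancy formula, above and below the floor
  rho0 <- 10^cfg@log10RepressionFold - 1
  g2 <- data.frame(log10_rnap_factor = 0, log10_operator_factor = 0,
                   trans_functionality = c(0.01, 0.5))
  expect_equal(trueExpression(g2, cfg, TRUE),
               pmax(log10(10^4.5 / (1 + rho0 * c(0.01, 0.5))), 2.0))
  # phi = 0.5 still represses below the floor: cryptic on the wildtype cis
  expect_equal(trueExpression(g2, cfg, TRUE)[2], 2.0)
})

test_that("true expression is monotone in the binding factors", {
  cfg <- syntheticConfig()
  base <- data.frame(log10_rnap_factor = -0.5, log10_operator_factor = -0.5,
                     trans_functionality = 0.7)
  for (d in c(0.2, 0.5, 1.5)) {
    weakerOp <- transform(base, log10_operator_factor =
                                  log10_operator_factor - d)
    expect_gte(trueExpression(weakerOp, cfg, TRUE),
               trueExpression(base, cfg, TRUE))
    weakerRnap <- transform(base, log10_rnap_factor = log10_rnap_factor - d)
    expect_lte(trueExpression(weakerRnap, cfg, TRUE),
               trueExpression(base, cfg, TRUE))
    expect_lte(trueExpression(weakerRnap, cfg, FALSE),
               trueExpression(base, cfg, FALSE))
  }
})

test_that("library generation honours the mutational structure", {
  cfg <- syntheticConfig(mutationRate = 0.07, nMutants = 4000,
                         cellsPerLibrary = 2e4, seed = 3)
  lib <- generateLibrary(cfg, "cis")
  # exact-wildtype genotype fraction = Poisson zero class (plus religation 0)
  expect_equal(mean(lib$truth$n_mutations_cis == 0), exp(-0.07 * 84),
               tolerance = 0.6)  # rare event, wide MC band
  expect_true(all(lib$truth$n_mutations_trans == 0))
  expect_true(all(lib$truth$true_log10_E_minus >=
                    lib$truth$true_log10_E_plus - 1e-12))
  expect_true(all(lib$truth$true_log10_E_minus <= cfg@log10EHi + 1e-12))

  # a fully re-ligated library is wildtype in law
  cfgR <- syntheticConfig(religationFraction = 1, nMutants = 500,
                          cellsPerLibrary = 2e4, seed = 4)
  libR <- generateLibrary(cfgR, "system")
  wt <- wildtypeCells(2e4, seed = 40)
  expect_gt(suppressWarnings(
    stats::ks.test(libR$samples$plus$value, wt$plus)$p.value), 0.01)

  # trans mutations leave the no-repressor condition untouched
  cfgT <- syntheticConfig(nMutants = 2000, cellsPerLibrary = 2e4, seed = 5)
  libT <- generateLibrary(cfgT, "trans")
  expect_gt(suppressWarnings(
    stats::ks.test(libT$samples$minus$value, wt$minus)$p.value), 0.01)
})

test_that("generation is deterministic under a fixed seed", {
  cfg <- syntheticConfig(nMutants = 200, cellsPerLibrary = 1000, seed = 9)
  a <- generateLibrary(cfg, "system")
  b <- generateLibrary(cfg, "system")
  expect_identical(a, b)
  pa <- generateDoubleMutantPanel(cfg, nPairs = 5, seed = 11)
  pb <- generateDoubleMutantPanel(cfg, nPairs = 5, seed = 11)
  expect_identical(pa, pb)
})

test_that("the planted regulatory structure departs from the additive null", {
  # the signal the pipeline must detect: with loss-of-function trans mutants
  # and cis RNAP effects, the true system law differs from the coupling-free
  # (additive) law under the same component genotypes
  cfg <- syntheticConfig(mutationRate = 0.04, nMutants = 4000,
                         cellsPerLibrary = 4e4, seed = 12)
  reg <- generateLibrary(cfg, "system", coupling = "regulatory")
  add <- generateLibrary(cfg, "system", coupling = "additive")
  ks <- suppressWarnings(stats::ks.test(reg$samples$plus$value,
                                        add$samples$plus$value))
  expect_lt(ks$p.value, 1e-6)
})

test_that("double-mutant panels respect the designed-selection filters", {
  cfg <- syntheticConfig(nMutants = 100, cellsPerLibrary = 1000,
                         plateNoiseCV = 0.05, seed = 21)
  pan <- generateDoubleMutantPanel(cfg, nPairs = 20, replicates = 6,
                                   selection = "designed")
  # every designed cis single keeps full no-repressor expression
  expect_true(all(pan$truth$log10_rnap_factor == 0))
  # every designed trans single fully represses the wildtype cis
  lowCut <- cfg@log10ELo + 3.09 * sqrt(log1p(cfg@noiseCV^2)) / log(10)
  transPlus <- pmax(with(pan$truth, log10(10^cfg@log10EHi /
    (1 + (10^cfg@log10RepressionFold - 1) * trans_functionality))),
    cfg@log10Background)
  expect_true(all(transPlus <= lowCut + 1e-9))
  # panel completeness: all roles and both conditions, 6 replicates
  expect_setequal(unique(pan$panel$role),
                  c("wildtype", "cis", "trans", "double"))
  expect_equal(nrow(pan$panel), (1 + 3 * 20) * 2 * 6)

  # infeasible filter is named
  cfgBad <- syntheticConfig(transLofProb = 1, nMutants = 10,
                            cellsPerLibrary = 100, seed = 22)
  expect_error(generateDoubleMutantPanel(cfgBad, nPairs = 2,
                                         selection = "designed"),
               "infeasible")
  expect_error(generateDoubleMutantPanel(cfg, nPairs = 2, replicates = 1),
               "replicates")
})

test_that("forcing all effects to zero yields zero epistasis within noise", {
  cfg <- syntheticConfig(nMutants = 10, cellsPerLibrary = 100,
                         cisRnapEffect = c(neutral = 1, mean = 0.5),
                         cisOperatorEffect = c(neutral = 1, mean = 0.5),
                         transLofProb = 0,
                         transPerturb = c(shape1 = 1e5, shape2 = 1e-3),
                         plateNoiseCV = 0.02, seed = 31)
  pan <- generateDoubleMutantPanel(cfg, nPairs = 1, replicates = 6)
  rec <- epistasisPanel(pan$panel)
  expect_lt(abs(rec$epsilon), 4 * rec$se_epsilon + 0.05)
})
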