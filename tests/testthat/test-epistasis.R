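test_that("relative effects and their errors behave as defined", {
  wt <- c(100, 110, 90)
  expect_equal(relativeEffect(wt, wt)$m, 0)
  r <- relativeEffect(10 * wt, wt)
  expect_equal(r$m, 1)
  # identical shapes: mutant and wildtype log-variances match
  expect_equal(r$varMut, r$varWt)
  # exact tenfold with zero variance
  r0 <- relativeEffect(c(1000, 1000), c(100, 100))
  expect_equal(r0$m, 1); expect_equal(r0$se, 0)
  expect_error(relativeEffect(c(1, -1), wt), "positive")
  expect_error(relativeEffect(1000, wt), "replicates")

  # coverage of m +/- t * se near 95 percent
  set.seed(1)
  cover <- vapply(1:2000, function(i) {
    r <- relativeEffect(plateReps(3.0), plateReps(2.0))
    abs(r$m - 1) < stats::qt(0.975, 10) * r$se
  }, logical(1))
  expect_gt(mean(cover), 0.92); expect_lt(mean(cover), 0.975)
})

test_that("epistasis is the exact additive residual on both scales", {
  mk <- function(m, se2) list(m = m, varMut = se2 / 2, varWt = se2 / 2,
                              dfMut = 5L, dfWt = 5L, se = sqrt(se2))
  st <- epistasisStat(mk(1.0, 1e-4), mk(0.4, 1e-4), mk(0.6, 1e-4))
  expect_equal(st$epsilon, 0)
  st2 <- epistasisStat(mk(2.0, 1e-4), mk(0.5, 1e-4), mk(0.5, 1e-4))
  expect_equal(st2$epsilon, 1)
  expect_equal(st2$se, sqrt(3e-4))
  # recomputing expected + epsilon returns the observed system effect
  expect_equal((0.5 + 0.5) + st2$epsilon, 2.0)

  # log-additive deviation = linear-multiplicative deviation
  mSys <- 1.7; mCis <- 0.4; mTrans <- 0.9
  epsLog <- mSys - (mCis + mTrans)
  epsLin <- log10(10^mSys / (10^mCis * 10^mTrans))
  expect_equal(epsLog, epsLin)

  # degenerate zero-error case is flagged
  expect_warning(d <- epistasisStat(mk(1, 0), mk(0.2, 0), mk(0.2, 0)),
                 "zero propagated error")
  expect_equal(d$p, 0); expect_true(d$degenerate)
})

test_that("the t-test on additive pairs is calibrated", {
  set.seed(2)
  ps <- vapply(1:800, function(i) {
    mc <- stats::runif(1, 0, 1); mt <- stats::runif(1, 0, 1.5)
    epistasisStat(relativeEffect(plateReps(2 + mc + mt), plateReps(2)),
                  relativeEffect(plateReps(2 + mc), plateReps(2)),
                  relativeEffect(plateReps(2 + mt), plateReps(2)))$p
  }, numeric(1))
  frac <- mean(ps < 0.05)
  ciHalf <- 1.96 * sqrt(0.05 * 0.95 / 800)
  expect_gt(frac, 0.05 - ciHalf - 0.01)
  expect_lt(frac, 0.05 + ciHalf + 0.01)
})

test_that("BH classification controls FDR and ranks correctly", {
  # one extreme p among 150 nulls: worst-rank BH q = 150 * p
  rec <- data.frame(pair_id = 1:150, epsilon = c(0.5, rep(0, 149)),
                    p = c(1e-9, rep(1, 149)))
  cl <- fdrClassify(rec)
  expect_equal(cl$q[1], 150e-9)
  expect_equal(cl$sign[1], "positive")
  expect_true(all(cl$sign[-1] == "none"))

  # planted panels: empirical FDR at the nominal level in expectation,
  # with high power at |eps| = 0.5, cv = 0.1
  set.seed(3)
  res <- vapply(1:5, function(r) {
    recs <- do.call(rbind, lapply(1:300, function(i) {
      planted <- i <= 40
      eps <- if (planted) 0.5 else 0
      st <- epistasisStat(
        relativeEffect(plateReps(2.6 + eps), plateReps(2)),
        relativeEffect(plateReps(2.3), plateReps(2)),
        relativeEffect(plateReps(2.3), plateReps(2)))
      data.frame(pair_id = i, epsilon = st$epsilon, p = st$p,
                 planted = planted)
    }))
    cl <- fdrClassify(recs)
    disc <- cl$sign != "none"
    c(fdr = sum(disc & !cl$planted) / max(sum(disc), 1),
      power = mean(disc[cl$planted]))
  }, numeric(2))
  expect_lte(mean(res["fdr", ]), 0.05 + 0.03)
  expect_gt(mean(res["power", ]), 0.9)
})

test_that("regulatory mechanisms set the sign of true epistasis", {
  cfg <- syntheticConfig()
  wtPlus <- 2.0
  mEff <- function(truth) trueExpression(truth, cfg, TRUE) - wtPlus
  g <- function(rnap, op, phi)
    data.frame(log10_rnap_factor = rnap, log10_operator_factor = op,
               trans_functionality = phi)
  # loss-of-function trans + RNAP-impairing cis: negative epistasis
  epsLof <- mEff(g(-0.8, 0, 0)) - (mEff(g(-0.8, 0, 1)) + mEff(g(0, 0, 0)))
  expect_lt(epsLof, -0.1)
  # cryptic trans perturbation revealed by operator-weakening cis: positive
  epsCry <- mEff(g(0, -2, 0.3)) - (mEff(g(0, -2, 1)) + mEff(g(0, 0, 0.3)))
  expect_gt(epsCry, 0.1)

  # the panel pipeline recovers those signs on (nearly) noiseless panels
  cfgN <- syntheticConfig(plateNoiseCV = 0.01,
                          cisRnapEffect = c(neutral = 0, mean = 0.8),
                          cisOperatorEffect = c(neutral = 1, mean = 0.7),
                          transLofProb = 1, nMutants = 10,
                          cellsPerLibrary = 100, seed = 4)
  pan <- generateDoubleMutantPanel(cfgN, nPairs = 30, replicates = 6)
  rec <- epistasisPanel(pan$panel)
  strong <- abs(pan$truth$epsilon_true) > 0.2
  expect_true(all(rec$sign[strong] ==
                    ifelse(pan$truth$epsilon_true[strong] > 0,
                           "positive", "negative")))
})

test_that("location association is a valid independence test", {
  rec <- data.frame(sign = rep(c("positive", "negative", "none"), each = 30),
                    trans_location = rep(c("N-terminal", "linker",
                                           "C-terminal"), 30),
                    cis_location = "operator")
  # balanced table: no association
  r <- locationAssociation(rec, "trans")
  expect_equal(r$chi2, 0, tolerance = 1e-9)
  expect_equal(r$df, 4)

  # perfect association: chi2 attains the table maximum (n * min(r,c)-1 df)
  rec2 <- data.frame(sign = rep(c("positive", "none"), each = 20),
                     trans_location = rep(c("linker", "C-terminal"),
                                          each = 20))
  r2 <- locationAssociation(rec2, "trans")
  expect_equal(r2$chi2, 40)  # n * (min(2,2) - 1)
  expect_lt(r2$p, 1e-9)

  expect_error(locationAssociation(rec, "cis"), "one cis location")

  # labels independent of sign: p roughly uniform
  set.seed(5)
  ps <- vapply(1:200, function(i) {
    rr <- data.frame(sign = sample(c("positive", "negative", "none"), 90,
                                   replace = TRUE),
                     trans_location = sample(c("N-terminal", "linker",
                                               "C-terminal"), 90,
                                             replace = TRUE))
    suppressWarnings(locationAssociation(rr, "trans")$p)
  }, numeric(1))
  expect_gt(mean(ps < 0.05), 0.0); expect_lt(mean(ps < 0.05), 0.12)
})

test_that("panel effect distributions and K-S comparisons are sound", {
  set.seed(6)
  rec <- data.frame(m_cis = stats::rnorm(50, 0.2, 0.05),
                    m_trans = stats::rnorm(50, 1.5, 0.3),
                    m_sys = stats::rnorm(50, 1.0, 0.5))
  r <- dmeOfPanel(rec)
  expect_named(r$effects, c("cis", "trans", "system"))
  expect_equal(nrow(r$ks), 3)
  # disjoint supports give D = 1
  i <- which(r$ks$group_a == "cis" & r$ks$group_b == "trans")
  expect_equal(r$ks$D[i], 1)
  expect_error(dmeOfPanel(rec[0, ]), "records")
})
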