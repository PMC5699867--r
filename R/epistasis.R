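#' Wildtype-relative expression effect of a mutant
#'
#' The effect of a mutant is its mean log10 fluorescence relative to the
#' wildtype, with the wildtype's replicate variance propagated into the
#' standard error: `se^2 = var(log10 mutant)/n_m + var(log10 wt)/n_w`.
#'
#' @param mutantReps,wtReps positive linear-scale fluorescence replicates
#'   (>= 2 each).
#' @return list with `m`, `se`, and the per-term variance components
#'   (`varMut`, `varWt`) and degrees of freedom (`dfMut`, `dfWt`) used for
#'   Welch-Satterthwaite combination downstream.
#' @examples
#' relativeEffect(c(1000, 1100, 900), c(100, 110, 90))$m  # about 1 (10x)
#' @export
relativeEffect <- function(mutantReps, wtReps) {
  if (length(mutantReps) < 2 || length(wtReps) < 2)
    stopf("need >= 2 replicates for mutant and wildtype")
  if (any(mutantReps <= 0) || any(wtReps <= 0))
    stopf("fluorescence must be positive (log10 undefined otherwise)")
  lm. <- log10(mutantReps); lw <- log10(wtReps)
  varMut <- var(lm.) / length(lm.)
  varWt <- var(lw) / length(lw)
  list(m = mean(lm.) - mean(lw), se = sqrt(varMut + varWt),
       varMut = varMut, varWt = varWt,
       dfMut = length(lm.) - 1L, dfWt = length(lw) - 1L)
}

#' Intermolecular epistasis of one double mutant
#'
#' Epistasis is the deviation of the system double mutant from additivity of
#' its single-mutant log10 effects: `epsilon = m_system - (m_cis + m_trans)`.
#' The standard error adds the three terms' variances in quadrature
#' (`se^2 = se_sys^2 + se_cis^2 + se_trans^2`), the degrees of freedom follow
#' Welch-Satterthwaite over all contributing variance components, and the
#' two-sided p-value tests epsilon = 0.
#'
#' @param sys,cis,trans results of [relativeEffect()] for the double mutant
#'   and the two singles.
#' @return list with `epsilon`, `se`, `t`, `df`, `p` and `degenerate`
#'   (TRUE when se = 0 with epsilon != 0, reported as p = 0).
#' @export
epistasisStat <- function(sys, cis, trans) {
  eps <- sys$m - (cis$m + trans$m)
  v <- c(sys$varMut, cis$varMut, trans$varMut,
         sys$varWt, cis$varWt, trans$varWt)
  dfc <- c(sys$dfMut, cis$dfMut, trans$dfMut,
           sys$dfWt, cis$dfWt, trans$dfWt)
  se2 <- sum(v)
  se <- sqrt(se2)
  if (se == 0) {
    if (abs(eps) > 0) {
      warnf("zero propagated error with nonzero epistasis: p set to 0")
      return(list(epsilon = eps, se = 0, t = Inf * sign(eps), df = NA_real_,
                  p = 0, degenerate = TRUE))
    }
    return(list(epsilon = 0, se = 0, t = 0, df = NA_real_, p = 1,
                degenerate = TRUE))
  }
  pos <- v > 0
  df <- se2^2 / sum(v[pos]^2 / dfc[pos])
  t <- eps / se
  list(epsilon = eps, se = se, t = t, df = df,
       p = 2 * pt(-abs(t), df = df), degenerate = FALSE)
}

#' Epistasis analysis of a double-mutant panel
#'
#' Computes wildtype-relative effects, epistasis, propagated errors and
#' FDR-corrected significance for every pair in a replicate panel (as
#' produced by [generateDoubleMutantPanel()] or read by
#' [readMutantPanel()]). Epistasis is evaluated in the repressor-present
#' condition; the wildtype replicate set of the batch is shared across all
#' pairs.
#'
#' @param panel data.frame with columns `pair_id`, `role`, `condition`,
#'   `replicate`, `fluorescence` and optionally `location_label`.
#' @param condition condition in which epistasis is computed ("plus").
#' @param qThreshold FDR threshold for the sign classification.
#' @return data.frame with one row per pair: `m_cis`, `m_trans`, `m_sys`,
#'   their standard errors, `epsilon`, `se_epsilon`, `t`, `df`, `p`, `q`
#'   and `sign` ("positive", "negative" or "none"), plus location labels
#'   when present.
#' @export
epistasisPanel <- function(panel, condition = "plus", qThreshold = 0.05) {
  need <- c("pair_id", "role", "condition", "replicate", "fluorescence")
  if (!all(need %in% names(panel)))
    stopf("panel lacks columns: %s",
          paste(setdiff(need, names(panel)), collapse = ", "))
  px <- panel[panel$condition == condition, , drop = FALSE]
  wtReps <- px$fluorescence[px$role == "wildtype"]
  if (length(wtReps) < 2) stopf("panel needs >= 2 wildtype replicates")
  ids <- unique(px$pair_id[px$role == "double"])
  if (!length(ids)) stopf("panel contains no double mutants")
  rows <- lapply(ids, function(id) {
    sub <- px[px$pair_id == id, , drop = FALSE]
    reps <- function(role) sub$fluorescence[sub$role == role]
    for (role in c("cis", "trans", "double"))
      if (length(reps(role)) < 2)
        stopf("pair '%s' lacks replicates for role '%s'", id, role)
    eCis <- relativeEffect(reps("cis"), wtReps)
    eTrans <- relativeEffect(reps("trans"), wtReps)
    eSys <- relativeEffect(reps("double"), wtReps)
    st <- epistasisStat(eSys, eCis, eTrans)
    loc <- function(role) {
      l <- sub$location_label[sub$role == role]
      if (length(l)) l[1] else NA_character_
    }
    data.frame(pair_id = id, m_cis = eCis$m, m_trans = eTrans$m,
               m_sys = eSys$m, se_cis = eCis$se, se_trans = eTrans$se,
               se_sys = eSys$se, epsilon = st$epsilon,
               se_epsilon = st$se, t = st$t, df = st$df, p = st$p,
               cis_location = loc("cis"), trans_location = loc("trans"))
  })
  fdrClassify(do.call(rbind, rows), qThreshold = qThreshold)
}

#' FDR correction and sign classification of epistasis records
#'
#' Benjamini-Hochberg q-values across the panel; a pair is classified as
#' "positive" (observed double-mutant effect above the additive expectation)
#' or "negative" only when significant at the FDR threshold, otherwise
#' "none".
#'
#' @param records data.frame with columns `p` and `epsilon`.
#' @param qThreshold FDR threshold (default 0.05).
#' @return `records` with columns `q` and `sign` added/replaced.
#' @export
fdrClassify <- function(records, qThreshold = 0.05) {
  if (!nrow(records)) stopf("no records to classify")
  records$q <- p.adjust(records$p, method = "BH")
  records$sign <- ifelse(records$q < qThreshold,
                         ifelse(records$epsilon > 0, "positive", "negative"),
                         "none")
  records
}

#' Association between epistasis and mutation location
#'
#' Pearson chi-squared test of independence between the epistasis class
#' (positive / negative / none) and the physical location category of the
#' point mutation in the chosen component (trans: N-terminal, linker,
#' C-terminal; cis: operator, RNAP-contact, both, neither). Classes or
#' locations absent from the panel are dropped before testing; the standard
#' low-expected-count warning (< 5) is propagated.
#'
#' @param records classified records from [epistasisPanel()].
#' @param component "cis" or "trans".
#' @return list with `chi2`, `df`, `p` and the contingency `table`.
#' @export
locationAssociation <- function(records, component = c("cis", "trans")) {
  component <- match.arg(component)
  col <- paste0(component, "_location")
  if (!col %in% names(records) || any(is.na(records[[col]])))
    stopf("every record needs a %s location label", component)
  tab <- table(records$sign, records[[col]])
  tab <- tab[rowSums(tab) > 0, colSums(tab) > 0, drop = FALSE]
  if (ncol(tab) < 2)
    stopf("only one %s location category present: no degrees of freedom",
          component)
  if (nrow(tab) < 2)
    stopf("only one epistasis class present: no degrees of freedom")
  ct <- chisq.test(tab, correct = FALSE)
  list(chi2 = unname(ct$statistic), df = unname(ct$parameter),
       p = ct$p.value, table = tab)
}

#' Effect distributions of a panel, with pairwise K-S comparisons
#'
#' Extracts the repressed-condition wildtype-relative effect distribution of
#' each group of a panel (cis singles, trans singles, system doubles) and
#' compares the groups pairwise with two-sample Kolmogorov-Smirnov tests.
#'
#' @param records classified records from [epistasisPanel()].
#' @return list with `effects` (named list of numeric vectors) and `ks`, a
#'   data.frame of pairwise D statistics and p-values.
#' @export
dmeOfPanel <- function(records) {
  effects <- list(cis = records$m_cis, trans = records$m_trans,
                  system = records$m_sys)
  if (any(vapply(effects, length, integer(1)) < 2))
    stopf("each group needs >= 2 records")
  combs <- utils::combn(names(effects), 2)
  ks <- apply(combs, 2, function(pr) {
    kt <- suppressWarnings(ks.test(effects[[pr[1]]], effects[[pr[2]]]))
    data.frame(group_a = pr[1], group_b = pr[2],
               D = unname(kt$statistic), p = kt$p.value)
  })
  list(effects = effects, ks = do.call(rbind, ks))
}
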