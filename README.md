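# DMEpistasis

Distributions of mutational effects (DMEs) and intermolecular epistasis in a
repressible promoter system.

## The problem

A transcriptional repression system of the λ-switch type has three
interacting parts: RNA polymerase, a repressor protein (the *trans*-element,
e.g. CI), and the promoter/operator DNA they both bind (the *cis*-element).
Mutagenizing each component alone yields characteristic distributions of
mutational effects on gene expression — graded for the DNA element, bimodal
(functional vs loss-of-function) for the protein. Mutagenizing the whole
system at once yields a DME that no additive model of the component effects
reproduces: the excess of intermediate phenotypes is *intermolecular
epistasis*, and most of it traces back to the regulatory structure itself —
cis mutations affect the binding of both proteins, and loss-of-function
repressor mutants turn the promoter constitutive.

DMEpistasis implements that analysis as a tested, reusable pipeline for
anyone working with flow-cytometry expression distributions of mutant
libraries:

- **DME estimation** — shared-grid binning of per-cell log10 fluorescence,
  phenotype categories bounded by >99.9% wildtype coverage, Shannon entropy
  `S = -Σ_k P_k ln P_k + ln Δx` with bootstrap errors and permutation tests,
  K-S subsampling robustness.
- **Convolution null models** — the additive expectation for the system DME
  `F_expected = f_cis * F_trans`, built by forward-fit deconvolution of the
  "true" cis component (three-parameter gamma, least squares against
  `f_γ * F_wt`), high-expression peak removal (fraction α), a smooth ceiling
  at the maximal attainable expression, and an add-back that is either the
  unrepressed wildtype ("naive") or the unrepressed cis DME
  ("structured", encoding the regulatory structure).
- **Partition predictions** — FACS-style sorting of libraries into phenotype
  bins, factorial recombination of partitions, trans-frequency-weighted
  prediction of system category frequencies, and the sorting-accuracy null.
- **Epistasis panels** — for double mutants,
  `ε = m_system − (m_cis + m_trans)` on log10 scale with error propagation,
  Welch–Satterthwaite degrees of freedom, Benjamini–Hochberg FDR, sign
  classes, and mutation-location association tests.
- **Expression noise** — subsampled coefficients of variation and per-stratum
  ANOVA for constancy of noise across mutants.
- **Synthetic generator** — mutant libraries with Poisson mutation counts,
  independent per-mutation cis effects on RNAP and operator binding, bimodal
  trans functionality, constant-CV log-normal measurement noise, an
  expression ceiling and a deep-repression floor, with full ground truth for
  recovery tests.

## Worked example

```r
library(DMEpistasis)

cfg <- syntheticConfig(mutationRate = 0.01, nMutants = 5000,
                       cellsPerLibrary = 2e5, seed = 11)
res <- runPipeline(cfg, outDir = "demo_out", nPairs = 50, nIsolates = 8,
                   nEffective = 1000, partitionCells = 5e4)
res$entropy
#>   library          S          sd
#>       cis -0.1275247 0.002428790
#>     trans  0.5944028 0.002108842
#>    system  0.8124977 0.002044866
res$convolution$chi2$naive$chi2
#> [1] 37.86277
res$convolution$chi2$structured$chi2
#> [1] 10.22658
table(res$epistasis$records$sign)
#> negative     none positive
#>        4       32       14
```

The entropy table says the system DME (S ≈ 0.81 nats) covers the expression
range more uniformly than either component DME (cis ≈ −0.13, trans ≈ 0.59):
mutating both components at once creates phenotypes neither reaches alone.
The chi-squared values compare observed system category frequencies with the
two convolution predictions at an effective count of 1,000: the naive
additive prediction is strongly rejected (χ² ≈ 38) while the
structure-aware prediction is several-fold closer (χ² ≈ 10) —
knowing that cis mutations affect both RNAP and repressor binding is what
makes the system predictable. The epistasis table classifies the
double-mutant panel: significant pairs are mostly in positive epistasis
(double mutant higher than the additive expectation), the signature of
cryptic repressor variation revealed by operator-weakening cis mutations.

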