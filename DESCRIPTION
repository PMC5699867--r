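Package: DMEpistasis
Title: Distributions of Mutational Effects and Intermolecular Epistasis in a
    Repressible Promoter System
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Estimates distributions of mutational effects (DMEs) of a
    transcriptional repression system and of its cis- and trans-components from
    per-cell log10 fluorescence measurements; quantifies distribution shape by
    Shannon entropy with bootstrap errors and permutation tests; builds additive
    null predictions of the system DME by convolution of component DMEs, both
    naively and accounting for the genetic regulatory structure of a repressible
    promoter; forms partition-weighted experimental predictions emulating
    FACS-sorted phenotype bins; computes intermolecular epistasis with error
    propagation and FDR-corrected significance for double-mutant panels; and
    tests constancy of gene-expression noise. A synthetic-data generator
    reproduces the statistical structure of the assayed system (bimodal
    trans-element effects, graded cis-element effects on polymerase and operator
    binding, Poisson mutation counts, constant-CV measurement noise, an
    expression ceiling) with full ground truth for recovery tests.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports: methods, stats, utils
Suggests: testthat (>= 3.0.0), jsonlite, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'utils.R'
    'synthetic.R'
    'dme.R'
    'convolution.R'
    'epistasis.R'
    'partition.R'
    'noise.R'
    'io.R'
    'pipeline.R'
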