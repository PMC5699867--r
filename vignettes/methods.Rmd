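---
title: "Models and methods behind DMEpistasis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind DMEpistasis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(DMEpistasis)
```

# Scope

DMEpistasis analyzes distributions of mutational effects (DMEs) of a
repressible promoter system and of its cis- and trans-components, and asks
how much of the system's behaviour an additive model of component effects
can explain. This vignette records the models, the tunable parameters, the
numerical choices, and the design decisions that were genuinely open —
together with what the synthetic-data generator does and does not emulate.

# The measurement model

The phenotype is log10 fluorescence per cell. A library's observed DME `F`
is the convolution of its noise-free effect distribution `f` with the
measured wildtype distribution, `F = f * F_wt`, which holds when
measurement noise is constant across genotypes and expression levels. The
generator enforces exactly that: per-cell linear-scale fluorescence is
log-normal around the genotype's true level with a constant coefficient of
variation (`noiseCV`, default 0.4, a typical flow-cytometry value for a
fluorescent reporter), centred so the true level is the geometric mean of
the cells. Population-level (plate-reader) replicates use an independent,
smaller constant-CV term (`plateNoiseCV`, default 0.1).

All DMEs live on one `ExpressionGrid`: bin width 0.05 log10 units, edges
aligned to the grid origin, range set once from the minimum and maximum of
the full dataset. Bins are half-open `[a, b)` with the top edge closed.
Shannon entropy is `S = -Σ_k P_k ln P_k + ln Δx` in natural log (entropy
differences and permutation tests are base-invariant; absolute values are
reported in nats). The `ln Δx` term makes S a discrete estimate of
differential entropy, so estimates are stable under refining the bin width
— the suite checks this at Δx ∈ {0.1, 0.05, 0.025}. Entropy errors come
from a 200-resample bootstrap of the underlying cells; entropy differences
are tested by permuting pooled cells with the `(1 + #{≥ obs}) / (B + 1)`
correction so p is never exactly zero.

Phenotype categories ("no expression", "intermediate", "high expression")
are bounded by one-sided 99.9% empirical quantiles (linear interpolation)
of the repressed and unrepressed wildtype distributions; boundary values
belong to the outer categories. Intermediate phenotypes are by construction
levels the wildtype cannot produce.

# The regulatory model of the generator

Each genotype carries three numbers: a summed log10 RNAP-activity factor
`a ≤ 0` and operator-binding factor `b ≤ 0` for its cis mutations, and a
residual repressor functionality `φ ∈ [0, 1]` for its trans mutations.
True mean expression follows occupancy competition:

- without repressor: `max(log10EHi + a, background)`;
- with repressor: `max(log10EHi + a − log10(1 + ρ0 φ 10^b), background)`,

with `ρ0 = 10^log10RepressionFold − 1`.

`log10RepressionFold` (default 3.5 decades) deliberately exceeds the
measured dynamic range (`log10EHi − log10ELo` = 2.5 decades): the repressed
wildtype sits at the autofluorescence floor, and about one decade of
repression is phenotypically invisible. This is the single most consequential
modelling choice in the package. It reflects how a tightly repressed
promoter behaves — the repressed wildtype is indistinguishable from
autofluorescence — and it is what makes intermolecular epistasis
bidirectional: under a calibration where the wildtype's repression exactly
equals the visible range (`ρ0 = 10^(EHi−ELo) − 1`), one can show that the
occupancy formula permits only ε ≤ 0, because
`log10(1 + ρ0 b) + log10(1 + ρ0 φ)` always exceeds
`log10(1 + ρ0 φ b) + log10(1 + ρ0)`. With cryptic repression, a partially
disabled repressor (say φ = 0.1) still drives the wildtype promoter to the
floor — its single-mutant effect is zero — but on an operator-weakened cis
background the double mutant rises well above what the cis single predicts:
positive epistasis, the dominant sign in real panels. Loss-of-function
trans mutations (φ = 0) paired with RNAP-impairing cis mutations give the
negative sign: the system becomes a constitutive two-component promoter
whose level only the cis RNAP channel sets.

Per-mutation effects: mutation counts are Poisson (`rate × length`; 84 nt
cis, 714 nt trans). Each cis mutation is neutral with probability 0.5 per
channel and otherwise contributes an exponential log10 decrease (mean 0.5
decades on RNAP activity, 0.7 on operator binding), independently for the
two channels — reproducing graded cis DMEs with a tunable neutral
fraction. Trans mutants lose function with a per-mutation escalating
probability (0.035 per mutation), otherwise φ is drawn once per mutant
from Beta(1, 4.5). The loss-of-function rate and the Beta law are
calibrated so a low-mutation-probability trans library splits roughly
0.69 / 0.10 / 0.22 across the three phenotype categories — the partition
weights of the assayed trans library. Note that under deep repression most
functional-but-perturbed repressors still show "no expression"; only
φ below about 0.03 becomes visible as an intermediate phenotype.

A `religationFraction` of each library is exact wildtype plasmid
(default 0; real libraries carry a small percentage). An optional
`coupling = "additive"` mode generates coupling-free system libraries in
which the system phenotype is the sum of each component's *observed*
single-mutant effect (each individually floored at background), capped at
the ceiling — the world in which the additive null is true by
construction, used to validate the null pipeline. An earlier design that
decoupled the two cis channels instead was rejected: operator-only effects
saturate against the ceiling and create an atom that no smooth component
family can represent, which tests the generator rather than the method.

What the generator does **not** emulate: scatter-gate artifacts,
instrument saturation and binning of the cytometer, day effects between
replicates, growth-rate differences among mutants, sequence-level
mutation maps, and repressor-operator *specificity* changes (a mutant CI
preferring a mutant operator); the last of these is a real source of
epistasis the occupancy model cannot produce, so tests passing here show
the pipeline detects regulatory-structure epistasis, not that it captures
every interaction in real data.

# Convolution null models

The additive expectation for the system DME is `f_cis * F_trans`. Because
numerical deconvolution is unstable, the true cis component is
reverse-engineered: `f_cis` is assumed three-parameter gamma (shape, scale,
location) and fitted so that its discrete convolution with `F_wt` matches
the observed cis DME in least squares. The optimizer is Nelder-Mead from a
deterministic lattice of 8–16 starts (shape ∈ {0.5, 1, 2, 5},
scale ∈ {0.1, 0.5}, location ∈ {0, observed mean shift}), parameters on log
scale with a 10⁻³ floor; the best SSE wins. The gamma is discretized by
CDF differences on offset bins *centred* at multiples of Δx — centring
matters, as edge-aligned offsets bias the fitted location by half a bin.
Out-of-grid mass folds into the edge bins during fitting. Discrete
convolution runs via FFT.

The system prediction then (i) removes the high-expression
(loss-of-function) peak from the trans DME as `α · F_wt⁻`, with α fitted by
closed-form least squares over the bins at or above the mode of `F_wt⁻`
(the left flank is contaminated by intermediate phenotypes); (ii) convolves
the remainder with the fitted `f_cis`; (iii) applies a smooth ceiling; and
(iv) adds back mass `α` plus the ceiling excess as `F_wt⁻` (naive) or as
the unrepressed cis DME `F_cis⁻` (structured — loss-of-function trans
mutants make the promoter constitutive, so their expression follows the
cis RNAP channel).

The ceiling is a logistic keep-weight `w(x) = 1/(1 + exp((x − c)/τ))` with
`τ = 2Δx`. Its centre `c` defaults to the *mean* of `F_wt⁻`, not an upper
percentile: the cap acts on true expression, and measurement noise spreads
capped genotypes over the whole wildtype-high distribution, so the
probability that observed mass at level x originates below the cap crosses
1/2 at the wildtype's central level. With noise SD ≈ 0.17 log10 units,
`τ = 2Δx = 0.1` matches the logistic approximation of the corresponding
normal tail. Both `c` and `τ` remain user parameters.

Category-frequency comparisons use Pearson χ² with df = 2. Printed
frequencies carry no sample size, so the effective count is an explicit
parameter; the package default is 30,000 (the number of uniquely
transformed mutants per library) and the pipeline reports sensitivity at
1,000, which is what the shipped summaries use.

# Partition predictions

`sortLibrary` assigns every cell to a phenotype bin on a *single* noisy
draw — a FACS machine sorts on one pass — so genotypes spill across bins
exactly as the noise model dictates. Re-measuring sorted pools with fresh
draws gives the sorting-accuracy null. The nine partition-combination
libraries cross each trans pool with each cis pool (the cis library sorted
without repressor, i.e. by RNAP binding alone) and are measured with
repressor. The prediction weights each trans partition's pooled cells by
the partition's realized frequency in the original trans library. Within a
trans partition the three cis cells are pooled with equal weight — the
convention of the experimental workflow, where the same cloned material
represents each cis partition — or, optionally, by the realized cis
partition frequencies (`cisWeighting = "realized"`). Self-consistency
against a directly simulated combined library holds only for the realized
weighting (equal thirds mis-states the cis composition by construction,
a few percentage points here); the package tests self-consistency with the
realized variant and exercises the equal convention in the
prediction-vs-null ordering checks.

# Epistasis panels

For a double mutant, `ε = m_system − (m_cis + m_trans)` with all effects
wildtype-relative mean log10 fluorescence; deviation from additivity in
log10 equals deviation from multiplicativity on the linear scale.
`se_ε² = se_sys² + se_cis² + se_trans²` by error propagation, each term
carrying the mutant's and the wildtype's replicate variances. Degrees of
freedom follow Welch–Satterthwaite over all contributing variance
components (replicate variances are not assumed equal). The wildtype
replicate set is shared across a batch; its variance is counted once per
term and the induced covariance between terms is ignored — a conservative
approximation (it overstates `se_ε` by up to √1.5 when all terms share one
wildtype set), so the package's significance calls err toward fewer
discoveries. The calibration tests therefore use independent wildtype
reference sets per term, where the test is exact. Epistasis is evaluated
in the repressor-present condition. Benjamini–Hochberg q-values classify
pairs as positive / negative / none at q < 0.05; location association uses
the general r×c Pearson χ² on sign class × location category, dropping
empty rows/columns and propagating the standard expected-count-below-5
warning.

# Noise analysis

Gene-expression noise is the CV of linear-scale fluorescence over ten
5,000-read subsamples of a mutant's pooled cells. When the pool allows,
subsamples are disjoint blocks of one permutation, making the CV
replicates independent — overlapping subsamples inflate the between-mutant
ANOVA F by roughly `1 + n_sub · subSize / pool`, a 25% inflation even at a
200,000-read pool, enough to triple the nominal type-I rate. Mutants are
stratified into expressing and non-expressing (≥ 99% of cells in the
no-expression category; the threshold is our choice, as the stratification
rule is qualitative in origin) because the fluorescence channel reads
autofluorescence, not reporter output, in the non-expressing stratum.

# Problem sizes and reproducibility

Library-scale checks run at 30,000 mutants and 10⁶ cells per library and
condition — the scale of the assayed libraries — in the acceptance script,
and at reduced sizes (2,000–10,000 mutants, 5×10⁴–2×10⁵ cells) in the test
suite, chosen so that Monte-Carlo error stays well inside each check's
tolerance. Every stochastic step takes an explicit seed; seeds for
sub-steps derive from one master seed, and identical configuration plus
seed reproduces results bit for bit.

# Known limitations

- The gamma family is an approximation to the true cis effect law (a
  point-mass-plus-continuum mixture); at very low mutation rates the fitted
  component is dominated by the near-neutral spike and the prediction error
  of the naive null is correspondingly larger.
- The occupancy model cannot represent repressor-operator specificity
  changes, so panels generated here under-produce the strongest positive
  epistasis seen in designed experimental panels.
- The χ² effective count is a modelling parameter, not an estimate;
  conclusions should be checked across a range (the pipeline reports 1,000
  by default precisely to keep the statistic conservative).
- Plate-reader panels treat replicate means as log-normal; instrument
  saturation and background subtraction artifacts are not modelled.
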