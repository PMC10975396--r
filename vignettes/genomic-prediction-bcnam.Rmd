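---
title: "Genomic prediction in backcross-NAM hybrid breeding: models, simulator and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genomic prediction in backcross-NAM hybrid breeding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nampred)
```

## The problem

Backcross nested association mapping (BC1-NAM) populations introgress exotic
diversity into an elite genetic background: each family derives from
(elite x exotic) x elite, so every line shares the same elite recurrent
parent and carries, in expectation, 25% of one exotic donor genome. Before
such lines can feed a hybrid breeding program they must be evaluated in
testcross combinations — an expensive proposition when families hold dozens
of lines each. `nampred` implements the full analysis path for this setting:
multi-environment trial adjustment, genomic relationship kernels from
in-silico hybrid genotypes, a Bayesian multi-kernel GBLUP, and the
family-representation cross-validation ladder (CV0–CV7) that asks how many
lines per family must be phenotyped before the rest can be predicted.

Because the package must be testable without access to field data, it ships
a first-class simulator of the whole design with known genetic truth.

## The prediction model

The central fitter, `bgblup()`, works on per-environment hybrid values
(typically within-environment BLUEs) and fits

y = Z_E beta + u_A + u_D + u_AE + u_DE + e,

where `beta` are fixed environment means (absorbing the intercept — with a
full-rank environment coding a separate grand mean would be confounded, so
none is carried), `u_A` and `u_D` are main additive and dominance hybrid
effects shared across environments with covariances `Z K_A Z' s2_A` and
`Z K_D Z' s2_D`, and the interaction terms have the environment-masked
covariances `K_AE = (Z_E Z_E') ⊙ (Z_A K_A Z_A')` (likewise `K_DE`): two
observations covary through the interaction only when they share an
environment. `K_A` is the VanRaden method-1 genomic relationship computed
from hybrid genotypes built by averaging the two parental inbreds at every
marker; `K_D` uses the classical dominance recode `(-2q², 2pq, -2p²)`.
Allele frequencies for both kernels are taken from the hybrids entering the
model, and kernels are computed once on the union of all hybrids and
sub-indexed per cross-validation split so folds stay comparable.

### Sampling scheme and priors

Each random vector is sampled in the eigenbasis of its observation-level
kernel: with `K = U S U'` and orthonormal `U`, the full conditional of the
eigen-coefficients is diagonal, so one Gibbs update costs two matrix-vector
products. Eigenvalues at or below 1e-10 are dropped — effects live in the
kernel's range space, which also makes rank-deficient kernels (duplicated
hybrids) unproblematic. Variance components get scaled inverse-chi-square
full conditionals with prior degrees of freedom 5 and prior scales chosen so
every variance's prior mean is an equal share of `var(y)` — the convention
of the Bayesian kernel-regression solver family this model belongs to.
Defaults are 10,000 iterations, 1,000 burn-in, thinning 2; the
cross-validation experiments in this package use 1,500/300/2, at which the
posterior means that enter accuracies are stable to well under the
repeat-to-repeat noise (the oracle test below bounds sampler error at 2% of
the response scale).

Missing responses are excluded rows rather than data-augmented: the
cross-validation design holds out whole lines, and `predict.bgblup()`
projects posterior-mean effects onto held-out observations through the
kernel cross-covariances (`K_cross K_train^+ u_hat`, computed in the
retained eigenspace). An in-sample observation therefore predicts exactly
its fitted value, and an untested hybrid borrows information purely through
relationship.

### Correctness anchors

Two independent oracles guard the sampler. With all variances fixed, the
posterior mean of every effect must agree with the closed-form GLS/BLUP
solution (explicit matrix inversion) to an RMS of 2% of the response SD on
small fixtures. And on data simulated from the generative model itself
(150 hybrids, 3 environments), the posterior means of the additive and
residual variances must land within 50% of truth as a median over 10 seeds.
Both checks run in the test suite.

## Trial models

Within each environment, `fit_env_blues()` fits
`trait ~ genotype + (1|block) + (1|range) + (1|row)` with genotype fixed
(REML via lme4), and `fit_env_varcomp()` refits with genotype random to get
the variance components behind repeatability `R = s2_g / (s2_g + s2_e / r)`.
Unreplicated augmented layouts remain estimable because the replicated
checks inform the random design terms; when every genotype sits on a single
plot the genotypic and residual variances are confounded and the result is
flagged rather than reported. The residual coefficient of variation is
`CVe = 100 * sqrt(MSE) / mean`: the root-MSE convention is used because a
variance divided by a mean has the trait's units and is not comparable
across traits; output metadata records this convention.

The multi-environment general-combining-ability model
(`fit_gca_multienv()`) keeps the male (pollinator) lines fixed and treats
environments, nested design factors, female testers and all interactions as
random; each male's BLUE is compared to a named check by a per-comparison
Student's t-test at alpha = 0.05, with no multiplicity adjustment — the
screening convention for identifying candidate lines, not a confirmatory
analysis.

## The simulator and the packaged benchmark

`simulate_bc1_family()` builds lines by F1 -> one backcross to the
recurrent parent -> configurable selfing generations (default 3, giving
BC1F4), with meiosis under the Haldane model (Poisson crossovers, no
interference) on a centimorgan map. Parental origin is tracked separately
from allele state, so identity-by-descent with the recurrent parent is
exact. Selection for major dwarfing/maturity genes is modelled as rejection
sampling of finished lines at designated loci — matching a program that
screens finished lines for agronomic desirability rather than truncating
every generation. Donor divergence is realized by flipping a seeded random
subset of recurrent alleles, since no donor allele-frequency spectrum is
available; how many selfing generations separate BC1F1 from the evaluated
seed increase is not documented for the motivating material, so 3 is the
configurable default. Two checks anchor the simulator: unselected BC1
genomes average 75% recurrent alleles (the Mendelian expectation, verified
against single-locus gamete enumeration), and selection at four unlinked
loci pushes the mean above 75%.

`nam_benchmark()` assembles the full scaled-down study: 14 families
(2 near-complete core families of 24 lines, 12 partially-sampled families
of 2–18 lines, echoing the very uneven line counts of a real program),
1,500 markers on 10 chromosomes, testcrosses to 2 elite seed-parent
testers, and 3 environments (one unreplicated augmented with replicated
checks, two RCBD with 2 replications). Family sizes, marker density and
environment count are scaled down from the motivating design so that a full
cross-validation experiment runs on a desk machine in minutes; the vignette
and tests state the sizes actually used.

### What the genetic architecture emulates — and why

The benchmark's two traits are designed around the phenomena the
cross-validation ladder is supposed to expose:

- **Family structure is real.** Lines within a family descend from 2 BC1F1
  plants (`n_bc1_plants = 2`), so sibs share which donor segments segregate
  at all — without this, independently-derived BC1 lines are nearly
  unrelated at segregating markers and family representation cannot matter.
- **Donors differ in combining ability.** Each trait carries a family main
  effect (`F` variance): the aggregate effect of a donor genome that
  markers under a genome-wide kernel track only weakly. This is the
  component that phenotyping a couple of lines per family reveals.
- **Exotic alleles are partly private.** The `mixed` architecture adds to a
  polygenic kernel-distributed component a finite-QTL component drawn from
  markers carried by exactly one donor, with a per-trait private fraction.
- **Traits differ in heritability and architecture.** `anthesis` is
  high-heritability (plot residual variance 0.3 against additive variance
  1.0) with a large family effect and a small private fraction (0.1): its
  family effects are learned from two lines per family, after which the
  ladder plateaus. `yield` is low-heritability (residual 2.0) with half its
  QTL variance private: its family effects are learned slowly and accuracy
  keeps climbing to five-seven lines per family. Elite testers diverge from
  the recurrent parent far less (0.08) than the exotic donors (0.35), as
  elite pools are mutually much closer than either is to unadapted
  accessions.

What the simulator does **not** emulate: real linkage disequilibrium decay
and allele-frequency spectra (donor alleles are flipped uniformly), GBS
missingness/error patterns (genotypes are complete and error-free; the QC
module is exercised on constructed fixtures instead), selection during line
development beyond the major-locus screen, and spatial field trend beyond
i.i.d. block/range/row effects. Passing the cross-validation tests
therefore shows that the pipeline orders training-set designs correctly
under a faithful genetic mechanism — not that real-data accuracies would
match the simulated values.

## Cross-validation design

`build_scheme()` realizes the CV0–CV7 ladder: training = two core families
+ checks + k seeded-random lines from every remaining family; validation =
every other line; all hybrids of a line move together, and families with
fewer than k lines contribute all of them (a 2-line family cannot supply
seven). Checks are training-only. Accuracy is the Pearson correlation
between predicted and observed per-environment BLUEs of the validation
observations, pooled within trait — the convention of the kernel-regression
literature this model family comes from; per-family accuracies can be
derived from the returned table for diagnosis. Scheme means are compared by
Tukey's HSD on the studentized range with the Tukey–Kramer adjustment for
unequal repeat counts, flagging every scheme statistically indistinguishable
from the best.

## Numerical choices

- Kernel eigenvalue floors: 1e-8 when drawing multivariate-normal truth in
  the simulator (PSD safety), 1e-10 when preparing kernels for sampling
  (components below it are dropped, not inflated).
- Nei's distance (1972 standard form, computed from per-line allele
  frequencies 0/0.5/1) is capped at ln(1e6) when two lines share no alleles
  anywhere, keeping the matrix finite for principal-coordinate analysis.
  Which Nei variant the motivating analysis used is not documented; the
  standard form is implemented and recorded here.
- "PCA of the genetic distance" is realized as classical metric scaling
  (PCoA) — the standard reading of a PCA applied to a distance matrix; a
  genotype-matrix PCA (`parent_pca()`) is provided for comparison.
- Numeric coding ties (a 50/50 allele split) go to the lexicographically
  smaller allele, so coding is deterministic.
- Marker filters run in a fixed order (parental call fraction >
  missingness > indel > MAF > heterozygosity), attribute each dropped
  marker to the first rule it fails, and compute MAF/heterozygosity after
  simple major-allele imputation, mirroring a pipeline that imputes between
  the missingness and frequency screens. MAF is computed across all
  genotyped lines, not parents only.
- Master seed -> stage seed derivation in `run_pipeline()` uses a fixed
  per-stage offset, so adding a stage never perturbs an earlier stage's
  stream.

## Problem sizes used in the shipped experiments

Unit and acceptance tests run the simulator at 500 lines x 1,000 markers
(genome expectations), the sampler oracle at 40 observations, parameter
recovery at 150 hybrids x 3 environments over 10 seeds, and the
cross-validation ladder on the default benchmark (165 lines, 167 hybrids,
3 environments) with 20 repeats per scheme at 1,500 Gibbs iterations.
These sizes are the package's reference experiment; all are arguments, and
larger runs only require changing them.

## Known limitations

- The Gibbs sampler stores thinned variance draws but only running means of
  effect vectors; posterior uncertainty of individual hybrid predictions is
  not reported.
- `fit_gca_multienv()` uses a normal-approximation t-test on the fixed-male
  contrasts with residual degrees of freedom; no Kenward–Roger correction.
- The dominance recode interpolates linearly for fractional hybrid codes
  (parents with residual heterozygosity); exact within-family dominance of
  non-inbred parents is out of scope.
- Epistatic and marker-weighted (fixed-effect SNP) kernels are not
  implemented.
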