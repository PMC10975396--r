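Package: nampred
Title: Genomic Prediction and Trial Analysis for Backcross-NAM Hybrid Breeding
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Simulation and analysis tools for backcross nested association
    mapping (BC1-NAM) hybrid breeding programs. Provides a seeded simulator of
    BC1-derived inbred families (Haldane meiosis, selfing, selection at major
    loci), testcross hybrid construction and multi-environment trial phenotypes
    with known genetic truth; marker quality control, numeric genotype coding,
    in-silico hybrid genotypes, Nei genetic distance and principal-coordinate
    analysis; per-environment mixed-model BLUEs, variance components,
    repeatability and residual coefficient of variation; VanRaden additive,
    dominance and genotype-by-environment relationship kernels; a Gibbs-sampled
    Bayesian multi-kernel GBLUP fitter with prediction of untested hybrids; and
    family-representation cross-validation schemes (CV0-CV7) with Tukey HSD
    comparison of prediction accuracies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    graphics,
    lme4,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    optparse,
    knitr
Config/testthat/edition: 3
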