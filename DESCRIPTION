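Package: splitmig
Title: Two-Population Demographic Inference from the Joint Site Frequency Spectrum
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for inferring two-population split-with-migration demographic
    histories from the joint site frequency spectrum (SFS). Implements a
    structured-coalescent Monte-Carlo engine for expected joint-SFS computation
    under four demographic scenarios (isolation, symmetric, asymmetric, and
    time-gated asymmetric migration) with a stepwise ancestral expansion and a
    bottleneck-plus-exponential-recovery derived population; Poisson
    composite-likelihood fitting with analytic profiling of the mutation
    parameter, AIC model choice, and parametric-bootstrap confidence intervals;
    SFS summary statistics (Watterson's theta, nucleotide diversity, Tajima's D,
    Hudson's Fst), recombination-class partitioning with a Pearson chi-squared
    SFS-skew test, and genotype PCA; time-binned within- and cross-population
    coalescence rates and the relative cross-coalescence rate (RCCR); and
    conversion between coalescent-scaled and physical units. Includes a
    synthetic-data generator emulating paired haploid population samples and
    readers/writers for VCF, BED, recombination maps, and dadi-style text SFS.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    tibble,
    dplyr,
    rlang,
    ggplot2,
    generics,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    knitr,
    ape
LinkingTo: Rcpp
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
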