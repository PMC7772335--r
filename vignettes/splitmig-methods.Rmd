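---
title: "Inferring two-population demographic histories from the joint SFS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring two-population demographic histories from the joint SFS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(splitmig)
```

## The model

`splitmig` fits the demographic history of a pair of populations — an
ancestral-range ("African-like", AF) population and a derived
("European-like", EU) population — to the joint site frequency spectrum
(SFS) of two samples of haploid genomes. The shared backbone of all four
scenarios, read forwards in time, is:

1. an ancestral population of size $N_{ANC}$ expands stepwise to
   $\nu_{af} N_{ANC}$ at time $T_{exp}$;
2. at $T_{split}$ a derived population splits off and is instantaneously
   reduced to a bottleneck size $\nu_{bot} N_{ANC}$, while the ancestral
   population keeps its size;
3. the derived population recovers exponentially, reaching
   $\nu_{eu} N_{ANC}$ at the present.

The four scenarios differ only in gene flow after the split: none
(`NOMIG`), symmetric (`SYMIG`), asymmetric (`ASYMIG`), or asymmetric
starting only at a later onset time $T_{mig}$ (`RASYMIG`). Free parameter
counts are 5, 6, 7 and 8.

All quantities are handled internally in coalescent units: population
sizes relative to $N_{ANC}$, times in units of $2 N_{ANC}$ generations
before the present, and migration rates scaled as $M = 2 N_{ANC} m$. The
pairwise coalescence rate within a population of relative size $\nu(t)$ is
$1/\nu(t)$, and a lineage currently in population $P$ jumps (backwards in
time) to the other population at the scaled rate of the forward direction
*into* $P$. The source literature for this class of models does not state
a direction convention for the printed migration rates, so the package
fixes this one and uses it consistently; the choice does not affect
goodness of fit, only the labelling of the two rates.

Two modelling details were genuinely open and were resolved as follows.

* **Recovery onset.** The derived population "can recover exponentially"
  after the bottleneck; no recovery start time is given. The package
  starts exponential growth immediately after the instantaneous
  bottleneck, so $\nu_{EU}(t) = \nu_{eu} (\nu_{bot}/\nu_{eu})^{t/T_{split}}$
  over the whole $(0, T_{split})$ interval. This is the simplest reading
  and matches common practice for this model family.
* **Ancestral size after the split.** The African-like population keeps
  its post-expansion size $\nu_{af}$ between the split and the expansion
  (backwards in time) and size 1 earlier.

## Monte-Carlo expected spectra

The expected joint SFS is computed by simulating structured-coalescent
genealogies (a compiled event-driven sampler) and summing branch lengths
by the number of descendant leaves each branch has in the two samples: a
branch subtending $(i, j)$ leaves contributes sites with derived counts
$(i, j)$ at rate $\theta/2$ per unit branch length. The factor $\theta/2$
makes the expected pairwise diversity of a sample of two equal $\theta$,
consistent with $\theta = 4 N_{ANC} \mu L$. Waiting times during the
derived population's exponential epoch are drawn by analytic inversion of
the cumulative coalescence intensity, not by time stepping, so epoch
boundaries are exact.

The primary convention check is the classical neutral expectation: for a
single constant-size population the expected spectrum per unit $\theta$ is
$E[\xi_i] = 1/i$. The test suite verifies this to within Monte-Carlo
error, together with the panmictic limit of a two-deme model under strong
migration (against the hypergeometric split of the pooled spectrum) and
the $E[T_{MRCA}] = 1$ identity for pairs.

## Likelihood, optimization and model choice

Fitting uses the Poisson random-field composite likelihood: each unmasked
SFS entry is treated as an independent Poisson count with mean
$\theta \, E_{ij}(\Theta)$. The mutation parameter $\theta$ is profiled
analytically ($\hat\theta = \sum S_{ij} / \sum E_{ij}$), is therefore not
counted among the $k$ free parameters used for AIC, and — because it is
profiled identically in all four models — leaves $\Delta$AIC unchanged
under the alternative counting.

Because the expected spectrum is a Monte-Carlo average, the package uses
common random numbers: one fixed genealogy seed is reused for every
likelihood evaluation within a fit, which makes the objective a smooth,
deterministic function of the parameters and hence optimizable by
derivative-free search. Optimization is multi-start Nelder–Mead in
log-parameter space ($T_{exp}$ is parameterized as
$T_{split} + e^{x}$ to enforce the event ordering, and the migration
onset as a logistic fraction of $T_{split}$), with box bounds enforced by
penalty. Starts after the first perturb the initial point by lognormal
factors ($\sigma = 0.5$). Each Nelder–Mead run restarts its simplex once
from its own endpoint, which protects against premature simplex collapse.

Optimizing a noisy-but-fixed surface leaves a bias of order the
Monte-Carlo error (the optimizer partly fits the noise realization of the
common-random-number stream). `fit_model()` therefore supports a
refinement phase: the best start endpoints are re-optimized under a fresh,
higher-precision stream (`n_mc_refine`), which measurably reduces this
bias. The default evaluation budget is 20,000 genealogies per likelihood
evaluation; the test suite uses smaller budgets (500–10,000) with
refinement, which the recovery tests show is sufficient at the spectrum
masses they use.

Numerical details worth knowing:

* Monte-Carlo zeros in expected cells that carry observed counts are
  floored at $10^{-12}$ before taking logs, so the objective stays finite
  and strongly repels such parameter regions.
* An all-zero observed spectrum is rejected; an identically zero expected
  spectrum with nonzero data is an error.
* Migration rates are searched down to $10^{-8}$, so nested-model
  comparisons can effectively switch migration off.

Model choice ranks fits by AIC ($2k - 2\ln L$) with ties broken toward
fewer parameters.

## Parametric bootstrap

Confidence intervals follow the parametric-bootstrap recipe: simulate
pseudo-observed spectra from the fitted model, re-fit the same scenario to
each, convert every replicate to physical units, and take 2.5–97.5
percentiles (the default is 150 replicates). Pseudo-data are independent
Poisson draws around the fitted expectation — exactly the model the
likelihood assumes; full genealogy re-simulation is available via
`method = "resim"`. Replicate re-fits warm-start at the fitted optimum
and should use the *same* evaluation settings as the original fit: the
intervals then reflect the total variability of the estimation procedure,
including the Monte-Carlo surface noise. Percentile intervals can exclude
the point estimate (the `point_in_ci` flag reports this rather than
"correcting" it), and with few replicates the percentiles are degenerate —
a warning is emitted below 10.

## Physical units

Scaled estimates convert to individuals and years with
$N_{ANC} = \hat\theta / (4 \mu L)$ and
$T_\text{years} = T \cdot 2 N_{ANC} / g$. Defaults are the empirical
*Drosophila melanogaster* values the package targets: $\mu = 5.21 \times
10^{-9}$ per bp per generation, $g = 15$ generations per year, and an
effective autosomal intronic length $L = 4{,}020{,}733$ bp (the X-linked
analysis uses the same machinery with its own $L$; no X-specific effective
size rescaling is applied).

## Summary statistics and the recombination-class skew test

The statistics module computes Watterson's $\theta_w = S/(a_1 L)$,
nucleotide diversity $\pi$, Tajima's $D$ (the 1989 constants), and
Hudson's $F_{ST}$ in ratio-of-averages form with small-sample-corrected
within-population heterozygosity. $F_{ST}$ estimator choice is a package
decision — the upstream analyses only state the computing tool, not the
estimator — and is documented here for comparability.

Sites are assigned to the three recombination classes
$[0, 1.5)$, $[1.5, 3)$ and $[3, 14.5]$ cM/Mb. The source intervals are
printed as closed and overlap at their boundaries, so a convention was
required: boundaries are assigned upward, and the last class is closed at
14.5. The SFS-shape comparison between classes is a Pearson chi-squared
test on the $2 \times (n-1)$ table of frequency-class counts; because
high-frequency classes are sparse, cells are pooled from the
high-frequency end until every expected count reaches 5 (the table
construction is not described upstream; this is the package's rule).

PCA is a plain SVD of the site-centered genotype matrix — deliberately
simpler than LD-aware pipelines (no clumping, no long-range-LD removal,
no kinship correction).

## Cross-coalescence rates

`coalescence_rates()` estimates time-binned coalescence rates from
simulated genealogies with a hazard estimator: events in a bin divided by
integrated available lineage pairs, separately for pairs of lineages
ancestral only to group 1, only to group 2, or one of each; pairs
involving mixed-ancestry lineages form a fourth bookkeeping category so
that every coalescence is counted exactly once. The relative
cross-coalescence rate is $RCCR = 2 c / (w_1 + w_2)$: 1 under panmixia, 0
under complete isolation; noise can push estimates slightly above 1, which
is flagged rather than clipped. Rates rescale to population sizes as
$N_e = N_{ref} / (2 \cdot \text{rate})$ and bin edges to years, mirroring
how sequence-based coalescence-rate methods are rescaled. Default bins are
logarithmic between the 1st and 99th percentiles of the observed
coalescence times.

The statistic is computed from true simulated genealogies, not from
sequence through a hidden-Markov model: the upstream sequence-based step
is an external published tool, while the RCCR formula and the rate-to-size
rescaling are the computations this package owns. Whether genealogy-based
RCCR should reproduce HMM-specific artefacts (e.g. recent-time admixture
signals) is untestable here and out of scope.

## The synthetic-data generator

`simulate_dataset()` emulates the structure of the motivating study:
two populations of 14 haploid genomes, intronic biallelic SNPs on
independent non-recombining loci (free recombination between loci, none
within — the same compositional assumption the SFS likelihood makes),
polarized ancestral/derived alleles, and three recombination classes. By
default loci are spread evenly over the classes ($1/3$ each): the study's
empirical class proportions are a property of the fly genome's
recombination map rather than of the inference problem, and equal classes
give the skew test balanced power. Class labels carry representative rates
(0.75, 2.25, 8.75 cM/Mb). An optional external-branch mutation-rate
multiplier (`singleton_inflation_f`) in the lowest class produces the
rare-allele excess expected under linked negative selection — a minimal
surrogate sufficient to exercise the chi-squared skew test, with no claim
of realism about background selection. The generator's default demography
is the best-fit autosomal scenario in scaled units
(`default_asymig_params()`).

What passing tests on these data do **not** show: robustness to
missing/erroneous calls (the generator emits complete haploid calls),
within-locus linkage, selection beyond the singleton surrogate, or
misspecified mutation-rate maps. Real-data use should treat those as open
validation questions.

## Problem sizes used by the test suite

The suite works at desk scale, chosen so the whole battery (including the
stochastic calibration checks) completes comfortably on one core: 50,000
genealogies for closed-form spectrum checks; spectra of mass
$\sim 5 \times 10^4$–$9 \times 10^4$ for recovery and model choice; 10
datasets for the model-selection check; a 20-replicate outer loop with 50
bootstrap re-fits each (5 + 5 samples) for the coverage check; 5,000–6,000
genealogies for RCCR calibration; and, for the chi-squared skew checks,
$\sim 10^4$ SNPs per class drawn in the generator's effectively-unlinked
regime (small per-locus $\theta$), since the Pearson test assumes
independent sites and within-locus genealogical linkage would otherwise
inflate its size. The headline empirical quantities of the
motivating study derive from ~$7 \times 10^5$ SNPs of real fly genomes and
are not reproducible from synthetic data at desk scale; the suite instead
verifies the properties (closed forms, calibrations, recoveries) that the
pipeline's correctness depends on.

## Known limitations

* The likelihood is composite (sites treated as independent); no
  Godambe-style adjustment or likelihood-ratio testing is provided.
* No diffusion (PDE) solver: expected spectra are Monte-Carlo, so
  likelihood values carry simulation noise; comparisons across models are
  made under shared common-random-number streams.
* Percentile bootstrap intervals inherit the estimator's bias; with few
  replicates their tails are coarse.
* No ancestral-recombination-graph simulation, no sequence-level error
  model, no X-specific model variants.
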