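---
title: "Demographic inference for wild common bean: models, statistics, and ABC"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Demographic inference for wild common bean: models, statistics, and ABC}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(beanABC)
```

## The inference problem

Wild common bean occurs as three genetically differentiated gene pools:
Mesoamerican (MW), southern Andean (AW), and Northern Peru–Ecuador (PhI).
Which pool is ancestral is a long-standing question: genome-wide diversity
favours Mesoamerica, while the PhI pool carries ancestral seed-protein and
chloroplast variants. `beanABC` frames the question as Bayesian model
choice among three explicit demographic histories and estimates the
divergence times under the winning model, using approximate Bayesian
computation (ABC) because the likelihood of SNP data under these structured
histories is intractable.

The three competing models share the same skeleton — three sampled demes,
two divergence events at times `T1` (AW) and `T2` (PhI/deep split, in
generations, equated to calendar years for this annual selfer), founder
bottlenecks on every derived deme — and differ only in which deme keeps a
constant size and therefore plays the ancestor:

* **mesoamerican** — MW constant; AW and PhI bud off MW through founders
  `NF_AW`, `NF_PhI`.
* **phi** — PhI constant; the species spreads north (MW at `T2`, founder
  `NF_MW`) and south (AW at `T1`, founder `NF_AW`) out of Northern
  Peru–Ecuador. A sub-topology in which AW derives from MW instead would
  be a different model; we follow the migration narrative (both derived
  directly from PhI), which keeps the three models symmetric.
* **protovulgaris** — an unsampled ancestor of size `N_ANC` is constant;
  MW and AW separate from it simultaneously at `T1` and PhI at `T2`; the
  ancestor leaves no modern sample (it went extinct, or is undiscovered).

### Assumptions

The coalescent engine is a continuous-time structured Kingman coalescent:
within each deme and epoch, lineage pairs coalesce at rate
$k(k-1)/2 \cdot 1/(2N)$ per generation for diploid size $N$; divergence
events move all lineages of the derived deme into its source, backward in
time. There is no post-divergence migration (the models under comparison
have none), no selection, and no recombination *within* a chromosome:
each of the 5 simulated chromosomes is one non-recombining genealogy and
chromosomes are independent. No recombination rate is available for the
calibration of within-chromosome linkage, and the five-chromosome
structure already reproduces the between-locus variance that the summary
statistics see; an effectively independent-sites mode can be had by
setting `snps_per_chrom = 1` with many chromosomes.

Mutations are handled in SNP-ascertainment mode: each site is placed on a
branch with probability proportional to branch length (the infinite-sites
limit conditioned on polymorphism), carriers below the branch get the
derived allele, and sites below the pooled minor-allele-frequency
threshold (default MAF ≥ 0.05, matching the SNP panel's ascertainment)
are rejected and re-drawn. A per-site mutation rate therefore never needs
to be specified; it would only matter for sequence-level simulation,
which is out of scope.

### The founder bottleneck

A founder episode is realised as an epoch of the founder size `NF_*`
spanning the `bottleneck_dur` generations immediately after the founding
(forward time), followed by instantaneous growth to the deme's current
size. `bottleneck_dur` defaults to 100 generations. The sources describing
this system state only that derived pools bottlenecked at separation,
without a duration or shape, so the duration is a package choice; an
"instantaneous intensity" parameterisation would reduce to exactly the
same epoch construction (intensity = duration/2NF), so only the duration
form is provided.

## Priors

The published analysis used priors from supplementary material that is not
available in text form. The shipped defaults are therefore labelled
reconstructions, chosen on the scales this literature uses and wide enough
to bracket the reported posteriors: log-uniform current sizes
$N \in [10^3, 10^6]$, log-uniform founder sizes $NF \in [10, 10^4]$,
uniform $T1 \in [10^4, 5\times10^5]$ and $T2 \in [5\times10^4, 2\times10^6]$
years. No ordering constraint $T2 > T1$ is imposed (the priors are
independent); a truncation can be added by editing the prior spec, which is
fully config-driven. All priors are drawn per simulation with recorded
per-row seeds, so any reference-table row can be regenerated exactly.

## Summary statistics

`sumstat_vector()` computes, in a fixed order shared by observed and
simulated data: per population the number of segregating sites `S`, mean
per-site nucleotide diversity `pi`, mean unbiased expected heterozygosity
at within-population segregating sites `H`, and Tajima's `D`; pairwise
Weir–Cockerham `fst` for the three population pairs; pooled `S_all` and
`H_all`. The exact statistic set of the upstream summary-statistics tool
is not printed anywhere we can verify, so the package defines its own
default — precisely the statistics the study system's headline table
reports — and keeps it extensible.

Numerical conventions worth knowing:

* Missing genotypes are excluded, never imputed (imputation is explicitly
  rejected for this kind of GBS data); frequencies use per-site sample
  sizes, and the harmonic constants of Tajima's `D` use the median
  per-site number of allele copies — an approximation that is exact for
  complete data.
* `fst` is Weir–Cockerham θ with ratio-of-sums multi-locus combination
  (a,b,c variance components summed across sites before the ratio). It is
  slightly negatively biased for weakly differentiated pairs, which is a
  property of the estimator, not a bug.
* Genome scans average π, `D`, `fst` over fixed 100-kb bins that contain
  at least 3 variants, each qualifying bin weighted 1. Scan diversity is
  normalised per bin width by default (`span_mode = "bin"` — the
  convention that puts wild-bean π on the 1e-5 scale over mostly
  invariant windows); per-assayed-site normalisation is one switch away,
  since the original normalisation cannot be verified from the printed
  value alone.
* Haplotype blocks are Gabriel-style: likelihood-based 90% confidence
  intervals on |D′| classify pairs as strong LD (CI within [0.70, 0.98])
  or recombinant (upper bound < 0.90); maximal intervals whose outermost
  pair is strong and with ≥ 95% strong informative pairs become blocks,
  greedily by physical length; blocks spanning ≤ 100 bp are discarded
  before the N50. The LD window defaults to 2 Mb: the tool flag quoted in
  the source (20,000 kb) contradicts its own prose ("no more than 2 Mb
  apart") and we follow the prose, with the window configurable.
  Double-heterozygous genotype pairs are phase-ambiguous and excluded
  pairwise — a cheap convention that is accurate for a selfing species
  with percent-level heterozygosity.

## The ABC engine

Statistics are standardized by their raw median absolute deviation across
the reference table (constant columns dropped), distances are Euclidean,
and rejection keeps the `floor(eps * n)` nearest simulations with ties
broken by stable row order. Model posteriors come from three estimators:

* **rejection** — accepted-model fractions;
* **mnlogistic** — multinomial logistic regression of model label on
  standardized statistics over the accepted set, Epanechnikov-weighted in
  distance (bandwidth = largest accepted distance), evaluated at the
  observation, clipped to [0, 1] and renormalized. A small ridge term
  (1e-6) keeps perfectly separated fits finite — which is also our best
  explanation for posterior probabilities of exactly 1 reported by
  comparable software: an out-of-range regression output clipped at 1.
* **neuralnet** — an ensemble (default 100 members, iteration cap 1,000,
  hidden layer of 5 tanh units) of softmax networks trained by weighted
  cross-entropy; the posterior is the ensemble mean at the observation.
  The weight-decay default is deliberately heavy (0.25 on standardized
  inputs): a posterior-probability estimator should collapse to the
  locally weighted class frequencies when the statistics carry no signal,
  and lighter decay lets individual members chase local sampling noise.
  Members whose optimizer fails outright are dropped and counted;
  reaching the iteration cap is a training budget, not a failure.

Bayes factors are posterior-probability ratios under the equal model
priors used throughout (`BF_ij = PP_i / PP_j`, infinite when `PP_j = 0`).
Parameter posteriors under one model report the accepted-draw mean, a 95%
CI of the mean (normal approximation, ±1.96 SE — which is why these CIs
are much narrower than the HPDs), and the 95% HPD as the narrowest window
of `ceiling(0.95 n)` consecutive order statistics. Cross-validation holds
out each of `n_cv` sampled rows, re-runs rejection against the rest, uses
the posterior mean as point estimate (matching the reported summaries;
a median mode exists), and reports
`Epred = Σ(θ̂ − θ)² / (n_cv · Var(θ))` — 0 for a perfectly informative
statistic, 1 when the estimator collapses to the prior mean.

## The synthetic-data generator

`make_pseudo_observed()` replaces the study's 246-genotype GBS panel: it
simulates a dataset under a named model with known truth (the
`"table3-like"` preset plants `T1 = 87,410` and `T2 = 373,060` years with
mid-prior sizes — generator inputs for recovery experiments, never
expected outputs) at either the full sampling profile (157/77/12 diploids
MW/AW/PhI) or a reduced 20/10/6 profile that keeps simulation-heavy tests
within desk budgets. `make_toy_vcf()` plants filter defects
(multiallelic records, monomorphic sites, missingness above the site and
individual thresholds, low-GQ/DP calls) with the expected filter outcome
derived by the generator's own budget arithmetic, independent of the
filter implementation. `make_annotation_fixture()` writes identical
intervals as GFF3 and BED together with a brute-force distance-based
genic/neutral/intermediate expectation.

What the generator does *not* emulate: GBS read-level artefacts (coverage
heterogeneity, allele dropout), real linkage structure within
chromosomes, repeat-region annotation (an optional BED mask is exposed,
with no default, since the original repeat track is unspecified), and
selfing-induced haplotype structure (simulated diploids pair exchangeable
haplotypes at random; an inbreeding mode is unnecessary for the
allele-frequency statistics the pipeline consumes). A green test
therefore establishes correctness of the algorithms on idealised
genotype matrices, not robustness to raw-data pathology.

## The filter chain

`apply_filters()` fixes the order: (1) mask calls with GQ < 10 or
DP < 3 (the "depth higher than three" prose conflicts with the tool
flag's ≥ 3 convention; we default to ≥ 3, switchable), (2) drop
multiallelic sites, (3) drop individuals with > 10% missing calls, (4)
drop sites with > 20% missing calls, (5) drop sites with MAF below 0.05
(inclusive boundary — MAF = 0.05 is kept — switchable). Steps 3–5 are
iterated to a fixed point because removing sites can push a remaining
individual back over the missingness threshold; a single pass (what
chained command-line tools would do) is not idempotent, and idempotence
is the contract this package promises. Per-step removal counts are
accumulated so input = output + removals always holds.

## Scaled-down acceptance experiments

The published headline numbers are functions of the real data and
unpublished priors, so the test suite validates the machinery instead:
exact oracles for every statistic; neutral-theory checks of the
coalescent core (pairwise coalescence time, Watterson branch length, the
1/i site-frequency spectrum); agreement with msprime as an independent
simulator within Monte-Carlo error; and two scaled-down analogues — model
selection on a 30,000-row balanced table recovering the generating model,
and divergence-time recovery with 95% HPD coverage of planted
`T1`/`T2` truth.

Two experiment-design points deserve spelling out. First,
"well-separated" pseudo-observed parameters must sit in each model's
identifiable region, which is less obvious than it sounds: the
mesoamerican topology *nests* the protovulgaris one (it is the special
case where the ancestor is the diverse MW deme itself), and founder
signatures vanish once a deme has had time to re-equilibrate
(`2N` much smaller than the divergence time). The shipped experiments
therefore use large current sizes with strong founders for the
mesoamerican/phi truths, and a tiny extinct ancestor with expanding
descendants for protovulgaris — a configuration the mesoamerican model
cannot imitate. Second, interval-recovery experiments need enough
accepted draws: the empirical 95% HPD from only 100 draws has a noisy
lower endpoint (the shortest window almost always drops the sparse left
tail), so the recovery experiment runs at the 5% tolerance (500 accepted
draws), one of the tolerance levels the original cross-validation also
used. The 30,000-simulation default budget (vs 1,010,101 in
the original analysis) is a deliberate desk-scale choice; the pipeline
config exposes a paper-scale flag that restores the original count and
warns about the runtime. Balanced per-model simulation counts are used
throughout (the original total is not divisible by three and the split is
unstated). Reference-table rows whose statistic vector is undefined —
a deme monomorphic in sample, most often PhI with 6 diploids behind a
10-individual founder — are re-drawn with fresh recorded seeds and
logged; the table thereby conditions on datasets for which the summary
vector exists, which is also the condition any observable dataset
satisfies. Hard simulation errors, by contrast, abort above a 1% rate.

## Known limitations

* Within-chromosome linkage is all-or-nothing (fully linked loci), so
  statistics sensitive to intra-chromosome recombination (e.g. block N50
  on simulated data) should not be compared to real data quantitatively.
* The reconstructed priors are not the published ones; posterior scales
  from real data depend on them.
* Arlequin-exact statistic definitions could not be verified; the
  statistic vector is package-defined (and config-extensible).
* The mnlogistic/neuralnet internals (kernel, bandwidth, decay, hidden
  size) mirror documented behaviour of comparable software but are
  design choices, stated above, not reproductions.
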