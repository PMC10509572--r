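---
title: "Models and methods in ypopgen"
author: "ypopgen authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in ypopgen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ypopgen)
```

# Scope

`ypopgen` analyses Y-chromosome haplotype data of the kind produced by
forensic Y-STR kits combined with Y-SNP haplogroup typing: one male per
row, a 27-STR haplotype (23 single-copy loci plus the duplicated DYS385
and DYF387S1, whose alleles are unordered combinations), a terminal
haplogroup call in ISOGG-style nomenclature, and sampling coordinates.
On top of that container it implements the standard analysis stack of
Y-chromosomal population studies: forensic summary statistics, haplogroup
frequency geography, AMOVA-based pairwise Fst, weighted median-joining
networks, and TMRCA estimation, together with a coalescent simulator that
generates datasets with exactly this structure so the whole stack can be
validated end to end without access to restricted genotype tables.

# The data model

A `YStrDataset` stores sample metadata and a numeric allele matrix with
one column per STR copy. The two copies of a duplicated locus are kept
sorted, so `11-14` and `14-11` are the same haplotype by construction;
haplotype identity for counting statistics is the string key over all 27
STR columns. DYS389II amplicons physically contain the DYS389I repeats,
so the panel works with the derived segment DYS389b = DYS389II − DYS389I;
the reader derives it when a table carries DYS389II instead. Rows that
fail parsing are rejected with line diagnostics rather than silently
dropped, while *content* checks (allele range 5–60, fractional parts
.0/.1/.2/.3, coordinate ranges, haplogroup parseability) are reported by
`validateDataset()` so that a questionable file can be loaded, inspected
and repaired.

The default panel covers the 27 STRs as 25 locus descriptors. Its
mutation rates are package defaults of the magnitude published in the
YHRD rate tables, not measurements; any serious dating analysis should
supply its own `readLocusPanel()` table. The 14-locus "slowly mutating"
subset (DYS389I, DYS389b, DYS390, DYS391, DYS392, DYS393, DYS437,
DYS438, DYS439, DYS448, DYS456, DYS458, DYS635, YGATAH4) is the default
basis of all TMRCA estimation, following standard practice of dating
with slow markers to limit saturation.

# Forensic statistics

All frequency statistics are direct counts. With category frequencies
$p_i$ and sample size $n$:

* diversity (gene, haplotype or haplogroup): $h = n(1-\sum_i p_i^2)/(n-1)$,
* match probability: $\mathrm{MP} = \sum_i p_i^2$,
* discrimination capacity: $\mathrm{DC} = k/n$ with $k$ observed haplotypes.

These satisfy $h = (1-\mathrm{MP})\,n/(n-1)$ identically, which the test
suite asserts exactly, and $\mathrm{DC}=1 \iff \mathrm{MP}=1/n$. Samples
missing a required allele are excluded from the affected statistic only,
with the excluded count attached to the result. For DYS385 and DYF387S1
the counted unit is the unordered allele combination, not the pooled
single alleles — this is why the duplicated loci sit at the top of
per-locus diversity tables.

# Population structure

`pairwiseFst()` computes Phi-ST from one-level AMOVA variance components
$\sigma_a^2/(\sigma_a^2+\sigma_w^2)$ on squared inter-haplotype
distances over the 23 single-copy loci. Because the classical software
leaves the distance implicit, both options are provided and recorded in
the result: `haplotype_identity` (0/1 mismatch) and `stepwise` (summed
squared repeat difference, Rst-like); intermediate alleles contribute
their numeric difference in stepwise mode and behave as plain categories
in identity mode. Significance is by permutation of individuals across
the pair with the $(b+1)/(m+1)$ estimator, so p-values never reach zero;
permutations are evaluated through a single BLAS product (quadratic
forms of all permutation indicators at once), which keeps
full-study-size pairs tractable. Negative estimates are reported as
computed — the unbiased estimator of two identical samples sits at
$-1/(m-1)$, not at zero — and clipping is left to display code.

PCA of population-by-haplogroup frequency matrices is covariance PCA on
column-centred frequencies (no correlation scaling, flagged in the
output), with each component's sign fixed so its largest-magnitude
loading is positive, making coordinates platform-reproducible.

Geographic frequency surfaces use inverse-distance weighting with
$w_i = d_i^{-p}$ ($p = 2$ by default) on a 0.5° lattice padded 2° beyond
the stations' bounding box, with distances taken in degree space — the
grid and the station-snap rule (a cell within half a cell size of a
station takes the station value exactly) are both defined in degrees, so
using the same space for weights keeps the surface self-consistent.
Values are convex combinations of station values and therefore bounded
by their range. No particular interpolation method is canonical for
haplogroup contour maps; IDW was chosen for determinism and monotone
behaviour between stations.

# Median-joining networks

Networks are built over mixed characters: single-copy STRs (numeric,
weighted 1–5) and optional binary SNP states (weight 99, so a SNP
difference always dominates). STR weights are derived from mutation
rates by quintile binning — slowest quintile 5, fastest 1 — and can be
overridden through the panel table. The algorithm iterates: build the
ε-relaxed minimum spanning network; for every mutually connected
triplet compute the component-wise quasi-median (numeric median for
STRs, majority for SNPs); add the median that most reduces the total
connection cost (MST length over the node set); stop at a fixed point;
then delete medians whose removal leaves the cost unchanged. All ties
break lexicographically on the character vectors, so output is invariant
to input order. ε defaults to 0 (strict network); the optional
pre-processing is star contraction, merging satellite classes within a
radius δ of a more frequent neighbour.

Two properties are worth stating precisely, because they are checked:
the network's edge set contains every minimum spanning tree over its own
node set (every MST edge on a node set is MSN-feasible by the cycle
property), and its total connection cost never exceeds the MST cost of
the observed classes alone. Literal containment of an observed-class
MST does *not* survive median insertion — in the classic 3-haplotype
binary example the optimal network is the 3-spoke star through the
median (cost 3 versus 4) and contains no observed-class MST edge at all.

# TMRCA estimation

Three estimators, one result type (`TmrcaEstimate`, generations and
years with an interval; years are always generations × generation time,
25 y by default).

**ASD.** Per locus the mean squared allele difference from a founder
haplotype has expectation $\mu t$ under the single-step model, so
$\hat t = \mathrm{mean}_l(\mathrm{ASD}_l/\mu_l)$; the founder defaults
to the modal haplotype (component-wise majority, ties to the smaller
allele) and the interval is a seeded bootstrap over samples. ASD is
unbiased on star genealogies and translation-invariant.

**Rho.** The multiplicity-weighted mean number of unweighted mutational
steps from a designated root across the network, divided by the summed
mutation rate; the interval uses the $\sigma_\rho=\sqrt{\rho/n}$
convention, recorded in the output. Rho undercounts once parallel
mutations start cancelling along branches (relative bias roughly half
the per-locus mutation load), which is why the rho/ASD agreement test
runs on shallow stars.

**MCMC.** A single-population Bayesian sampler over coalescent
genealogies with exponential growth. The state is the genealogy (times
and topology), the effective size $N$ (lognormal prior, default median
1000, sdlog 1; sdlog 0 fixes it) and the scaled growth $g = Nr$
(exponential(1) prior; rate 0 fixes growth at zero) — all priors are
configuration, never hard-coded. The STR likelihood is a symmetric
single-step continuous-time Markov chain on a bounded integer allele
lattice (observed range ± 10 repeats; widening the pad changes
log-likelihoods negligibly because the chain mass never reaches the
boundary on these time scales), evaluated by Felsenstein pruning with
the lattice generator eigendecomposed once per locus. Intermediate
alleles are rounded to the lattice for this estimator. Moves are
node-time slides, a root scale, narrow exchange (topology), a whole-tree
scale, and hyperparameter random walks; node-local moves recompute only
the dirtied root path, implemented in C++. The run reports the posterior
median height and central 95% interval, is deterministic given the seed,
and flags non-convergence (split-half height comparison) with a warning
rather than silently. The production preset mirrors a two-million-sample
run with 3000 burn-in; the `scaled_down` preset (10,000 samples, 500
burn-in) is for tests and is labelled as such in the output.

Correctness is established three ways in the test suite: a prior-only
run must reproduce the coalescent prior quantiles obtained by direct
simulation; for $n=2$ and one locus the posterior must match direct
numerical integration of prior × transition probability; and across 100
replicates with the truth drawn from the prior, the 95% interval must
cover the true height at least 85 times.

# STR-based haplogroup prediction

The predictor is a conditional-independence (naive Bayes) model over the
single-copy loci: smoothed per-class allele frequencies (additive
pseudocount, default 0.5, with an explicit `.other` category so unseen
alleles keep mass) and training-proportion priors, evaluated in log
space so 23-locus products cannot underflow. Classes default to
major-clade resolution (level 1, e.g. O1 vs O2), the resolution at which
STR haplotypes carry usable signal. `associationTable()` provides the
descriptive basis (per-haplogroup gene diversity and allele spectra);
`crossValidate()` reports seeded stratified k-fold accuracy against the
majority-class baseline, which is the honest yardstick for imbalanced
haplogroup data.

# The synthetic generator

`simulateDataset()` generates datasets with the statistical structure
the analyses assume, not a demographic reconstruction of any real
population. Per population, haplogroup labels are multinomial draws from
a configured mixture; per population × haplogroup, one shared coalescent
genealogy (exact time-transformed sampling; $E(T_{\mathrm{MRCA}})=N$ for
$n=2$, $2N(1-1/n)$ in general) carries symmetric single-step STR
mutations (per branch, Poisson($\mu t$) mutations of ±1 repeat,
reflected into the reportable 5–60 band). Haplogroup founder haplotypes
are themselves evolved along the nomenclature tree, and each
population's clade founder drifts further — this hierarchical founder
structure is what gives haplogroups (strongly) and populations (weakly)
real STR signal. SNP states are set derived on the root-to-call path and
ancestral elsewhere. Everything is deterministic given the master seed,
with one derived substream per population × haplogroup cell.

The default configuration mirrors the five-ethnicity Chinese study
design the package ships as its worked example: sizes 1266 (Han), 654
(Hui), 680 (Mongolia), 427 (Yi), 314 (Kyrgyz) — the reciprocals of the
published per-population minimum haplotype frequencies — and major-clade
mixtures matching the published frequency table (Han O 0.800, Kyrgyz R
0.455, pooled O 0.548, ...). The published table prints non-zero cells
only; the assignment of values to clades was reconstructed from the
anchors named in the running text and validated against the pooled row,
which the size-weighted means reproduce to the printed digit. Sub-clade
splits within each major clade follow the qualitative descriptions of
the network analyses (Kyrgyz C concentrated in C2a1a3, no O1 in Kyrgyz,
Yi D dominated by D1a1a1a1b, ...) and are otherwise uniform — they are
plausible study-like defaults, not published values. The remaining free
parameters were fixed at field-realistic scales: within-cell coalescent
dynamics use an expansion regime ($N = 3000$ with forward growth rate
$r = 0.005$ per generation), giving expected within-haplogroup TMRCAs
near 680 generations — about 17 000 years at 25 y/generation, the
post-glacial time scale such studies report — and star-like genealogies
whose long terminal branches keep nearly all 27-STR haplotypes distinct,
as the published discrimination capacities require. (An initial
constant-size draft of the generator produced Kingman-shaped trees whose
excess haplotype sharing contradicted the published regime; expansion is
the realistic choice, and is also what the study's own interpretation of
its TMRCAs implies.) Founder drift runs 480 generations (~12 ky) per
nomenclature-tree edge so that macro-clades span the expansion era, and
100 generations per population.

What the generator deliberately does not emulate: migration and
admixture between populations (differentiation comes from mixture
differences and founder drift only), locus-specific allele spectra and
mutation asymmetries, genotyping artefacts, and missing data. Passing
tests therefore show that the implementations are correct under the
stated model, and that the pipeline reproduces the published frequency
structure when configured to it; they do not show that any particular
biological conclusion transfers to real data.

# Numerical choices and conventions

* Allele tokens: integers, one-decimal intermediates (17.2), "-"-joined
  combinations; everything else is a parse error. Formatting is
  canonical value-wise (trailing ".0" stripped), so `12` and `12.0`
  always collide and `17.2` never does.
* Diversity statistics keep full precision internally; rounding to
  printed precision is presentation only.
* AMOVA estimates are clipped nowhere in computation; the `[-small, 1]`
  range is a property of the estimator.
* Median-joining tie-breaks (equal-cost medians, equal-length links) are
  lexicographic on character vectors; the MSN uses a union-find sweep
  whose feasibility threshold is monotone, so ε-relaxation only widens
  the link set.
* MCMC lattice: observed allele range ± 10 repeats per locus; tips enter
  as exact indicator vectors; pruning partials are max-rescaled per node
  with log-scale accumulators.
* Permutation p-values use $(b+1)/(m+1)$ everywhere.
* Seeds: every stochastic entry point takes an explicit seed; the
  generator derives named substreams so adding a population does not
  shift another population's draws.

# Problem sizes used in the validation suite

The shipped tests run the formula suites on hundreds of random
micro-datasets, the study-scale checks on one full 3341-male synthetic
dataset, the MCMC coverage experiment at $n = 30$ with 10,000-sample
scaled-down chains (100 replicates), the prior-recovery run at $10^6$
prior-only iterations, and the network suite on 100 random instances of
up to 8 classes against exhaustive (Prüfer-enumeration) spanning-tree
oracles. These sizes were chosen so the full suite completes on a
laptop-class single core in well under half an hour while keeping every
statistical tolerance at 3 standard errors or tighter.

# Known limitations

* The coalescent MCMC models a single panmictic population with
  exponential growth; it is a scoped replacement for full
  population-splitting samplers, suitable for within-clade dating, not
  for multi-population joint inference.
* Rho and ASD assume a known (or modal-proxy) founder; both degrade on
  strongly non-star genealogies, rho additionally under mutation
  saturation.
* The haplogroup predictor assumes locus independence within classes;
  linkage on the non-recombining Y makes this an approximation that
  works at major-clade resolution and degrades for terminal subclades.
* IDW surfaces are interpolators, not process models: they honour the
  stations and bound the field, but infer nothing about unsampled
  structure.
* The default mutation-rate table is a package default of realistic
  magnitude; locus-specific published estimates should replace it for
  any substantive dating.
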