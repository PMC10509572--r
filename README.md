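# ypopgen

Population genetics of the Y chromosome from forensic-style haplotype
data: per-male Y-STR haplotypes (Yfiler Plus-like 27-STR panels) with
SNP-defined haplogroup calls, the data produced when forensic Y-STR
databases are merged with high-resolution Y-SNP typing. The package is
aimed at forensic and population geneticists who need the standard
analysis stack of such studies in one validated, scriptable place.

## What it computes

* **Forensic summary statistics** by direct counting: gene / haplotype /
  haplogroup diversity `h = n(1 − Σ pᵢ²)/(n − 1)`, match probability
  `MP = Σ pᵢ²`, discrimination capacity `DC = k/n`, with DYS385 and
  DYF387S1 treated as unordered allelic combinations and
  `DYS389b = DYS389II − DYS389I` derived on input.
* **Haplogroup nomenclature**: ISOGG-style name parsing and collapsing
  (`O2a2b1a1a1-F438` → `O2` at level 1), tree construction from
  (haplogroup, defining SNP) tables with nomenclature-inferred topology,
  and haplogroup assignment from SNP ancestral/derived states with
  conflict detection and paraphyletic `*` handling.
* **Population structure**: pairwise Fst (Φst) from one-level AMOVA on
  23 single-copy STR loci, with haplotype-identity or stepwise (Rst-like)
  distances and permutation p-values; covariance PCA of haplogroup
  frequency matrices; inverse-distance-weighted haplogroup frequency
  surfaces over latitude/longitude grids.
* **Median-joining networks** over mixed characters — STRs weighted 1–5
  by mutation-rate quintile, SNPs weighted 99 — with quasi-median
  (Steiner) vector insertion, optional star-contraction pre-processing,
  and GraphML/DOT/TSV export carrying population pie-chart compositions.
* **TMRCA**: average-squared-distance (ASD) dating with bootstrap
  intervals, the network rho statistic, and a Bayesian single-population
  coalescent MCMC with a stepwise-mutation lattice likelihood (C++
  pruning core), all reporting generations and years (25 y/generation by
  default).
* **Haplogroup prediction from STRs**: a smoothed naive-Bayes classifier
  over single-copy allele frequencies with stratified cross-validation.
* **A coalescent simulator** (`simulateDataset()`) producing
  multi-population datasets with haplogroup mixtures, hierarchical
  founder drift along the haplogroup tree and per-branch stepwise STR
  mutation — the test bed for everything above.

## Worked example

The package ships a study-like default configuration: five Chinese
ethnic groups (Han, Hui, Mongolia, Yi, Kyrgyz; 1266/654/680/427/314
males) with published major-clade haplogroup mixtures (Han O 0.800,
Kyrgyz R 0.455, ...).

```r
library(ypopgen)

sim <- simulateDataset(defaultSimConfig(), seed = 1)
ds  <- sim$dataset
ds
#> YStrDataset: 3341 samples, 5 populations, panel 'YfilerPlus27'
#>   ethnicities: Han (1266), Mongolia (680), Hui (654), Yi (427), Kyrgyz (314)

forensicSummary(ds, by = "ethnicity")
#>      group    n n_haplotypes        hd        dc           mp haplogroup_diversity
#> 1      Han 1266         1179 0.9998739 0.9312796 0.0009159223            0.8857926
#> 2      Hui  654          645 0.9999579 0.9862385 0.0015711360            0.9344826
#> 3 Mongolia  680          653 0.9998787 0.9602941 0.0015916955            0.9282076
#> 4       Yi  427          414 0.9998571 0.9695550 0.0024845197            0.8848171
#> 5   Kyrgyz  314          302 0.9997355 0.9617834 0.0034484158            0.7861867
```

HD near 1, MP in the 0.0008–0.0052 decade and DC close to 1 are the
regime published for panels and sample sizes of this kind; the
haplogroup diversity column responds to each group's mixture evenness
(Hui highest, as its mixture is the most even). Frequencies recover
their configured (published) targets:

```r
fm <- haplogroupFrequencyMatrix(ds, level = 0, by = "ethnicity")
round(fm[, c("O", "C", "R")], 3)
#>              O     C     R
#> Han      0.784 0.068 0.009
#> Hui      0.433 0.087 0.124
#> Mongolia 0.351 0.353 0.065
#> Yi       0.569 0.019 0.000
#> Kyrgyz   0.029 0.363 0.446

est <- asdTmrca(subsetByClade(subsetByPopulation(ds, "Kyrgyz"), "C2a1a3"))
est
#> TmrcaEstimate (asd): 464.0 generations = 11600 years (95%: 408-527 gen; 25 y/gen)
```

With 25 years per generation the simulated within-clade ages land in the
roughly 10–20 kya band, the post-glacial expansion window such studies
report (the ASD point sits below the simulated truth of ~17 kya because
the modal-haplotype founder proxy shrinks distances — a documented bias
of the estimator).

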