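---
title: "Detecting a polychromatic greenbeard locus from segregation data"
author: "greenbeardr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting a polychromatic greenbeard locus from segregation data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(greenbeardr)
```

## The problem

When two strains of a social amoeba such as *Dictyostelium discoideum*
co-aggregate, they can either develop together as an even chimera or sort
into genotype-biased fruiting bodies. A *greenbeard* locus — one that
encodes a recognizable tag, the perception of that tag, and tag-conditional
behaviour — predicts a very specific pattern: the degree of segregation
between two strains should track their allelic distance *at that locus*,
not their genome-wide relatedness, and the locus should carry enough
functional allelic diversity to give each strain a distinguishable tag
(a *polychromatic* greenbeard). This package implements the statistical
machinery to test that prediction: a normalized segregation statistic with
a fitted null, a genome-wide gene-by-gene association scan, entropy-based
diversifying-site detection, tree-concordance metrics, and
phenotype-linkage statistics — together with a seeded synthetic-data
generator so the entire pipeline can be exercised and validated end to end.

## The segregation statistic

For one mix, let $p_1, \dots, p_n$ be the percentages of the labeled
(focal) strain in each of $n$ fruiting bodies, with mean $m$. The raw
segregation is the standard deviation $s$ of the $p_i$. Because a strain
that makes up a fraction $m$ of all spores can reach a per-fruiting-body
standard deviation of at most $\sqrt{m(100 - m)}$ (attained by a
composition supported on $\{0, 100\}$), the normalized segregation value is

$$\mathrm{nsv} = 100 \times \frac{s}{\sqrt{m\,(100 - m)}} \in [0, 100],$$

interpretable as percent segregation.

Two choices here were genuinely open:

* **Population versus sample standard deviation.** `compute_nsv()` uses the
  population (divide-by-$n$) form. Only with it does the two-point
  $\{0,100\}$ composition reach nsv exactly 100, which the "percent
  segregation" reading requires; with the sample form the maximum would
  exceed the bound for small $n$.
* **Degenerate means.** At $m = 0$ or $m = 100$ the ceiling is 0 but so is
  $s$; the statistic is defined as 0 there.

### The self-mix gamma null

Mixing a strain with itself measures pure assay noise (labeling, counting,
sampling of spores). `fit_gamma_null()` fits a gamma distribution to
self-mix nsv values by maximum likelihood (an L-moment estimator is
available via `method = "lmoments"`) and sets the classification threshold
at a high quantile of the fit, by default the 99th percentile. A mix
segregates when its nsv *reaches* the threshold (`>=`), matching the
convention that a threshold of 18 puts nsv = 18 in the segregating class.

One numerical subtlety is documented rather than hidden: for the published
parameters (shape 4.26, rate 0.51) the 99% quantile is about 20.5, while
the published working cutoff was 18 (closer to the 97.5% quantile). Because
the intended quantile cannot be reconstructed from the reported values,
both the quantile level and an explicit manual threshold are exposed in
`pipeline_config()`; no silent choice is made between them.

### Bootstrap comparisons and non-transitivity

`bootstrap_compare()` resamples fruiting bodies without replacement
(default 10 of the available set, 1000 times), recomputes nsv per
subsample, and compares mixes by pairwise t-tests at the Šidák-corrected
per-test level $\alpha' = 1 - (1 - \mathrm{FWER})^{1/m}$; for 15 tests at
FWER 0.05 this gives 0.0034. `hierarchy_and_swaps()` ranks partners by nsv
against two reference strains and reports every partner pair whose order
flips between them — the non-transitive signature that distinguishes
partner-specific recognition from a one-dimensional "strength" scale.

## The genome scan

`greenbeard_scan()` computes, per gene, the Pearson correlation between the
upper-triangle vector of the gene's pairwise protein p-distances and the
corresponding nsv values (self-mixes never enter), with the two-sided
p-value from the t transform at $n_\text{pairs} - 2$ degrees of freedom. A
gene passes when its p-value falls below the Šidák level for the number of
genes actually tested. Design choices:

* **Distance.** The uncorrected p-distance (mismatches over compared
  columns), with complete deletion of gapped columns by default; the source
  analyses removed gapped sites before computing distances. A
  pairwise-deletion mode is available.
* **Independence.** Per-gene tests are treated as approximately independent
  for the multiplicity correction, which is how the original threshold of
  $7.85 \times 10^{-6}$ for 6,532 genes arises. Strain pairs within one
  gene share strains, so the per-gene p-values are themselves
  Mantel-style approximations; a permutation p-value (joint row/column
  permutation of the segregation matrix, `n_perm`) is available for users
  worried about pair non-independence. Under the package's own null
  simulations (targets drawn independently per pair) the familywise pass
  rate of the t-based procedure is controlled at the nominal level, which
  is the regime the correction assumes.
* **Zero variance.** Monomorphic genes (or genes constant over the shared
  strains) are recorded with `r = NA` and excluded from the multiplicity
  count, with a warning — they carry no test.

Synonymous/non-synonymous tallies (`count_syn_nonsyn()`) classify each
distinct non-consensus codon against the column consensus under the
standard genetic code, counting variant nucleotide sites. This reproduces a
per-site S/NS bookkeeping without ancestral reconstruction, which the
descriptive statistics do not need. `colocate_candidates()` merges passing
genes into genomic clusters by single-linkage with a configurable gap
(default 50 kb).

## Trees, entropy, phenotypes

Tree inference inside the package is neighbor joining (`nj_tree()`);
externally computed trees (e.g. maximum likelihood) can be supplied as
Newick at the same interfaces. Negative NJ branch lengths are clamped to
zero with the deficit moved to the sibling edge. Robinson–Foulds distances
(`rf_distance()`) use the unrooted, non-trivial-splits convention.

`entropy_profile()` computes per-column Shannon entropy with gaps excluded
from the frequencies (not a 21st state — gapped sites were removed in the
source analyses). The log base matters for the conventional cutoff of 1 and
is configurable and recorded; natural log is the default. Diversifying
sites are variable columns with entropy above the cutoff;
`positional_clustering()` locates their densest window, e.g. to check
N-terminal clustering.

`percent_binding()` uses bound / (bound + unbound); the input lane, when
present, is stored for auditing but does not normalize (the original
normalization is unstated). Migration deviations are absolute trail-length
differences from the same-experiment clonal mean, not percentages.
Both phenotype correlations exclude self pairs.

## The synthetic-data generator

`simulate_bundle()` produces a complete dataset with the statistical
structure the analysis assumes. The defaults define the study conditions
used throughout the tests:

* **Strains.** 20 haploid strains in 4 deep clades (coalescent-style joins:
  within-cluster heights up to 0.3, deep joins at 0.7–1), with 3,000
  infinite-sites SNPs dropped on branches — mirroring the real design of 20
  co-occurring strains, four genomic clusters, and ~30k genome-wide SNPs at
  desk scale.
* **The planted locus.** Two 300-codon genes with substitution rate
  elevated 20-fold in the N-terminal quarter and a forced deep two-group
  split covering 60% of N-terminal sites. The within-group genealogy uses
  the strain tree's shape with permuted tips (`decouple = TRUE`): the
  haplotype groups are ancient and cut across present-day relatedness, so
  locus distance is decoupled from genome-wide identity-by-state. This is
  the defining polychromatic-greenbeard signature — locus distance predicts
  segregation while genomic distance does not — and it is also what makes
  the background familywise error controllable: the segregation structure
  shares no systematic component with the tree on which the 500 background
  genes (100 codons each, background rate 0.003 per site per unit branch)
  evolve.
* **Compositions.** Per-fruiting-body proportions are Beta$(\alpha,
  \alpha)$ with $\alpha = ((100/t)^2 - 1)/2$ for target nsv $t$; the Beta
  variance closed form makes the expected population standard deviation
  equal $t/2$ against a ceiling of 50, so $E[\mathrm{nsv}] \approx t$. This
  gives an analytic calibration oracle (realized nsv within 2% of target at
  $n = 10{,}000$). Mixes get 6–12 fruiting bodies, bracketing the real
  average of 8.4 per mix.
* **Coupling.** Target nsv follows a saturating curve
  $\mathrm{nsv} = 95\,d/(d + d_{1/2})$ with $d_{1/2}$ a quarter of the mean
  locus distance plus Gaussian noise (s.d. 7); binding decreases linearly
  with scaled locus distance; migration deviation is $-0.1$ trail-length
  units per nsv unit over 4 experiments. The real data constrain only the
  monotonicity and sign of these couplings, not their functional form;
  the saturating form and slopes are acknowledged conveniences chosen once.
* **Self-mixes.** Beta(400, 400) noise around 50, giving per-FB percent
  s.d. of about 1.8 and self nsv around 3.5 — small, right-skewed and
  gamma-like.

What the generator does *not* emulate: real spore-count noise per fruiting
body, assay-specific labeling bias, gapped alignments, missing genotype
data beyond what the readers tolerate, linkage between background genes,
and any molecular mechanism (adhesion kinetics, aggregation dynamics).
Passing tests therefore demonstrate that the statistics recover planted
structure of realistic shape and size, not that they would behave
identically on raw experimental data.

## Problem sizes and determinism

The validation suite runs at desk scale, chosen so that the full suite and
the acceptance script complete in minutes on one CPU: 20 bundles of 502
genes for planted-locus recovery, 200 bundles of 100 genes for the null
familywise control (with a 60-codon locus, since the locus is not part of
the tested family there), $n = 10{,}000$ draws for the nsv and gamma
calibrations, and 100 random trees for the NJ inversion property. Every
stochastic step flows from a single integer seed; a bundle written twice
from the same seed is byte-identical.

## Known limitations

* The per-gene scan p-values inherit the pair non-independence of distance
  matrices; the Šidák threshold is exact only under the independence
  approximation stated above. The permutation option is the conservative
  alternative.
* The gamma null requires at least 5 strictly positive self-mix values;
  exact zeros are floored at 0.01 (logged), and a degenerate
  (all-identical) sample is refused rather than fitted.
* Protein distances are uncorrected p-distances; no multiple-hit correction
  or alignment-score alternative is provided.
* Neighbor joining stands in for maximum-likelihood tree inference; for
  published-quality trees supply an external Newick file.
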