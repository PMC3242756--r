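---
title: "Subset strategies and permutation FDR for epistasis detection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Subset strategies and permutation FDR for epistasis detection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epistrat)
```

## The problem

Quantitative traits — gene-expression levels in particular — may be shaped
not only by single genetic variants but by interactions between pairs of
loci (epistasis).  Screening all pairs of markers for interactions is both
computationally heavy (the number of pairs grows quadratically: 2,931
markers already give `r format(epistrat::n_pairs(2931), big.mark = ",")`
pairs, and a few hundred thousand SNPs give tens of billions) and
statistically punishing, because the multiple-testing burden at the
pair level drowns true signals.  `epistrat` implements a framework for
comparing *subset strategies*: rules that nominate a much smaller set of
candidate SNP pairs before any interaction test is run, together with an
FDR estimator that makes strategies comparable and matched random
controls that ask whether a strategy's information actually helps.

## Models

For a phenotype $y$ and additively coded genotypes ($x \in \{0,1\}$ for
haploid cross segregants, $x \in \{0,1,2\}$ for diploid samples), the
marginal model is

$$y = \mu + \beta x + \varepsilon,$$

tested by a two-sided t-test on $\beta$ with $n-2$ df.  The epistasis
model for a SNP pair is

$$y = \mu + \beta_1 x_1 + \beta_2 x_2 + \beta_{12}\, x_1 x_2 + \varepsilon,$$

tested on the product-term coefficient $\beta_{12}$ with $n-4$ df.  The
interaction predictor is the product of the additive codes for both
ploidies.  Missing genotypes/phenotypes are handled per test by pairwise
complete cases.  p-values come from the t distribution rather than a
normal approximation because typical panel sizes (around a hundred
individuals) make the difference visible.  The pair scan accumulates the
4×4 normal equations per pair in compiled code; degenerate pairs
(identical SNPs, an absent genotype combination making the product
collinear, fewer than 5 complete cases, zero residual variance) yield
missing statistics and never abort a scan.  A condition-number guard
(reciprocal condition below 1e-12) flags near-singular designs.

A dominance-adjusted variant adds heterozygote indicator terms for each
diploid SNP ($n-6$ df on the product term) to check that an interaction
is not an artifact of dominance; when a SNP carries no heterozygotes the
dominance terms are inestimable and the additive model is used instead,
flagged in the result.

## Subset strategies and their controls

Given per-SNP marginal p-values, the **MM** (marginal-by-marginal)
strategy takes all pairs within the set $S$ of marginally associated
SNPs; **MG** (marginal-by-genomewide) takes all pairs with at least one
end in $S$; **ST** takes all SNP pairs whose genes are connected in a
protein-interaction network with confidence score strictly above a
threshold.  $S$ can be defined by a p-value threshold (inclusive
$\le$) or as the top-k SNPs by marginal p (ties broken by SNP index) —
the top-k form is the natural knob for sweeping subset size.  MM is a
subset of MG by construction.

Each strategy has a matched control that discards its information while
keeping its multiplicity: **MM⁰/MG⁰** run the marginal scan against a
freshly drawn standard-normal phenotype and apply the same selection
rule, and **ST⁰** draws gene pairs uniformly from unordered pairs of
network nodes (ignoring the edges) until the mapped SNP-pair count
reaches the candidate subset's size.  Controls are functions of their
seed alone, never of the measured expression data.

## Shared-permutation FDR

The unit of inference is the trait: does a trait have *at least one*
significant interaction in its subset?  That makes the per-trait minimum
p-value the test statistic.  Its null distribution is estimated by
permuting phenotype values; the key trick is that every trait is first
rank-transformed to normal quantiles — value $\Phi^{-1}((r-0.5)/m)$ for
rank $r$ of $m$ non-missing values, ties averaged, missing values set to
0 *after* transformation (0 is the transformed median).  All fully
observed traits then carry the identical value multiset, so **one** set
of K permutations of that shared template provides the null for every
trait.  For MM/MG the subset is rebuilt from a fresh marginal scan in
every permutation, because the subset itself depends on the phenotype;
for ALL/ST and all control strategies the fixed subset is reused.

The p-value cutoff is the $r$-th smallest of the K null values with
$r = \mathrm{round}(qK)$ (so $q=0.001$, $K=10{,}000$ and $q=0.01$,
$K=1{,}000$ both select the 10th smallest).  With $T$ traits scanned,
$qT$ traits are expected to pass under the null, giving the estimator

$$\widehat{\mathrm{FDR}} = \min\!\left(1, \frac{qT}{\#\mathrm{hits}}\right),$$

undefined when there are no hits.  Hit counting is inclusive
($\le$ cutoff).  A strategy is compared to its controls by the share of
controls achieving an FDR as low or lower; undefined control FDRs count
as 1.0 so the candidate is never unfairly favored, and an undefined
candidate FDR is excluded (reported NA) with a log note.

## The synthetic-data generator

The generator provides every input with known ground truth.  Haploid
genotypes emulate a two-parent cross: each individual is a two-state
Markov chain along the marker order, switching parental origin between
adjacent markers with probability `recomb_prob` (theoretical adjacent
correlation $1-2\cdot\texttt{recomb\_prob}$) — a single-knob stand-in
for the block LD of a linkage panel.  Diploid genotypes draw per-SNP
allele frequencies from `maf_range` and genotypes Binomial(2, f) under
Hardy–Weinberg, independent across SNPs.  Phenotypes are sums of planted
marginal terms, planted interaction terms and Gaussian noise; traits
without planted effects are pure noise.  Annotation partitions SNPs into
contiguous gene blocks, and the network includes a tunable fraction
(`causal_enrichment`) of the true interacting gene pairs as high-score
edges (scores Uniform(700, 999) vs Uniform(150, 699) for background), so
the information content of the ST strategy can be dialed from perfect to
none.

Defaults are fixed once as the study conditions: 112 individuals (a
typical cross panel), `recomb_prob` 0.1, diploid MAF range (0.2, 0.5)
matching the MAF > 0.20 filtering regime, unit noise SD, and a
20-gene/30-edge network at enrichment 0.5.

What the generator does *not* emulate: population structure and
relatedness, genotyping error, batch and environmental effects,
heavy-tailed expression noise, and realistic LD between unlinked
regions.  Passing tests therefore demonstrate correctness of the
machinery and its calibration under clean conditions, not performance on
real cohorts.

### A caveat worth knowing: rank transforms can erase interactions

One property discovered while validating the pipeline end to end: if a
pair carries strong marginal effects *and* an interaction such that the
four genotype-combination means are a monotone sequence (e.g. 0, 0.5,
0.5, 2), the rank-normal transform can map them onto a nearly additive
pattern, wiping out $\beta_{12}$.  A *pure* planted interaction survives
the transform — and itself induces marginal associations at the two
SNPs, which is exactly the regime in which marginal-information
strategies can outperform their controls.  The strategy-comparison
tests therefore plant interaction-only architectures; the switch
between the two regimes is the presence of explicit `marginal_effects`
rows in the simulation configuration.

## Numerical and design choices

- Quantile-transform offset $(r-0.5)/m$; the Blom offset $3/8$ is
  available through the `offset` argument.  Ties get average ranks.
- MAF filters use strict `>`; the trait-SD filter uses inclusive `≥`;
  network-score thresholds are strict `>`; marginal-p thresholds and hit
  counting are inclusive `≤`.
- Pairs are always stored with the smaller SNP index first,
  deduplicated; self-pairs are rejected.
- Genes are 1-based fully closed intervals; the SNP-gene window extends
  the gene body by `window_bp` (default 1000) on both sides, and SNPs
  hitting two or more extended bodies are excluded from the map.
- Degenerate tests return missing p-values; a trait whose whole subset
  is degenerate gets min-p 1.0 and can never be a hit.
- An FDR above 1 is capped at 1; `round(q*K) < 1` is an error
  ("insufficient permutations") rather than a silent extrapolation.
- Reproducibility: every random component (permutations, controls,
  simulations) takes an explicit seed, and simulation sub-draws use
  fixed seed offsets so genotypes, phenotypes and annotation are
  independently reproducible.

## Problem sizes used in the test suite

The packaged experiments run at desk scale, chosen to keep the full
suite in a few minutes while leaving the statistical assertions
well-powered: null calibration uses 200 quantile-transformed null traits
× 100 haploid SNPs × 112 individuals with K = 1,000 shared permutations
across four strategies (the fraction of traits passing the q = 0.01
cutoff must sit within 3 binomial standard errors of 0.01); power
checks use 200 replicates of a planted $\beta_{12} = 1$, noise SD 0.25
interaction; and the strategy-vs-control comparisons use 20 replicate
worlds per regime with K = 200 permutations and 10 controls per world.

## Limitations

- The MM strategy can, by construction, only find interactions between
  SNPs with detectable marginal associations; purely epistatic pairs
  without any induced marginal signal are invisible to it (and largely
  to MG).  The ST path finds them only if the genes are annotated
  partners.
- The expected-false-positives FDR estimator targets the trait level,
  not the pair level; with few hits its variance is large, and it is
  most informative at moderate FDR values.
- With a fixed p-threshold (rather than top-k), MM/MG subsets built on
  permuted phenotypes are typically much smaller than on real traits,
  which makes the null slightly conservative; the top-k parameterization
  avoids the size mismatch and is the default sweep knob.
- The compiled kernel fits each pair independently; no incremental
  updates across overlapping pairs are attempted, trading some speed for
  simplicity and exact agreement with the per-pair oracle.
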