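---
title: "Methods: haplotype accounting, directional analysis and island genetics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: haplotype accounting, directional analysis and island genetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phylodapp)
```

## Scope and model of the data

`phylodapp` implements the analysis chain used in mitochondrial
phylogeography of patchily distributed taxa whose ranges break into
*distributional islands* — geographically and genetically distinct blocks
of habitat. The data model is:

* an **alignment** of one or more mtDNA gene partitions per specimen
  (0-based, half-open column intervals; protein-coding partitions may
  declare a reading frame);
* a **specimen table** mapping each specimen to a *general locality* (a
  pooled sampling site treated as a population);
* a **locality table** with WGS84 decimal-degree coordinates and optional
  trapping-effort counts;
* an **island table** with `log10` areas (km²), per-island sample sizes
  `n` and observed unique-haplotype counts `h`.

Tree inference, model selection and divergence dating are out of scope;
the package covers everything downstream of an alignment that does not
require a phylogeny.

## Haplotype accounting

`collapse_haplotypes()` partitions specimens into equivalence classes of
identical sequences over a chosen scope (one partition, or the
*composite* concatenation of all partitions). The default matching is
**strict**: gap, `N` and IUPAC ambiguity codes are literal states that
match only themselves. This is the reproducible reading of
character-identity-based haplotype declaration; an **ambiguity-tolerant**
mode is provided in which a sequence joins an existing class only when it
is compatible at every column (processed in sorted specimen order, so the
result is deterministic). Both modes are exposed because tools differ in
how they treat ambiguity codes when declaring haplotypes unique, and the
choice changes counts on real data containing `N`s. Representatives and
haplotype numbering are tie-broken lexicographically by sorted specimen
id, so output is stable across runs.

A specimen missing an entire partition is excluded from composite
collapsing (with a message): a composite haplotype is only defined when
every gene was sequenced.

A haplotype observed at exactly one general locality is **private**; one
observed at `m ≥ 2` localities is **shared** and contributes all
`choose(m, 2)` unordered locality pairs to the directional analysis
(`classify_private()`, `sharing_pairs()`). Pairs are grouped by the clade
of their localities; a pair bridging clades is tallied separately as
`cross-group`, which clade-structured data should leave empty.

## Directional analysis of phylogeographical patterns (DAPP)

Bearings between localities that share haplotypes are **axial** data: a
line between two localities has no preferred direction, so an angle θ and
θ + 180° are the same axis. All statistics therefore double the angles
onto the full circle, operate there, and halve mean directions back
(reporting both μ and μ + 180°).

`axial_bearing()` computes the initial great-circle azimuth on the
sphere, folded modulo 180°. Folding makes the A→B / B→A choice irrelevant
up to meridian convergence, which is bounded by Δλ·sin(φ); at Great Basin
scales (a 4° × 6° window near 40° N) this stays below about 3° in the
worst east-west case and well below 1° for predominantly north-south
pairs. The residual asymmetry is made deterministic by always measuring
from the lexicographically smaller locality id. A planar (plate carrée)
option exists for comparison with map-measured bearings; within the
default window the two differ negligibly.

Uniformity tests (all on doubled angles):

* **Rayleigh** (`rayleigh_test()`): Z = nR̄², P by the standard
  fourth-order series approximation, clamped to [0, 1]. Powerful against
  single-axis alternatives.
* **Rao spacing** (`rao_spacing_test()`): U = ½·Σ|Tᵢ − 360/n| over
  circular spacings. P is reported as a band (<0.10, <0.05, <0.01,
  <0.001, or ≥0.10) against a packaged critical-value table at those four
  levels. The table was computed by Monte-Carlo simulation of the exact
  null (2 × 10⁵ replicates per n up to 50; see the generation function
  referenced in `R/rao_table.R`), with linear interpolation between
  tabulated n. A packaged table keeps the test deterministic and fast;
  its agreement with a fresh null simulation is itself under test.
* **Kuiper** (`kuiper_test()`): rotation-invariant Kolmogorov-type test;
  the raw V is standardised to V* = V(√n + 0.155 + 0.24/√n) and P
  evaluated by the asymptotic series, truncated when terms fall below
  1e−12.

Two-sample tests (`mww_test()`, `watson_u2_test()`): the
Mardia–Watson–Wheeler uniform-scores test (chi-square with 2 df) and the
Watson U² test (asymptotic alternating series). Two numerical choices
matter here:

* **Exact small-sample P.** The asymptotic null of both tests is visibly
  shifted in the body of the distribution when the pooled sample is small
  (for two samples of 10 the Watson U² asymptotic P can differ from the
  exact permutation P by 0.05–0.10 around P ≈ 0.7). Because the
  permutation null is exactly enumerable at such sizes — `choose(20, 10)`
  = 184,756 arrangements — both tests switch to exact enumeration
  whenever the number of label arrangements is at most 250,000, and use
  the asymptotic forms above that, where their error is comfortably below
  Monte-Carlo resolution. The result object records which route was
  taken (`p_method`).
* **Ties.** Ranks use midranks, and the Watson U² empirical-CDF
  difference is evaluated once per distinct pooled value with tie-group
  weights (this makes U² exactly 0 for identical samples). When more
  than 10% of pooled values tie, a warning recommends the seeded
  Monte-Carlo P (`mc_reps`), which every test also offers.

Near-zero statistics are short-circuited to P = 1 in both series
evaluations (V* < 0.05, U² < 0.002), where the alternating series decay
too slowly for the term budget but the limit is 1 to numerical accuracy.

`dapp_pipeline()` runs the whole chain — bearings with full provenance
(haplotype, locality pair, angle, pattern), per-pattern axial summaries
and uniformity tests, and all pairwise pattern comparisons. Patterns with
fewer than 4 bearings are flagged under-powered and skipped by the
uniformity tests rather than producing meaningless P values.

## Haplotype–area curves and sampling completeness

`haplotype_area_regression()` fits ordinary least squares of `h` on
`log10` island area and reports slope, intercept, r², and the two-sided
slope t-test. On the packaged island fixture the nine-island fit gives a
slope of 12.918 haplotypes per log10 km² with r² = 0.922 (five-island
subset: 12.071, r² = 0.920) — the regression tests assert these to three
decimals. `haplotype_samplesize_regression()` adds hat-value leverage and
a leave-one-out slope/P table, flagging localities whose removal flips
the significance of the haplotype-count ~ sample-size relationship (a
single high-leverage locality can manufacture such a trend).

`completeness()` implements the equal-frequency urn estimator of
haplotype sampling completeness: with `n` individuals showing `h`
distinct haplotypes and a population of `k` equally frequent haplotypes,
the likelihood is L(k) ∝ k(k−1)…(k−h+1)/kⁿ (the Stirling-number factor
counting set partitions does not depend on k and cancels). With a uniform
prior on k over {h, …, k_max}:

* the **probability of completeness** P = L(h)/Σₖ L(k) — the posterior
  probability that every haplotype in the population was sampled;
* the **predicted haplotype number** ĥ = argmax L(k), the posterior mode
  (ties to the smaller k).

All likelihood arithmetic is in log space (`lgamma` and log-sum-exp), so
sample sizes up to 10⁴ are safe. The default prior bound `k_max = 1000`
is the value under which the estimator reproduces the published
small-sample completeness values exactly (e.g. P = 1/H₁₀₀₀ ≈ 0.134 at
n = 2, h = 1); it is exposed as an argument since the bound is a prior
choice, and results for n ≫ h are insensitive to it. ĥ is the posterior
mode, not the mean: for n = 2, h = 1 the mode is 1 (matching both
intuition and the published table) while the posterior mean over a wide
uniform prior is badly behaved. When n = h the sample carries no
information on unseen haplotypes, and `island_completeness()` marks such
rows not applicable; `completeness()` itself still evaluates the
posterior (with k_max = h it is forced to P = 1). The estimator assumes
equal haplotype frequencies; under frequency skew it is optimistic about
completeness, which is why the package reports it per island rather than
pooling.

## The synthetic-data generator

`sim_config()` fixes the study conditions the tests run under; its
defaults emulate the shape of a Great Basin mtDNA survey:

* 5 distributional islands spanning log10 areas 2.5–5.0, with true
  haplotype counts `k = max(1, round(a + b·log10A + N(0, σ)))` at
  a = −35, b = 13, σ = 2 (the fitted haplotype–area relationship of the
  packaged island fixture, with realistic scatter);
* 9 general localities per island and per-locality sample sizes
  1 + Poisson(3), matching a mean of ~4 individuals per locality;
* a 990-column alignment in three partitions (542 + 403 + 45), the
  protein-coding partition carrying frame 0;
* Poisson substitution counts: ~25 root-to-island-ancestor substitutions
  (≈5% between-clade divergence) and ~3 per within-island haplotype on a
  star genealogy, with instantaneous transition bias κ = 4 (a transition
  with probability κ/(κ+2));
* per-locality haplotype frequencies drawn from a symmetric Dirichlet(1);
* two designed orientation patterns mirroring the published sharing
  table: a concentrated axis at 20° with locality multiplicities
  {5,4,3,3,3,2,2,2,2,2} (30 axial pairs) and an isotropic "web" with
  multiplicities {6,7} (36 pairs).

Concentrated patterns draw each shared haplotype's axis from an axial von
Mises distribution (κ on doubled angles) and place its localities along
that axis, accepting the placement only when every realized pairwise
bearing is within a tolerance derived from the concentration; isotropic
patterns scatter localities uniformly in a disc, whose rotational
symmetry makes pairwise bearings exactly uniform in distribution
(collinear placement would spuriously concentrate them). Coordinates are
confined to a Great-Basin-like window (38–42° N, 114–120° W) so
spherical-versus-planar bearing differences stay within the documented
bounds. Every stage derives its own sub-stream deterministically from the
single configuration seed, so stages can be re-run independently and a
given seed yields byte-identical files.

What the generator does **not** emulate: coalescent genealogies within
islands (haplotypes radiate from a star), recombination (absent in mtDNA
anyway), frequency-dependent sampling, ambiguity codes or missing data,
and any coupling between the sharing geometry and the sequence content
(sharing sets are designed, not emergent). Passing recovery tests
therefore show that the estimators are consistent under their assumed
models, not that real data meet those assumptions.

## Divergence summaries and the McDonald–Kreitman test

Pairwise distances use **pairwise deletion**: each pair is compared over
the columns where both sequences carry an unambiguous base, which keeps
single-pair results well defined and matches the per-pair
"compared sites" semantics of the common distance software. The Kimura
two-parameter distance is d = −½·ln[(1−2P−Q)·√(1−2Q)]; when a logarithm
argument is non-positive (saturation) the pair is flagged undefined and
excluded-but-counted in group means rather than raising an error. K2P ≥ p
always holds where defined, and the implementation is cross-checked
against an independent distance routine in the tests.

The McDonald–Kreitman test (`mk_test()`) classifies each variable codon
into fixed differences (codon-state sets of the two groups disjoint;
classified between group-consensus codons) and polymorphisms (≥2 states
within a group; each minor state classified against the group majority).
Multi-step codons are decomposed into single-nucleotide steps averaged
over all minimal-step orderings (orderings through a stop codon are
dropped when avoidable), so counts can be fractional; raw and rounded
counts are both reported and Fisher's exact test runs on the rounded
table. The vertebrate mitochondrial genetic code is the default,
overridable by NCBI table id.

Three Fisher tail conventions are reported — one-tailed (the smaller
hypergeometric tail of the observed cell), doubled one-tailed, and
two-tailed by the minimum-likelihood rule — because published software
differs in its tail rule and the conventions can disagree dramatically on
asymmetric tables: for the table (0, 9; 11, 110) the one-tailed value is
≈0.439 while the minimum-likelihood two-tailed value is 1.0. Reporting
all three makes the choice explicit instead of silently matching any one
program.

## Problem sizes and reproducibility

The test suite builds every fixture in code (or ships it as small TSV
files), runs the circular-test calibration at 2,000 uniform-null
replicates of n = 30, compares analytic with Monte-Carlo P at
n ∈ {10, 30, 100} with 2,000 replicates, and runs 100-replicate recovery
studies for the mean-axis and area-slope parameters — sizes chosen so the
whole suite completes in well under a minute on one core while leaving
Monte-Carlo error well below the tolerances under test. All randomness is
seeded; `scripts/acceptance.R` recomputes the headline quantities from
scratch and writes them as JSON.

## Known limitations

* The bearing fold leaves a meridian-convergence asymmetry (≤ Δλ·sinφ);
  it is negligible in the default window but grows for continental-scale
  east-west pairs.
* The Rao band is a tabulated inequality, not a continuous P; use the
  Monte-Carlo option when a numeric P is required.
* The completeness estimator's equal-frequency assumption makes its P an
  upper bound under frequency skew.
* MK counting uses consensus codons for fixed differences; very deep
  within-group structure could misattribute a difference that a
  tree-aware method would place differently.
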