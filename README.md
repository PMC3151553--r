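# phylodapp

Analysis toolkit for mitochondrial phylogeography of patchily distributed
taxa — built around three questions that arise when a species' range
breaks into "distributional islands" of habitat:

1. **Who shares haplotypes with whom, and along which axes?**
   Aligned multi-gene mtDNA sequences are collapsed into unique composite
   haplotypes; haplotypes found at a single general locality are
   *private*, the rest are *shared*. Every shared haplotype at `m`
   localities yields `choose(m, 2)` locality pairs, and the great-circle
   bearings of those pairs are axial data (a line has no direction: θ ≡
   θ + 180°). The DAPP pipeline (directional analysis of
   phylogeographical patterns) doubles the angles, summarises each
   orientation pattern by its mean axis μ and resultant length R̄, tests
   uniformity (Rayleigh Z = nR̄², Rao spacing U, Kuiper V*), and compares
   patterns (Mardia–Watson–Wheeler W, Watson U²; exact permutation P for
   small samples).

2. **Does genetic diversity scale with island area?**
   The haplotype–area curve is an OLS fit h = a + b·log₁₀(area),
   formally analogous to a species–area curve but explained by
   mutation–drift equilibrium at the population level.

3. **Was sampling deep enough to have seen every haplotype?**
   An equal-frequency urn estimator: with `n` individuals showing `h`
   haplotypes from `k` equally frequent ones, L(k) ∝ k(k−1)…(k−h+1)/kⁿ;
   with a uniform prior on k, the probability of completeness is
   P = L(h)/Σ L(k) and the predicted haplotype number ĥ is the posterior
   mode.

Also included: base-composition chi-square homogeneity, uncorrected p and
Kimura two-parameter distances under pairwise deletion
(d = −½ ln[(1−2P−Q)√(1−2Q)]), transition/transversion ratios, saturation
series, the McDonald–Kreitman neutrality test under the vertebrate
mitochondrial code (all three Fisher tail conventions reported), and a
seeded synthetic-data generator that emulates clade-structured sequences,
locality geometry with controlled axial orientation, and island tables —
so the full chain is testable end to end without any external data.

## Worked example

The package ships a nine-island fixture (`log10` areas, sample sizes and
observed unique-haplotype counts) and a twelve-haplotype sharing fixture.

```r
library(phylodapp)

isl <- read_island_table(system.file("extdata", "islands_table4.tsv",
                                     package = "phylodapp"))
fit <- haplotype_area_regression(isl)
sprintf("slope = %.3f, r2 = %.3f, P = %.2g", fit$slope, fit$r_squared, fit$p_value)
#> "slope = 12.918, r2 = 0.922, P = 3.9e-05"
```

Each extra log₁₀ km² of island area adds ~13 unique haplotypes, and area
explains 92% of the variance — diversity and island size are tightly
coupled. Completeness of sampling per island:

```r
island_completeness(isl)[, c("island_id", "n", "h", "h_hat", "p_complete")]
#>              island_id  n  h h_hat p_complete
#> 1        western_clade 65 23    24    0.17276
#> 2        idaho_isolate  2  1     1    0.13359
#> 3    main_central_unit 61 31    38    0.00181
#> 4         mono_isolate  8  8    NA         NA
#> 5        eastern_clade 50 25    31    0.00680
#> ...
```

On the largest islands a few haplotypes likely remain unseen (ĥ > h,
small P); the `n = h` row is marked not applicable — when every
individual is a new haplotype the sample says nothing about how many
remain. Sharing structure:

```r
sh <- read_sharing_table(system.file("extdata", "sharing_table3.tsv",
                                     package = "phylodapp"))
grouping <- setNames(rep(sh$group, lengths(sh$localities)), unlist(sh$localities))
sharing_pairs(sh, grouping)$totals
#> central eastern western
#>      52       3      11
```

66 locality pairs in total, none bridging clades. With coordinates (here
from the synthetic generator, which designs a concentrated axis at 20°
plus an isotropic "web"), the DAPP pipeline recovers the orientation
structure:

```r
geo  <- simulate_localities_and_sharing(sim_config(seed = 42))
dapp <- dapp_pipeline(geo$sharing, geo$localities, geo$pattern_assignment)
ns <- dapp$patterns$northsouth
sprintf("mean axis = %.1f (and %.1f), Rbar = %.2f, n = %d",
        ns$summary$mu, ns$summary$mu_reciprocal, ns$summary$rbar, ns$summary$n)
#> "mean axis = 23.3 (and 203.3), Rbar = 0.91, n = 30"
ns$rayleigh
#> Rayleigh uniformity test (axial)
#>   statistic = 24.7534, n = 30
#>   P = 9.251e-11
dapp$comparisons[[1]]$watson_u2
#> Watson U2 two-sample test (axial)
#>   statistic = 0.9833, n = 30/36
#>   P = 7.443e-09
```

The concentrated pattern's uniformity is rejected and the two patterns
have clearly different angular distributions, while the isotropic web
pattern (not shown) stays consistent with uniformity.

## Layout

- `R/` — implementation: `data_io.R`, `haplotypes.R`, `divergence.R`,
  `mk_test.R`, `circular.R` (+ `rao_table.R`), `island_genetics.R`,
  `synthetic.R`
- `inst/extdata/` — island and sharing fixtures (TSV)
- `vignettes/phylodapp-methods.Rmd` — models, assumptions, numerical
  choices and limitations
- `tests/testthat/` — unit, property and acceptance tests
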