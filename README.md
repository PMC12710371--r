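# paircomm

Analysis of **paired RNA/DNA metabarcoding data**: the same physical
samples sequenced once from DNA (the *total* community — everything
present, including dormant cells and relic DNA) and once from cDNA (the
*active* community — taxa metabolically active at sampling time).

The package is for microbial ecologists running dual-assay amplicon
surveys of soils, rhizospheres or similar systems who want to go beyond
single-assay composition: quantify dormancy, separate seasonal activity
dynamics from population dynamics, and ask which "core" taxa are
actually active rather than merely present.

## What it computes

For aligned pairs with RNA detection set $A$ and DNA detection set $D$
per sample:

- **dormant fraction** $= 1 - |A|/|A \cup D|$ and **shared fraction**
  $= |A \cap D|/|D|$, per pair with mean ± SD summaries;
- **total and active core microbiomes**: taxa with occupancy $\ge \tau$
  (default 0.95) in the DNA or RNA assay respectively, plus a per-taxon
  **activity frequency** (fraction of DNA occurrences that are
  RNA-detected) that exposes core members persisting in dormancy;
- **community structure**: square-root + Wisconsin double
  standardization + Bray–Curtis, PERMANOVA (sequential SS, optional
  strata-restricted permutations), beta dispersion, PCoA, Mantel /
  partial Mantel distance decay against log geographic distance;
- **compositional differential abundance**: CLR values, per-taxon F
  statistics with within-block permutations and a median-of-effects
  compositional bias correction, BH adjustment, and the joint
  "significant *and* ≥2×" rule for active/total enrichment;
- **environment linkage**: PCA collapsing of correlated covariates,
  held-out permutation importance with partial-dependence curves and
  threshold localization, an exact-F scale-dependence (common vs
  per-site slope) test, and a logistic presence model with separation
  detection;
- a **synthetic paired-community generator** (hierarchical log-normal
  abundances, Bernoulli activity states with seasonal modulation,
  multinomial sequencing, planted core/enriched taxa with ground-truth
  ledger) used to validate every stage.

## Worked example

```r
library(paircomm)

params <- synth_params()              # 3 site types x 3 sites x 5 plots x 3 seasons
sim <- synth_community(params, seed = 42)
pc <- sim$paired                      # 135 aligned RNA/DNA pairs

dorm <- dormancy_profile(pc)
mean(dorm$dormant_fraction, na.rm = TRUE)
#> 0.424

sh <- shared_fraction(pc)
sprintf("%.1f%% (+/- %.1f%%)", 100 * sh$mean, 100 * sh$sd)
#> "54.6% (+/- 3.4%)"

core_report(pc)
#> <core_report> tau = 0.95 over 135 pairs: 97 total-core, 3 active-core taxa
#> (3 total-core frequently inactive)

design <- pc$pair_meta; design$sample_id <- rownames(design)
d_active <- bray_curtis(sqrt_wisconsin(pc$active))
permanova(d_active, design, c("site_type", "season"), n_perm = 999, seed = 1)
#>        term  df sum_of_squares         r2 pseudo_f     p
#> 1 site_type   2       2.179177 0.06952927 5.262439 0.001
#> 2    season   2       2.246179 0.07166703 5.424240 0.001
#> 3  Residual 130      26.916513 0.85880370       NA    NA
#> 4     Total 134      31.341869 1.00000000       NA    NA
```

Reading the output: on generator defaults roughly 42% of each sample's
detected taxa are dormant (DNA-only); about 55% of the total community
is detected as active in the matched RNA library; the active core is a
small subset of the total core, and some total-core taxa are flagged
frequently inactive — present nearly everywhere, active almost nowhere.
In the active community, season explains as much variance as site type
(R² ≈ 0.07 each); in the matching total-community table (not shown)
the seasonal R² drops to ~0.014 while site type rises — seasonal
turnover lives in activity states, spatial structure in populations.

Real data enter through `read_feature_table()` (TSV or BIOM 1.0 JSON),
`read_metadata()` (QIIME-style TSV with a `pair_id` column linking the
two assays of each physical sample), and `align_pairs()`; or run
everything at once with `run_pipeline()` on a YAML/list configuration.

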