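---
title: "Analysing paired RNA/DNA metabarcoding data: dormancy, active cores, and seasonal dynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analysing paired RNA/DNA metabarcoding data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paircomm)
```

## The problem

Amplicon surveys based on DNA profile the *total* microbial community:
everything present, including dormant propagules and relic DNA from
dead cells. Sequencing the same marker from cDNA (reverse-transcribed
rRNA/ITS transcripts) profiles the *active* community — the subset that
is metabolically switched on at sampling time. When both assays are run
on the same physical samples, the paired tables support a family of
questions no single-assay survey can answer:

* What fraction of each sample's community is dormant?
* Which "core" taxa (near-universally present) are actually active, and
  which persist only as dormant propagules?
* Does seasonal turnover act on population sizes (visible in DNA) or on
  activity states (visible only in RNA)?
* Which taxa are systematically more abundant in one assay — e.g.
  arbuscular mycorrhizal fungi that are scarce in DNA surveys but
  highly active?

`paircomm` implements this analysis framework end-to-end for a
hierarchical field design: site types (habitat classes), replicated
sites, plots along within-site transects, repeated seasonal sampling,
and two assays per physical sample.

## The statistics

**Dormancy fraction.** For one RNA/DNA pair with detection sets
$A$ (RNA) and $D$ (DNA), the dormant fraction is
$1 - |A| / |A \cup D|$. Detection is count $\ge$ 1 after rarefaction by
default (the simplest faithful reading of "observed"; the threshold is
configurable). Pairs with an empty union are reported as undefined
rather than imputed, so they cannot bias summaries.

**Shared fraction.** $|A \cap D| / |D|$ per pair: the proportion of the
total community detected as active in the matched sample.

**Cores and activity frequency.** A taxon is in the *total core* when
its occupancy (fraction of samples with a detection) in the DNA assay
is at least $\tau = 0.95$, pooled over all site types and seasons, and
in the *active core* under the same rule on the RNA assay. The
threshold is applied as $\ge$ and the denominator is the set of samples
retained after rarefaction. Per taxon, the *activity frequency* is the
fraction of its DNA occurrences that are also RNA-detected; total-core
taxa below an activity frequency of 0.5 are flagged as "frequently
inactive" — the pattern of core members that owe their core status to
dormant persistence.

**Community structure.** The dissimilarity chain is square-root
transform, Wisconsin double standardization (taxon maximum first, then
sample total — exactly that order), and Bray–Curtis. PERMANOVA
(sequential sums of squares, terms in user order) partitions the
distance matrix by design terms; permutations are free by default and
can be restricted within strata (e.g. sites, when testing season in a
plots-within-sites design, where free permutation inflates
significance). Beta dispersion is the distance to the group centroid in
principal-coordinate space. Distance decay is the Mantel correlation of
community dissimilarity with log10 geographic distance, per season and
on season-averaged distances, with a partial Mantel variant controlling
a soil-chemistry distance matrix.

**Ordination.** PCoA (classical scaling) is used as the deterministic
ordination whose axes feed the environment screen. NMDS would serve the
same visual purpose but brings stress-minimization convergence
ambiguity into downstream regressions; PCoA has a closed-form solution,
reports its negative-eigenvalue diagnostic, and is exactly testable
against Euclidean geometry.

**Differential abundance.** Counts are CLR-transformed (pseudocount
0.5, the standard half-count correction). Each taxon gets a linear
model with the blocking factor (site, or the pair id for the
active/total contrast) as a fixed additive effect; the design term is
judged by its F statistic against within-block permutations, with BH
adjustment across tested taxa (default prevalence filter 10%). One
subtlety is essential: if even a few taxa are genuinely enriched in one
group, the CLR reference of every sample in that group shifts, handing
all null taxa a spurious common effect. The screen therefore removes
the median of the per-taxon group effects (an estimate of that common
shift, the core idea of bias-corrected compositional testers) *inside*
the test statistic, recomputed for every permuted labelling, so the
permutation reference remains exact. "Enriched between active and
total" requires both BH significance and a fold change of at least 2
($|\log_2 FC| \ge 1$); site-type and season screens use significance
only. Because p-values are permutation-based, their floor is
$1/(n_{\mathrm{perm}}+1)$; screens over hundreds of taxa need the
default 999 permutations for BH-adjusted calls at 0.05.

**Environment linkage.** Correlated covariates are collapsed to
first-principal-component indices (e.g. total organic carbon, cation
exchange capacity and calcium into a soil-organic-matter index), with
scores standardized and sign-anchored to the first-named member.
Covariate importance is held-out permutation importance under a
pluggable regressor contract (`fit`/`predict`); the default backend is
a random forest, but the contract means tests can use a deterministic
least-squares stub. Partial-dependence curves are evaluated on 50 grid
points between the 2.5th and 97.5th percentiles — clipping the edges
keeps extrapolation artifacts out of the threshold search.
`locate_threshold()` reports the grid interval holding the largest
absolute first difference when that jump exceeds `min_jump` (default
0.5) times the interquartile range of the curve, and reports "none"
otherwise.

**Scale dependence.** For a plot-level association, a common-slope
model (site intercepts + one slope) is compared against a per-site-slope
model. The likelihood ratio is $n \log(\mathrm{RSS}_A/\mathrm{RSS}_B)$
with $n_{\mathrm{sites}} - 1$ degrees of freedom. Because the LRT for
nested Gaussian linear models is a monotone function of the F
statistic, the primary p-value uses the exact
$F(n_{\mathrm{sites}}-1,\, n-p)$ null distribution rather than the
asymptotic chi-square, which is anticonservative at realistic design
sizes (tens of plots); the chi-square p is also reported. Sensor-style
covariates that are constant within a site are handled at site level
(site-mean response regressed on the site covariate) since a site fixed
effect would absorb them entirely.

**Presence model.** Logistic regression (IRLS via `glm`) for the
probability of detecting a taxon group as a function of a covariate,
with Wald intervals. Complete separation is detected (divergent linear
predictors or non-convergence) and flagged instead of reporting a
meaningless Wald p.

## The synthetic generator

`synth_community()` generates paired tables with the statistical
structure the analysis assumes, so every stage is testable without any
sequencing data. Defaults are fixed once as the emulated study
conditions:

| parameter | default | what it encodes |
|---|---|---|
| design | 3 site types × 3 sites × 5 plots × 3 seasons | 135 pairs, 270 libraries |
| `n_taxa`, `depth` | 500, 20,000 | richness and library size |
| `base_abundance_sd` | 1.5 | log-normal rank-abundance |
| `plot_effect` > `site_effect` > `site_type_effect` | 1.2 > 0.9 > 0.6 | hierarchical composition; fine spatial structure dominates |
| `season_population_amplitude` | 0.25 | seasonal change in true abundance |
| `season_activity_amplitude` | 0.9 | seasonal change in activity probability |
| `activity_prob` | 0.6 | baseline probability a taxon is active in a sample |
| `activity_intensity_sd` | 0.5 | graded metabolic rates of active taxa |
| `core_taxa` | 8 taxa, occupancy 1 | activity probabilities 0.9×5, 0.3, 0.2, 0 — including always-present-never-active members |
| `enriched_taxa` | 10 taxa | RNA:DNA ratios 4×5 and 0.25×5 |

True abundance is log-normal with additive site-type, site and plot
offsets plus a per-taxon seasonal loading. Activity is a per-sample
Bernoulli on a logit scale carrying the seasonal activity loading and,
optionally, a dormancy slope against the site organic-matter field;
active taxa additionally receive a continuous log-normal intensity, so
activity is graded, not just binary. Both assays are sampled as
fixed-depth multinomials — compositionality enters through the
sequencing mechanics, as in real amplicon data. Planted core taxa have
damped hierarchical and seasonal abundance variance (habitat
generalists); that is what makes a 100% occupancy target attainable at
finite depth. Planted enriched taxa are set always-active with no
seasonal activity loading so the planted RNA:DNA ratio is the clean
expected fold change. The seasonal amplitude ordering (activity ≫
population) makes seasonal turnover concentrate in the RNA assay while
spatial structure dominates the DNA assay — the qualitative contrast
the framework is designed to detect. The choice of site-level
environmental fields (riparian sites warmest and iron-rich,
high-elevation sites coldest and most organic-matter-rich) mirrors
typical montane gradients.

What the generator does *not* emulate: ribosomal copy-number variation
between taxa, primer and PCR bias, chimeras, relic-DNA decay dynamics,
spatially autocorrelated plot effects beyond the site hierarchy, and
multi-year trends. Passing tests on generator output therefore
demonstrate the statistical machinery is correct under the stated
model, not that these measurement biases are overcome on real data.

`expected_dormant_fraction()` is a deliberately separate Monte-Carlo
code path (independent per-pair simulation) used as the oracle in
parameter-recovery tests; note that the expected dormant fraction is
*not* simply one minus the activity probability — finite-depth
detection in both assays enters, which is exactly why the oracle
simulates rather than computes a closed form.

## Numerical and design choices

* All permutation p-values are $(b+1)/(m+1)$ and every stochastic step
  takes an explicit seed; the pipeline derives per-stage seeds from one
  global seed by stage-name hashing.
* Rarefaction is a single seeded subsample without replacement per
  table; samples under the depth are dropped and logged.
* Pairing is by an explicit `pair_id` metadata column, never by
  sample-name munging, and the RNA/DNA tables are zero-filled on the
  union of taxa so set statistics are well defined.
* Ties in Spearman Mantel use average ranks (the default of the
  underlying correlation).
* Degenerate inputs error loudly and specifically: all-zero samples,
  empty pair intersections, constant distance triangles, one-level
  terms, confounded term/block pairs, single-class presence outcomes,
  sites with constant covariates.
* In the seasonal delta contrast, when both site partitions have zero
  variance (e.g. literally identical abundances across seasons) the
  Welch test is undefined; the contrast reports p = 1 when the
  partition means agree, rather than failing.
* BIOM input is JSON 1.0 (dense and sparse); feature tables are
  oriented taxa × samples (observation-major). Counts must be integral
  before rarefaction; relative-abundance matrices are a separate,
  explicitly produced object, which prevents silent double
  normalization.

## Problem sizes used in the test suite

The suite validates each statistic against independent oracles
(brute-force double loops, exhaustive permutation enumeration,
closed-form cases, Monte-Carlo simulation). Simulation-based checks use
200 replicates at 199 permutations for type-I calibration, 50
replicates of the full default design for the seasonal-contrast
property, a 3-point activity-probability grid with 4 generator
replicates against a 400-pair oracle for dormancy recovery, and 8
replicates of a 200-taxon clean design for enrichment recovery — sizes
at which the Monte-Carlo error of each check is small relative to the
property being asserted.

## Known limitations

* The active/total contrast treats RNA detection as activity; ribosomes
  persisting in dormant cells (a recognized caveat for 16S) are outside
  the model.
* The differential-abundance screen uses a fixed block effect, not a
  random one; with few blocks and strong block-by-term interactions its
  effect estimates are conditional on the observed blocks.
* The scale-dependence test is a fixed-effects approximation of a
  random-slope comparison; it answers "do within-site slopes differ
  from the among-site slope" without shrinkage across sites.
* Permutation p floors mean small designs cannot reach small
  BH-adjusted thresholds; the floor is reported implicitly through
  `n_perm` in every result object.
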