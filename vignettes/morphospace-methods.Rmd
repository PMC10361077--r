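---
title: "Morphospace occupancy of fragmented populations: models and methods"
author: "morphospace package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Morphospace occupancy of fragmented populations: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(morphospace)
```

## The scientific question

When a generalist species is fragmented into isolated populations — worker
ants confined to separate urban parks are the motivating case — two distinct
mechanisms can reshape each population's functional morphology:

* **filter strength**: habitats differ in the range of phenotypic variation
  they support, contracting or expanding the *volume* of trait space a
  population occupies;
* **optimum shift**: habitats differ in their phenotypic optimum, *moving*
  the population's position in trait space.

This package treats each individual as a point in a morphospace built from
six continuous functional traits (Weber's length, head width, eye width,
mandible length, scape length, hindleg length; all mm), and each population
as a point cloud in that space. Occupied morphospace is measured by
convex-hull volume, position by the cloud centroid. Both are tested against
a pooled random-draw null model.

## The pipeline, stage by stage

### Ordination

Traits are standardized to zero mean and unit variance and decomposed by
eigenanalysis of the correlation matrix. Correlation (rather than
covariance) PCA is the default because the six traits differ in scale by an
order of magnitude — eye width is ~0.1 mm against a hindleg of ~1.3 mm —
and loadings stored as `eigenvector * sqrt(eigenvalue)` are then
trait-component correlations in `[-1, 1]`. The switch
`pca_matrix = "covariance"` is available should raw-scale analysis be
preferred.

The first `k_dims = 4` components are retained and rotated by raw varimax
(no Kaiser row normalization; `varimax_normalize = TRUE` restores it).
Varimax maximizes the variance of squared loadings per component, giving
each component a compact trait interpretation (size, sensory, trophic,
exploratory axes). Scores are rotated by the same orthogonal matrix.
Variance-explained percentages are reported pre-rotation (rotation
redistributes variance across components; the redistributed shares are
stored separately as `variance_explained_rotated`). Each loading column is
signed so its largest-magnitude entry is positive, making loadings tables
reproducible across linear-algebra backends.

A consequence worth noting: because the rotation is orthogonal, every hull
volume and centroid distance downstream is *identical* between
`scores = "rotated"` and `scores = "unrotated"` — the switch affects only
how axes are labelled and plotted. The test suite asserts this, which
retires the question of which variant the occupancy statistics should use.

### Hull geometry

Convex hulls are built by an incremental beneath-beyond algorithm with
facet half-space inequalities $u \cdot x \le b$ (unit outward normals) and
*exact* facet-based volumes via simplicial decomposition around an interior
point; the implementation is cross-checked in the tests against an
independent qhull implementation and against Monte Carlo membership
sampling. Membership uses the facet inequalities with tolerance
$10^{-9}$ (scaled to the data), boundary counting as inside — a
measure-zero convention fixed for determinism.

Affinely degenerate point sets raise an error carrying the observed affine
rank instead of silently returning a flat hull: silent dimension loss would
corrupt volume comparisons. Populations need at least `k_dims + 1`
individuals to span a hull.

Set operations (union, uniquely occupied regions, pairwise overlap) are
estimated by rejection sampling in the axis-aligned bounding box of all
hull vertices — exact polytope boolean algebra in four dimensions would be
disproportionate engineering for no statistical gain. Each region fraction
carries its binomial standard error $\sqrt{p(1-p)/n}$. The default
`mc_points = 1e5` resolves percentages to a standard error of about 0.16
points. One known weakness of box sampling: when hulls are far apart the
union occupies a vanishing fraction of the box and the estimates degrade;
at the separations realistic for conspecific populations (hulls overlapping
or adjacent) the union occupies a usable fraction of the box.

### Resampling and the null model

Sampling effort is equalized by drawing `subsample_size = 10` workers per
population (without replacement within a draw), `n_subsamples = 100` times,
giving per-population distributions of hull volume and of the distance from
the sub-sample centroid to the grand centroid (the unweighted mean score
over *all* individuals pooled). The null model draws the same-size
sub-samples from the pooled individuals, `n_null = 1000` times. Two-sided
Mann-Whitney U tests (normal approximation with tie correction) compare
each population's replicate list to the null's, at `alpha = 0.001`;
the direction of the median difference classifies populations as
*clustered*/*expanded* (volume) or *displaced*/*converged* (centroid).
No multiple-testing correction is applied, matching the fixed
study-wide threshold.

### Morphological dissimilarity

One hull per population (all of its individuals) enters a single occupancy
estimate: the percentage of the pooled (union) morphospace inside exactly
one population's hull is that population's unique contribution, and the
uniques sum to the total dissimilarity *exactly* because they share one
Monte Carlo point set. Pairwise turnover between populations $a$ and $b$
is $100\,(V_{a\cup b}-V_{a\cap b})/V_{a\cup b}$.

No published construction exists for attaching significance to the unique
percentages, so the package supplies its own, clearly labelled as such: a
label-permutation null (population labels shuffled over individuals
`n_perm = 999` times, group sizes preserved, unique percentages recomputed
with a lighter `perm_mc_points = 2e4` sample, two-sided rank p-value).

### Seeding

A master seed spawns named substreams (hashed from stage name or population
label), so per-population draws are independent of population ordering, and
analysis stages see individuals in a canonical label-sorted order. Reports
are therefore invariant to how population blocks are arranged in the input
file, and identical seeds give byte-identical reports.

## The synthetic world

Real measurement data cannot ship with the package, so `default_design()`
fixes a seven-population study emulating the intended use: sample sizes
19, 15, 15, 18, 38, 15, 43 (163 individuals), trait means typical of a
small myrmicine worker with ~7% coefficients of variation, and a
single-"body-size"-factor correlation structure (loadings 0.84, 0.81,
0.42, 0.50, 0.60, 0.74) whose first standardized principal axis carries
~53% of the variance and whose first four axes carry ~88% — the
size-dominated structure typical of ant morphometrics. Three populations
carry designed effects: one contracted (`cov_scale = 0.3`), one displaced
(about 2 pooled SD, deliberately off the size axis), one untouched
reference. Draws are multivariate normal with redraw-on-nonpositivity;
means sit many SDs above zero, so truncation is rare and the Gaussian
structure the recovery tests assume is essentially intact.

What the generator does *not* emulate — caste polymorphism, allometric
curvature, measurement error, spatial structure within parks — bounds what
passing tests show: they validate the estimator pipeline, not the biology
of any particular data set.

## Calibration findings and known limitations

The test suite includes an error-rate calibration: 200 replicates of a
homogeneous seven-population world (no designed effects; 50 sub-samples
per population against 250 null draws — sizes chosen to keep the suite
affordable; the effect below only grows with larger replicate counts),
counting how often a population is flagged at `alpha = 0.001`.

**The pooled-null Mann-Whitney design is severely anti-conservative.** The
N sub-sampled replicates of one population re-use the same 15-43
individuals and are strongly dependent, while the U test assumes
independent samples; its effective sample size is closer to the number of
individuals than to N. Measured false-flag rates are ~0.42 per volume
test and ~0.28 per centroid test — orders of magnitude above nominal — and
under the default design the untouched reference population is flagged in
~28% of replicates. Detection of real effects is correspondingly easy (the
contracted and displaced populations are recovered in 50/50 replicates),
but a significant flag from this procedure cannot be read as a calibrated
p < 0.001 statement. A second distortion compounds it: a strongly
displaced population inflates the pooled null's volumes, so unrelated
populations can appear "clustered" relative to it.

The package implements the procedure as published because reproducing it
is the point; users wanting calibrated inference should treat the
replicate medians as descriptive statistics and derive significance from
a design-level resampling (e.g. bootstrapping individuals, not
sub-samples), which is outside the present scope. The permutation null
for unique volumes does not suffer from this issue (each permutation
replicate re-draws at the individual level), but its Monte Carlo
resolution is limited by `perm_mc_points`.

Other limitations: hull volumes in 4-D need `subsample_size >= 5` and are
noisy at 10; box-rejection sampling degrades for widely separated hulls;
and degenerate (affinely dependent) populations are an error, not a
fallback to lower dimension.

## Problem sizes used by the shipped checks

The packaged tests run the geometry oracles at $10^5$–$10^6$ Monte Carlo
points, the calibration study at 200 replicates and the recovery study at
50 replicates (50 sub-samples / 250 null draws each), and exercise the full
pipeline at reduced replicate counts. The acceptance script
(`scripts/acceptance.R`) runs the complete default configuration
(100 sub-samples, 1000 null draws, 999 permutations, $10^5$ Monte Carlo
points) on the default design.

```{r example, eval = FALSE}
tab <- generate_traits(default_design(), seed = 1)
fit <- morphospace(tab, config = morphospace_config(seed = 1))
summary(fit)
plot(fit)
```
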