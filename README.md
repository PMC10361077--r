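# morphospace

Convex-hull morphospace analysis of fragmented populations.

When a species is split into isolated populations — the motivating case is
worker ants of a generalist species confined to separate urban parks — each
habitat can act on functional morphology in two distinct ways. It can
*filter*: supporting a narrower range of phenotypes and contracting the
volume of trait space the population occupies. Or it can *shift the
optimum*: favouring a different phenotype and moving the population's
position in trait space. `morphospace` quantifies both from a simple
per-individual trait table, for ecologists and morphometricians comparing
labelled populations of one species.

## The model

Each individual is a point in a morphospace built from six functional
traits (Weber's length, head width, eye width, mandible length, scape
length, hindleg length; mm). The pipeline is:

1. **Ordination** — PCA on the trait correlation matrix, first *k* = 4
   components retained and varimax-rotated; loadings are trait–component
   correlations, scores carry the individuals into 4-D morphospace.
2. **Occupied volume** — for each population, the exact volume of the
   convex hull of repeated sub-samples of *m* = 10 individuals (100
   replicates), equalizing sampling effort across unequal samples.
3. **Position** — the Euclidean distance of each sub-sample centroid from
   the grand centroid of all individuals pooled.
4. **Null model** — the same statistics for 1000 random draws of *m*
   individuals from all populations pooled; two-sided Mann–Whitney U tests
   flag populations as clustered/expanded (volume) or displaced/converged
   (centroid) at α = 0.001.
5. **Morphological dissimilarity (MD)** — the pooled morphospace
   ∪ᵢ hull(popᵢ) is decomposed by Monte Carlo sampling into the
   percentage occupied uniquely by each population (with a
   label-permutation significance test) and pairwise turnover
   100·(V(a∪b) − V(a∩b))/V(a∪b).

A seeded synthetic generator (`default_design()`, `generate_traits()`)
emulates a seven-population study (163 individuals, size-dominated trait
correlations, one contracted population, one displaced, one reference) so
every stage is testable without measurement data.

## Worked example

```r
library(morphospace)

tab <- generate_traits(default_design(), seed = 1)   # or read_trait_table("traits.csv")
cfg <- morphospace_config(n_subsamples = 50, n_null = 200, n_perm = 99,
                          mc_points = 20000, perm_mc_points = 5000, seed = 1)
fit <- morphospace(tab, config = cfg)
fit
#> Morphospace analysis
#>   163 individuals, 7 populations analysed (k = 4 components, 89.4% of variance)
#>   morphological dissimilarity: 60.6% of pooled morphospace uniquely occupied
#>   populations departing from the pooled null at alpha = 0.001: 3 (volume), 4 (centroid)
#>   use summary() for per-population tables
```

`summary(fit)` prints the per-population tables; the key blocks (here the
designed effects are P2, contracted, and P4, displaced):

```
Convex hull volume vs pooled null:
 population median null_median  p_value    status
         P1  4.650        3.57 8.55e-04  expanded
         P2  0.739        3.57 7.25e-27 clustered
         P3  3.250        3.57 1.93e-01        ns
         P4  2.080        3.57 7.77e-11 clustered
         P5  3.470        3.57 3.89e-01        ns
         P6  3.460        3.57 7.71e-01        ns
         P7  3.590        3.57 9.91e-01        ns

Centroid displacement vs pooled null:
 population median null_median  p_value    status
         P1  0.495       0.587 7.65e-04 converged
         P2  0.411       0.587 8.02e-09 converged
         P3  0.969       0.587 1.31e-12 displaced
         P4  1.660       0.587 2.28e-25 displaced
         ...
```

Reading it: P2's sub-sampled hulls (median volume 0.739) sit far below the
pooled-null band (3.57) — strong trait clustering; P4's centroid sits 1.66
score units from the grand centroid against a null median of 0.59 — a
shifted optimum. The unique-volume table and the turnover matrix (lower
triangle %, upper triangle volume-difference p-values) decompose the
pooled morphospace among populations. `plot(fit)` draws the two boxplot
panels against the null band. Note the flags P1/P2/P3 pick up: the
calibration study in the methods vignette shows this null-model test is
strongly anti-conservative, so treat flags as descriptive, not as
calibrated p < 0.001 statements.

From the shell:

```sh
Rscript inst/cli/morphospace-cli.R simulate --out-dir data --seed 1
Rscript inst/cli/morphospace-cli.R analyze data/traits.csv --out-dir report --seed 1
```

`analyze` writes `volume_tests.csv`, `centroid_tests.csv`,
`unique_volume.csv`, `turnover.csv`, `loadings.csv`, a `summary.json` with
every statistic, and a `manifest.json` (input digest, config, seed,
stage timings) sufficient to re-run the analysis identically.

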