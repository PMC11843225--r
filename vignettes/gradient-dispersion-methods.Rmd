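---
title: "Mapping interindividual variability of functional gradients and its behavioral correlates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping interindividual variability of functional gradients and its behavioral correlates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(graddisp)
```

## The scientific problem

Resting-state functional connectivity can be summarized by *functional
gradients*: latent axes along which every cortical location receives a
coordinate, such that nearby coordinates imply similar connectivity
profiles. The first three gradients are the workhorses — a sensory-to-DMN
axis, an axis separating frontoparietal from default-mode territory, and a
visual-to-somatomotor axis. `graddisp` implements an analysis stack built
around one question: *where* in the cortex do individuals differ most in
their gradient coordinates, and do those differences covary with cognitive
ability?

The stack has five stages:

1. **Embedding** — place all subjects' vertices into one shared K=3
   gradient space via a two-step generalized canonical correlation analysis
   (GCCA).
2. **Dispersion mapping** — for every vertex, measure the spread of
   subjects around the group centroid in gradient space; extract contiguous
   clusters of maximal dispersion on the cortical mesh.
3. **Behavioral composites** — build crystallized, fluid and general
   intelligence scores from ten task measures and residualize confounds.
4. **Inference** — model intelligence from the clusters' gradient
   coordinates with stratified cross-validated permutation tests, FDR
   control, and lockbox (hold-out) validation.
5. **Topology** — profile the clusters' graph-theoretic role in
   cluster-augmented parcellation networks.

Because the motivating data (large multi-run resting fMRI cohorts with
cognitive batteries) are access-restricted, the package ships a
synthetic-cohort generator that plants known gradients, dispersion hotspots
and brain–behavior couplings, so every stage can be validated against
ground truth.

## The two-step group embedding

Each subject's vertex-by-time matrix is z-scored per vertex within each
acquisition run and the runs are concatenated (`normalize_concatenate()`).
Constant series map to zeros rather than being dropped, so vertex indexing
stays aligned across subjects.

Step one (`subject_decomposition()`) computes the top-r singular triplets
of each subject's matrix. The component count r is not prescribed by the
two-step construction; the default keeps the smallest r reaching 50% of
subject variance, capped at 10 (`target_variance`, `max_rank`). Step two
(`group_decomposition()`) concatenates all subjects' component score
matrices column-wise — after scaling each subject's columns to unit norm so
every subject contributes equal energy — and takes the top-K left singular
vectors as the group gradients. Each subject is then projected into the
group space (`project_subject()`): because the subject's score columns are
orthonormal, the least-squares representation of gradient `g` within the
subject's component subspace is `U (U' g)`.

SVD leaves every axis's sign arbitrary. Subject coordinate columns are
flipped to correlate positively with the matching group gradient
(`align_signs()`; zero-variance columns are flagged and left at +1), and
group gradients themselves are sign-fixed against a template when one is
available (in synthetic mode, the planted maps), otherwise by making the
largest-magnitude element positive. Gradient order is by group singular
value only; no reordering to match external conventions is attempted.

Since the two-step construction has no single explained-variance number,
`variance_profile()` reports two curves: the mean subject-level variance
fraction per component, and that fraction multiplied by the cumulative
group-level explained-variance fraction.

## Dispersion and cluster extraction

For vertex v with subject coordinates `x_s(v)` in K dimensions, the group
centroid is the arithmetic mean and dispersion is the sum of squared
Euclidean distances `sum_s ||x_s(v) - c(v)||^2`, decomposed additively per
axis (`vertex_dispersion()`). The mean is used (not the median) because it
is the minimizer of this statistic; a `normalize` flag divides by (n-1)
for cross-cohort comparability but the raw sum is the default. Dispersion
is translation-invariant at each vertex and equals the trace of the
per-vertex scatter matrix — both are enforced by tests.

`extract_clusters()` thresholds the total dispersion map at a percentile
(default 95th, linear-interpolation quantile, strictly-greater comparison),
partitions suprathreshold vertices into connected components under mesh
edge adjacency (no geodesic dilation or gap bridging), drops components
below a minimum area (default 200 mm^2, using per-vertex barycentric areas),
and orders clusters by descending area. An empty result is a valid outcome,
not an error. Per-subject cluster coordinates (`cluster_coordinates()`) are
plain means of the subject's aligned coordinates over cluster vertices.

## Intelligence composites and confounds

Ten task scores are z-scored across subjects. Crystallized intelligence is
the unweighted mean of two language tasks; fluid intelligence the unweighted
mean of five executive/reasoning tasks; the g factor is the loading-weighted
mean of all ten, with fixed factor-analysis loadings (`g_factor_weights()`,
weight sum 4.424). Building all three composites from z-scored tasks keeps
synthetic cohorts internally consistent even though operational test
batteries publish age-adjusted standard scores; because z-scoring absorbs
affine rescalings, the g factor is invariant to how any raw task column is
scaled.

Confounds (age, sex, handedness, education in years, mean framewise
displacement) are regressed out of both behavioral and gradient measures by
OLS with an intercept (`residualize_confounds()`); rank-deficient confound
matrices are an error that names the collinear columns. Hold-out subjects
are residualized in a separate fit so no statistic leaks from the
estimation sample.

## Cross-validated permutation inference

For each intelligence measure and each gradient axis, the clusters'
coordinates on that axis enter one linear model (nine models per run).
Bilateral homolog clusters whose coordinates correlate at rho >= 0.6 on
every axis are averaged into a single predictor first
(`bilateral_average()`); the gate value is configurable and every merge
decision is logged.

Subjects are split into k = 10 folds stratified by the outcome: ranked,
cut into k quantile bins, shuffled within bins and dealt round-robin
(`stratified_folds()`). Each fold's model is fit on the remaining folds and
judged *out of sample*: `R^2 = 1 - SS_res/SS_tot` on the held-out fold
(test-fold centering), `F = (R^2/p)/((1-R^2)/(n_test-p-1))` floored at 0
when R^2 is negative, with an infinite sentinel when the test residuals
vanish, and `t_j = beta_j / sqrt(sigma2_test [(X'X)_test^-1]_jj)`. The real
statistics are fold averages.

The null construction deserves its own paragraph. Candidate schemes were
compared on simulated null cohorts (n = 120, six predictors, ten folds, 200
permutations, repeated draws): pooling the k x n_perm single-fold permuted
statistics and comparing the fold-averaged real statistic against that pool
yields an empirical type-I rate of 0.00 at alpha = 0.05 — the fold average
concentrates while single-fold nulls have a heavy right tail. Averaging the
nulls across folds per permutation, with an independent permutation in every
fold, overshoots (0.083) because the real fold statistics share one y and
are positively dependent. Drawing **one permutation per null replicate and
sharing it across all folds**, then averaging the k fold statistics,
reproduces the real statistic's between-fold dependence and is calibrated
(0.050). `cv_permutation_model()` therefore permutes y once per replicate,
refits on each fold's permuted training rows, evaluates on the intact test
fold, and compares the fold-averaged real statistic against the n_perm
fold-averaged nulls with the add-one rule `p = (1 + #{|null| >= |real|}) /
(1 + n_perm)` (so p can never be exactly 0). Infinite sentinels are excluded
from null comparisons with a warning. The raw k x n_perm per-fold pool is
kept on the result object for inspection.

FDR control is Benjamini–Hochberg (`fdr_adjust()`, a validated wrapper over
the standard step-up): across the nine model F tests in a run, and across
the post hoc predictor t tests within any globally significant model.

Hold-out validation (`holdout_validation()`) averages the fold coefficients
into one cross-fold model and applies it unchanged to a disjoint lockbox
sample; F and t are computed as above with the hold-out as the test fold,
and nulls permute the hold-out response while keeping the averaged
coefficients fixed (default 10,000 permutations). A consequence of the
fixed-coefficient null is that all null t statistics are a common rescaling
of the real ones (only the residual variance changes under permutation), so
the post hoc t permutation p-values coincide across predictors and carry
the same information as the F p-value; they are reported for completeness.

`spearman_screen()` correlates a brain measure with individual task scores
(Spearman, asymptotic p, BH across tasks) for a finer-grained cognitive
readout.

## Graph topology of the variability clusters

`augment_parcellation()` adds the dispersion clusters to an atlas
parcellation, masking the overlap out of the donor parcels (parcels left
empty are dropped) and assigning all clusters to one shared `"cluster"`
community — the reading chosen for "a separate community of their own"; the
alternative (one community per cluster) only changes the participation
coefficient and can be emulated by editing the community vector. Parcel
series are unweighted vertex means; `correlation_graph()` zeroes
self-connections and keeps exactly the `floor(density * n(n-1)/2)` largest
strictly positive correlations (default density 0.10), breaking ties
lexicographically for determinism. Negative and zero correlations are never
retained, whatever the density.

`node_metrics()` computes six weighted metrics, with path lengths 1/weight
for everything shortest-path based: strength; global efficiency (mean
inverse distance to the other nodes, 0 for unreachable); local efficiency
(global efficiency of the neighbor-induced subgraph); the geometric-mean
triangle clustering coefficient on weights normalized by the maximum
retained weight; betweenness centrality; and participation
`1 - sum_m (k_im/k_i)^2` over the community structure. Weighted rather than
binarized metrics were chosen because strength is only meaningful weighted
and thresholded-in edges still differ in magnitude; the choice is a
convention, and all six metrics are verified exactly against brute-force
oracles (Floyd–Warshall distances, explicit triangle enumeration, direct
formula sums) on random graphs. Cluster profiles are z-scored within
subject across nodes and averaged across subjects
(`metric_zprofile()`), and `gradient_topology_association()` correlates a
cluster's gradient coordinate with its metrics across subjects (Spearman,
BH across the six metrics).

## The synthetic cohort generator

`simulate_cohort()` draws, for subject s and vertex v, true coordinates
`coord(s,v,k) = map_k(v) + offset(s,v,k)`: shared planted orthogonal maps
plus Gaussian offsets with per-vertex standard deviation from a dispersion
profile. Time series are `coord(s,v,) %*% sources(t) + noise`, where the
latent sources are moving-average-smoothed Gaussian signals,
QR-orthogonalized within each run — resting fMRI is dominated by slow
components, and orthogonality makes ground truth exactly low-rank when
noise is off. The sources are drawn once per run and shared by all
subjects, so between-subject structure lives entirely in the spatial
coordinates; a noise-free, offset-free cohort is exactly identical across
subjects.

Defaults, chosen once as a realistic desk-scale cohort and then left alone:

| parameter | default | meaning |
|---|---|---|
| `runs` | 4 x 150 | four acquisition runs (timepoints) |
| `gradient_amplitudes` | 1, 0.7, 0.5 | coordinate SD per planted map; distinct values make the gradient order identifiable |
| `dispersion_background` | 0.05 | offset SD outside the hotspot |
| `dispersion_hotspot` | 0.3 | offset SD inside the hotspot |
| `hotspot_area_mm2` | 400 | contiguous central patch, twice the 200 mm^2 cluster threshold |
| `behavior_effect` | -0.4 | standardized slope, fluid score on the hotspot's gradient-1 coordinate |
| `noise_sd` | 1 | i.i.d. measurement noise (planted signal variance is about 1.7) |

The behavioral table couples a fluid latent factor to the standardized
hotspot coordinate with the planted slope, adds small covariate effects
(framewise displacement uniform on [0.04, 0.24], age N(28.6, 3.6),
education, sex, and a continuous right-skewed handedness laterality score),
and generates ten task scores loading 0.6–0.85 on fluid, crystallized and
general latent factors. Task noise attenuates the observable correlation
between the fluid *composite* and the planted coordinate to about -0.38
when the planted slope is -0.4.

What the generator does **not** emulate: hemodynamics, spatial noise
correlations, motion artifacts, folded anatomy, and any genuine coupling
between gradient position and network topology in the time series. The
last point matters: parcel series are linear mixtures of only K latent
sources, so parcel graphs are near-degenerate similarity structures and
the planted cluster tends to sit peripherally in them. Passing pipeline
tests therefore validate the machinery, not the biology; the
gradient–topology association operation is validated separately by
planting a monotone coupling directly in the metric table.

## The end-to-end pipeline

`run_pipeline()` chains simulate → embed → disperse → score → model →
graph → report, with per-stage checkpoints (`resume = TRUE` reuses them, so
deleting one reruns only the downstream stages), plain TSV/JSON outputs, and
a manifest of parameter values and per-file MD5 digests. All stage seeds
derive from one master seed and a rerun is byte-identical. Defaults: a
50 x 50 vertex mesh at 2 mm spacing (9604 mm^2), 120 estimation and 50
hold-out subjects (roughly a 70/30 estimation/lockbox split),
four 75-timepoint runs, ten folds, 1000 permutations per fold and 10,000
hold-out permutations. The group embedding is estimated on the estimation
sample only; hold-out subjects are projected onto it.

Problem sizes in the shipped validation suite were chosen to exercise each
claim at the smallest scale where it is statistically meaningful: gradient
recovery on 20-subject, 500-vertex cohorts over 10 seeds; detection of a
400 mm^2 hotspot on a 2500-vertex mesh over 20 seeds; type-I calibration on
200 null cohorts (n = 120, six predictors, 200 permutations); power on 50
replicates at the planted slope (n = 300); and metric-oracle equivalence on
100 random graphs of up to 30 nodes.

## Numerical conventions and edge cases

* Quantile thresholds use linear interpolation (type 7); threshold
  comparisons are strict.
* Constant series: z-scoring maps them to zeros; correlation-graph rows
  become zero with a warning; Spearman screens flag them as `constant` and
  report `NA`.
* Perfect out-of-sample fits produce an infinite F sentinel, excluded from
  null comparisons; negative out-of-sample R^2 floors F at 0.
* Add-one permutation p-values are bounded below by `1/(1 + n_perm)` and
  can never be 0.
* Edge ties at the density cutoff and cluster-area ties are broken by
  lexicographic node/vertex order, for determinism.
* All random stages save and restore the global RNG state, and derive their
  streams from explicit seed arguments.

## Known limitations

The hold-out post hoc t p-values are degenerate with the F p-value by
construction (fixed-coefficient null). The dispersion statistic is an
unnormalized sum of squares, so comparisons across cohorts of different
size need `normalize = TRUE`. Cluster anatomy (which parcel, which
hemisphere) is metadata the caller supplies; the package does not label
anatomy. And all validation is synthetic: none of the shipped checks speak
to preprocessing choices (motion correction, smoothing, registration) that
dominate real resting-state analyses upstream of this package's scope.
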