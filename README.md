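# graddisp

Functional-connectivity **grad**ient **disp**ersion: an R package for
asking where cortical functional organization differs most between people,
and whether those differences track cognitive ability.

Resting-state BOLD time series from many subjects are embedded into a
shared low-dimensional *gradient space* by a two-step generalized canonical
correlation analysis (GCCA): per-subject principal components, then a
singular value decomposition of the concatenated, unit-normalized component
matrices. Every cortical vertex gets a coordinate on each of K = 3
gradients. Interindividual variability at vertex *v* is the dispersion of
the subjects around the per-vertex group centroid *c(v)*,

    D(v) = sum_s || x_s(v) - c(v) ||^2 ,

decomposed additively per gradient axis. Thresholding the dispersion map at
the 95th percentile and keeping connected mesh components of at least
200 mm^2 yields clusters of maximal variability. The clusters' per-subject
gradient coordinates then enter linear models of crystallized, fluid and
g-factor intelligence composites (confounds regressed out), tested with
stratified 10-fold cross-validation, permutation nulls, FDR control, and
lockbox validation on held-out subjects. Finally, the clusters are added to
a parcellation as their own community and profiled with six weighted graph
metrics (strength, global/local efficiency, clustering, betweenness,
participation) on density-thresholded positive-correlation networks.

A synthetic-cohort generator plants known gradient maps, a contiguous
dispersion hotspot, and a signed brain–behavior coupling, so the entire
stack is testable against ground truth without access-restricted data.

## Worked example

```r
library(graddisp)

mesh <- build_mesh(50, 50, 2)                    # 2500-vertex toy cortex, 9604 mm^2
cfg  <- cohort_config(n_subjects = 40, seed = 1) # 4 x 150 timepoints, planted
coh  <- simulate_cohort(mesh, cfg)               #   hotspot + beta = -0.4 coupling

emb  <- embed_cohort(coh$timeseries, k = 3)      # two-step GCCA embedding
disp <- vertex_dispersion(emb$embeddings)        # per-vertex dispersion map
cl   <- extract_clusters(disp, mesh, percentile = 95, min_area_mm2 = 200)
cl
#> fc_clusters: 1 cluster(s) above the 0.00143 threshold (95th pct, min area 200 mm^2)
#>   id n_vertices area_mm2
#> 1  1        119      476

coords <- cluster_coordinates(emb$embeddings, cl)
fi   <- composite_score(coh$behavior, "FI")      # fluid composite (5 tasks)
covs <- encode_covariates(coh$behavior)          # age, sex, handedness, edu, FD
y <- residualize_confounds(fi, covs)
x <- residualize_confounds(coords[, "c1_g1", drop = FALSE], covs)

cv <- cv_permutation_model(y, x, stratified_folds(y, 10, seed = 2),
                           n_perm = 1000, seed = 3)
cv
#> fc_cv_result: 10 folds, 1000 permutations/fold
#>   mean out-of-sample F = 1.416 (p = 0.002997)
#>   predictor  mean_t        p        q
#> 1     c1_g1 -0.8958 0.000999 0.000999
```

The generator planted a 400 mm^2 high-dispersion patch and a -0.4
standardized slope between the patch's first-gradient coordinate and the
fluid score. The dispersion map recovers the patch as a single
476 mm^2 cluster (vertex-level detection AUC 1.0; the recovered group
gradients correlate with the planted maps at |rho| = 0.98–1.00), and the
cross-validated permutation test recovers the coupling: a significant model
(p = 0.003) driven by a negative association between the cluster's
principal-gradient coordinate and fluid intelligence (mean out-of-sample
t = -0.90, q = 0.001).

`run_pipeline(pipeline_config(out_dir = "out", seed = 7))` chains the whole
analysis (simulate → embed → disperse → score → model → graph → report) at a
larger default scale (120 estimation + 50 lockbox subjects), writing
TSV/JSON stage outputs and a digest manifest; reruns with the same seed are
byte-identical.

## Package layout

| file | contents |
|---|---|
| `R/mesh.R` | triangulated mesh, vertex areas, patch growth |
| `R/cohort.R` | synthetic cohort generator and ground truth |
| `R/embedding.R` | normalization, two-step GCCA, projections, variance profile |
| `R/dispersion.R` | dispersion maps, cluster extraction, cluster coordinates |
| `R/behavior.R` | intelligence composites, confound residualization |
| `R/inference.R` | folds, CV permutation tests, FDR, holdout, Spearman screen |
| `R/topology.R` | parcellation augmentation, graphs, node metrics, z-profiles |
| `R/pipeline.R` | end-to-end orchestration with checkpoints and manifest |

The methods vignette (`vignettes/gradient-dispersion-methods.Rmd`) explains
the model, every tunable parameter, the null-construction choices, what the
synthetic generator does and does not emulate, and known limitations.
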