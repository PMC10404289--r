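# renograph

Annotation-free prediction of kidney function from trichrome-stained biopsy
core images.

## What it does

Pathologists grade chronic kidney disease on biopsy cores, but pixel-level
annotation of whole-slide images is slow and inconsistent. `renograph`
implements a clustering-based spatial analysis pipeline that needs no
expert labels:

1. **Preprocess** — Reinhard stain normalization against cohort-global CIE
   Lab statistics, heuristic tissue masking, tiling into fixed-size patches.
2. **Cluster** — patch texture features (pluggable extractor), k-means with
   silhouette-selected K, clusters ordered by classical MDS; per-case
   frequency histograms `f1..fK` and quartic trend coefficients from
   `f(x) = c1·x⁴ + c2·x³ + c3·x² + c4·x + c5` fitted over the ordered bins.
3. **Spatial analysis** — each core's clustered patch lattice becomes a
   graph (nodes = patches, edges = 4-neighbour adjacency, node features =
   cluster MDS coordinates), classified by a deep graph convolutional
   network (four graph conv layers, SortPooling, two 1-D convolutions, max
   pooling, dense sigmoid head) under threefold patient-stratified
   cross-validation.
4. **Patient aggregation** — each core's predicted class `P ∈ {−1,+1}` is
   weighted by its normalized tissue area `A` and summed:
   `patient score = Σᵢ Aᵢ·Pᵢ` (the *aw-score*), classified +1 when
   nonnegative.
5. **Classification** — a random forest over the spatial, frequency, trend
   and clinical feature groups predicts dichotomized outcomes (eGFR ≥ 60 at
   biopsy; eGFR slope ≥ 0 at one year, with
   `slope = (eGFR_year1 − eGFR_biopsy) / (age_days_year1 −
   age_days_biopsy)`), with Gini-importance ranking, top-7 selection, OOB
   error and cross-validated ROC/AUC (accuracy
   `(TP+TN)/(TP+FN+TN+FP)`, DeLong 95% CI).

A fully seeded synthetic-cohort generator (textured blob cores, contiguous
lesion regions, logistic outcome linked to lesion burden *and* lesion
contiguity, label-consistent clinical tables) makes every stage testable
without clinical data.

## Worked example

```r
library(renograph)

spec <- cohort_spec(n_patients = 20, cores_per_patient = c(2, 3),
                    core_shape = c(256, 256), patch_size = 32,
                    k_true = 6, lesion_pattern_ids = 1:2, seed = 11)
cohort <- generate_cohort(spec)
config <- pipeline_config(out_dir = tempdir(), k_range = 5:8,
                          rf_ntree = 300, seed = 4)
res <- analyze_cohort(cohort, config)

res$scores[1:3, ]
#> # A tibble: 3 × 4
#>   patient_id n_cores  total class
#>   <chr>        <int>  <dbl> <int>
#> 1 P001             2 -1.37     -1
#> 2 P002             3  0.439     1
#> 3 P003             3 -2.32     -1

res$cv_top$report
#> <eval_report> acc 0.850 | sens 0.750 | spec 0.917 | AUC 0.896 (95% CI 0.757-1.000)
#>   confusion: TP=6 FN=2 TN=11 FP=1
```

`res$scores$total` is each patient's summed area-weighted score: P001's
two cores were both predicted −1 (declining function) with normalized
areas summing to 1.37, while P002's three cores netted slightly positive.
The evaluation report is the patient-stratified cross-validated performance
of the random forest on the Gini top-7 features; on this 20-patient
synthetic cohort it recovers the planted outcome with AUC ≈ 0.90.
`plot_case_histogram()`,
`plot_cluster_map()`, `plot_roc()` and `plot_importance()` visualize the
intermediate artifacts.

The staged, on-disk equivalent (PNG cores in, CSV/JSON artifacts out) is
driven by `run_pipeline()` / `run_stage()` or from a shell via
`inst/cli/renograph.R <stage|all> --config config.yaml`.

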