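# frailmotion

Classify the Fried frailty phenotype (healthy vs. pre-frail) — or gender —
from 25-joint depth-camera (Kinect V2) skeleton time series recorded while
a subject performs four functional exercises: a 30-s arm curl, a 30-s
chair sit-to-stand, a 4-m walk and a 2-min step test.

The package is aimed at movement-analysis and digital-biomarker
researchers who have (or want to simulate) per-subject pose streams plus
the five binary Fried components, and want a tested, reproducible pipeline
from raw joints to holdout classification accuracy.

## The method

The Fried score sums five binary components — weight loss, weakness, poor
endurance, slowness, low physical activity:

```
FS = WL + WK + PE + SL + LA,   0 -> healthy, 1-2 -> pre-frail, 3-5 -> frail
```

Each recording is processed as: Gaussian smoothing of every joint
trajectory → movement-cycle isolation on an exercise-specific inter-joint
distance (significant extrema found by automatic multiscale peak
detection, AMPD) → four per-frame geometric feature families over the
cycle:

* **SA** — spherical angles (φ, θ) of 8 limb segments (16 tracks),
* **ED** — pairwise joint distances (210 tracks for the 21 active joints),
* **JCD** — cosine dissimilarity of joint pairs about the spine (190),
* **JTA** — triangular areas of the same triples (190),

then aggregation of each track to `nb` scalars (bin means or histogram
probabilities), giving `nb * 606` features per exercise, standard scaling
and random-forest Gini-importance selection, and finally five classifiers
(KNN, SVC, MLP, bagged trees, soft voting) tuned by randomized-search
k-fold cross-validation and scored on held-out subjects.

Because clinical cohorts of this kind are not distributable, the package
includes a synthetic-motion generator with analytic ground truth whose
class profiles encode the kinematic reading of the phenotype (pre-frail =
slower, smaller, noisier movement). Every stage is tested against it.

## Worked example

```r
library(frailmotion)

# a synthetic cohort: 25 healthy + 25 pre-frail, sit-to-stand only
coh    <- generate_cohort(cohort_spec(n_per_class = 25,
                                      exercises = "sit_to_stand", seed = 7))
tracks <- extract_track_sets(coh$recordings)
report <- run_experiment(tracks, coh$subjects,
                         classifiers = c("knn", "svc"),
                         ns = 100, n_iter = 5, repeats = 5, seed = 1)
glance(report)
#> # A tibble: 2 × 8
#>   classifier exercise_set family_set    n_subjects median_accuracy    q1    q3
#>   <chr>      <chr>        <chr>              <int>           <dbl> <dbl> <dbl>
#> 1 knn        sit_to_stand SA+ED+JCD+JTA         50             100   100   100
#> 2 svc        sit_to_stand SA+ED+JCD+JTA         50             100   100   100
```

Both classifiers separate this clearly contrasted cohort perfectly on
held-out subjects: the generator's default pre-frail profile (1.5× longer
cycle periods, 0.7× amplitudes, 1.5× jitter) is an easy target at n = 50.
Each `median_accuracy` is the median percent of correct holdout
predictions over 5 independent balance/subsample/split repeats.

The lower-level stages are ordinary functions:

```r
g      <- generate_recording("sit_to_stand", seed = 2)
metric <- cycle_metric(g$recording)       # knee–spine distance, smoothed
seg    <- isolate_cycles(metric)          # AMPD + sit-to-stand rule
seg
#> <cycle_segment> [24, 115) spanning 1 cycle(s), 91 frames
autoplot(metric, seg)                     # QC plot: metric + extrema + borders

v <- build_feature_vector(segment_tracks(g$recording), nb = 20)
length(v)                                 # 20 * (16+210+190+190)
#> [1] 12120
round(v[1:3], 3)
#> SA:HumerusLeft:phi:b01 SA:HumerusLeft:phi:b02 SA:HumerusLeft:phi:b03
#>                 -0.615                 -3.084                 -0.628
```

The one detected sit-to-stand cycle covers frames 24–114 (about 3 s at
30 Hz); the feature vector's first entries are the bin means of the left
humerus azimuth over that cycle.

On-disk workflows (CSV/JSON recordings + a cohort manifest) go through
`read_recording()` / `read_cohort()`, and the whole chain is scriptable
via `cmd_simulate()`, `cmd_extract()` and `cmd_train_eval()` or the thin
CLI in `inst/cli/frailmotion`.

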