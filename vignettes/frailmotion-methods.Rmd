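---
title: "Classifying the frailty phenotype from skeleton motion: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying the frailty phenotype from skeleton motion: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(frailmotion)
```

## The problem

The Fried frailty phenotype scores five binary clinical components —
unintentional weight loss (WL), weakness (WK), poor endurance (PE),
slowness (SL) and low physical activity (LA) — and classes a subject as
healthy (score 0), pre-frail (1–2) or frail (3–5):

$$FS = WL + WK + PE + SL + LA.$$

Measuring these components takes trained staff and equipment. A depth
camera (Kinect V2) watching a subject perform four simple functional
exercises — a 30-s arm curl, a 30-s chair sit-to-stand, a 4-m walk and a
2-min step test — produces a 25-joint skeleton time series per exercise
at ~30 Hz. `frailmotion` implements a pipeline that turns these pose
streams into a fixed-length feature vector per subject and trains
classifiers to predict the frailty class (or, as a validation target with
known baselines, gender).

The pipeline stages, in order: label balancing → Gaussian smoothing →
movement-cycle isolation → geometric feature extraction → aggregation to
fixed length → standard scaling → Gini-importance feature selection →
randomized-search k-fold tuning of five classifiers → subject-disjoint
holdout evaluation.

## Cycle isolation

Raw joint trajectories carry sensor jitter that creates many spurious
local extrema, so each coordinate series is first smoothed with a
normalized Gaussian moving average. The default kernel covers 0.25 s of
frames (forced odd) with $\sigma = \mathrm{window}/5$: wide enough to
suppress frame-to-frame jitter, narrow relative to the ≥1-s movement
cycles so the global extrema survive. At the series edges the kernel is
renormalized over its in-range support, which preserves constants
everywhere.

Movement cycles are delimited on a per-exercise scalar *cycle metric*,
the 3D distance between a joint pair chosen so that its oscillation
tracks the movement: head–dominant wrist (arm curl), left knee–spine
shoulder (sit-to-stand), and left–right ankle (gait and step, where one
movement cycle spans two metric oscillations because the ankles separate
twice per cycle).

Significant extrema of the metric are found with automatic
multiscale-based peak detection (AMPD; Scholkmann et al. 2012): after
linear detrending, a point scores at window scale $k$ when it exceeds
both neighbours at distance $k$; the scale $\lambda$ with the most
scale-$k$ maxima is selected, and the reported extrema are the points
that win at *every* scale up to $\lambda$. This multiscale agreement is
what makes the detector insensitive to local jitter. Three implementation
choices are worth recording:

* the scalogram is deterministic (0/1 entries rather than the original's
  random weights for non-maxima — the selected scale is the same in
  expectation, and determinism is part of the package contract);
* comparisons at the series edges are truncated to the in-range side, so
  an extremum within $\lambda$ frames of an edge is still found when it
  dominates its one-sided window — but extrema within $\lambda/4$ frames
  of an edge are suppressed, because a heavily one-sided window no longer
  supports a credible extremum;
* comparisons use a relative tolerance ($10^{-8}$ of the detrended
  range), so constant or purely linear series yield no extrema.

A cycle is then cut out by the per-exercise rule: arm curl runs from a
maximum through a minimum to the next maximum; sit-to-stand from a
minimum through a maximum to the next minimum; gait and step from a
maximum to its second subsequent maximum. Before the rule is applied,
extrema whose prominence (distance to the nearest opposite extremum) is
below `min_prominence` (default 0.2) of the metric range are discarded as
jitter; 0.2 reliably rejects sensor-scale ripple on synthetic traces
while keeping movement-scale extrema. After discarding, runs of equal
polarity are collapsed to their most extreme member (earliest frame on
ties). The two boundary extrema are finally refined by a least-squares
parabola fitted over a quarter of the inter-extremum spacing: the vertex
of the fit averages the noise and localises a flat extremum considerably
better than the raw argmax, whose position wanders under jitter.
Segments are half-open `[start, end)` in 1-based frame indices, and
`n_cycles` (default 1, the identified "complete cycle") controls how many
consecutive cycles the segment spans. For gait's three repetitions, each
repetition is segmented independently and the first successful detection
is used.

## Feature families

Over the segment frames, four families of per-frame geometric quantities
are extracted (all on the smoothed sequence):

* **SA** — spherical angles $(\varphi, \theta)$ of eight limb segments
  (left/right humerus = shoulder→elbow, radius = elbow→wrist, femur =
  hip→knee, tibia = knee→ankle), with
  $\varphi = \mathrm{atan2}(\Delta z, \Delta x)$ and
  $\theta = \arccos(\Delta y / l_r)$; 16 tracks. At a vertical segment
  the azimuth follows the $\mathrm{atan2}(0,0)=0$ convention.
* **ED** — Euclidean distance of every pair of the 21 active joints
  (the 25 minus hand tips and thumbs, which move rigidly with the
  hands); $21 \cdot 20 / 2 = 210$ tracks.
* **JCD** — cosine dissimilarity
  $\delta_c = 1 - \frac{R_1 \cdot R_2}{\lVert R_1\rVert \lVert R_2\rVert}$
  of every joint pair relative to the spine; 190 tracks.
* **JTA** — triangular area
  $A_t = \tfrac{1}{2}\lVert R_1 \times R_2 \rVert$ of the same triples;
  190 tracks.

The "spine" reference for JCD/JTA is mapped to `SpineMid`, the more
literal reading of a mid-torso reference point; `SpineBase` is the
plausible alternative and is supported through the `reference` argument.
The reference joint is excluded from the JCD/JTA pair enumeration, hence
the $(N_a-1)(N_a-2)/2$ counts.

Each track is aggregated to `nb` scalars, either as bin means over `nb`
near-equal contiguous intervals (remainder frames go to the leading bins)
or as an `nb`-bin histogram of probabilities over a predefined range. The
default assignment — bin means for SA/ED, histograms for JCD/JTA — keeps
the waveform of the angle/distance channels and summarises the value
distribution of the dissimilarity/area channels; both aggregators are
available for every family. Histogram ranges are "predefined" by fitting
the per-track min/max on the training subjects and freezing them, so
held-out subjects cannot influence the binning. With all four families,
the concatenated vector has $N_f = nb\,(16 + 210 + 190 + 190) = 606\,nb$
entries per exercise (12,120 at the default `nb = 20`); multi-exercise
runs concatenate per-exercise vectors under an `exercise|` name prefix.
`nb = 20` keeps single-exercise vectors well below typical track lengths
while leaving the width identity easy to audit.

Features are standard-scaled (zero mean, unit variance, estimated on the
training rows only, with the usual $n-1$ denominator; zero-variance
features map to 0), ranked by the normalized mean Gini-impurity decrease
of a random forest grown on the training rows (ties broken by feature
name), and the top `ns` are kept. `ns = 150` is the default: far fewer
starves the classifiers, far more re-introduces the dimensionality curse
at cohort-scale sample sizes.

## Classifiers and tuning

Five classifier kinds are tuned by randomized search over documented
spaces with stratified k-fold cross-validation (`k = 5`, `n_iter = 50` by
default; ties in CV accuracy resolve by draw order, and the whole
procedure is bit-reproducible under a seed):

| kind | model | search space |
|------|-------|--------------|
| knn  | k-nearest neighbours | k 1–30; uniform or distance weights |
| svc  | support vector classifier (e1071) | rbf/linear; cost $10^{-2}$–$10^3$; width $10^{-4}$–$10^1$ |
| mlp  | single-hidden-layer perceptron (nnet) | 4–16 units; L2 decay $10^{-5}$–$10^{-1}$ |
| bag  | bagged decision trees (random forest with mtry = p) | 10–200 trees; bootstrap fraction 0.5–1 |
| vote | soft voting | mean predicted probability of the four tuned bases |

The KNN predictor is implemented in the package because soft voting needs
class probabilities and the search space includes distance weighting,
neither of which the standard `class::knn` interface exposes. The MLP is
a single hidden layer of 4–16 units: with at most ~100 training subjects
and 150 selected features, wider or deeper nets add variance without
capacity the problem can use, and the dense quasi-Newton optimizer behind
`nnet` scales quadratically in the weight count, making them
disproportionately expensive to search.

The experiment runner repeats, per design cell: balance labels → draw
`n_subjects` → stratified 75/25 train/holdout split → fit histogram
ranges, scaling, ranking and tuning on the training subjects only →
score the holdout. Balancing precedes the split, mirroring the study
design it reproduces; users auditing leakage should note that balancing
itself sees all labels, but no quantity fitted downstream of the split
ever touches a holdout row. Note that feature selection happens before
the tuning CV, so CV accuracies are optimistically biased in small
cohorts; only the holdout accuracies are unbiased, and all reported
results use them.

## The synthetic cohort generator

The study-grade data such a pipeline is built for (clinical recordings of
hundreds of elderly subjects) is not distributable, so the package ships
a generator that emulates its structure with analytic ground truth.
Recordings are built from a neutral standing/sitting template with
sinusoidal joint trajectories keyed to each exercise's cycle metric: the
arm curl rotates the dominant forearm (modulating head–wrist distance),
sit-to-stand lowers and raises the trunk, gait and step move the ankles
in anti-phase. White Gaussian jitter (default 8 mm per axis, the scale of
depth-camera tracking error), optional linear posture drift, and optional
coordinate quantization (mimicking the stepwise raw traces of the sensor)
are added on top. Arm-curl and sit-to-stand recordings begin a quarter
period into the cycle — as when the sensor starts while the movement is
already underway — so the first rule anchor lies in the interior of the
series. Protocol defaults are 30-s arm curl and sit-to-stand, the time to
walk 4 m (three repetitions), and a 2-min step test, all at 30 Hz.

Cohorts draw per-subject profiles from class-conditional distributions
that encode the kinematic reading of the phenotype: pre-frail subjects
are slower (cycle periods 1.5× healthy), move less (amplitudes 0.7×) and
track noisier (jitter 1.5×); subject-level log-normal multipliers
(sd 0.08) are shared across exercises so a slow subject is slow
everywhere; gender leaves a weak trace (males 1.1× amplitude); Fried
components are sampled consistently with the class (slowness and weakness
first, matching the components that have a kinematic expression). Setting
all three ratios to 1 yields a null cohort with identical class profiles.

What the generator does *not* emulate: biomechanical couplings (joints
move along prescribed sinusoids, not a skeleton model), fatigue and
within-trial tempo drift, tracking dropouts and occlusions, and the
heterogeneity of real populations. Consequences worth keeping in mind:
passing tests show the pipeline recovers class structure that is
expressed as period/amplitude/noise differences, not that real frailty is
so expressed; and on a fixed-difficulty i.i.d. cohort, holdout accuracy
cannot systematically *decrease* as subjects are added — the decline
reported on real cohorts reflects population heterogeneity the generator
does not model — so the corresponding trend check asserts
non-increase within a noise allowance rather than a strict decline. Note
also that a finite null cohort is only null in the population sense:
chance composition differences between its two class samples are genuine
within-cohort signal, which is why classifiers hover a few points above
50% rather than exactly at chance.

## Numerical choices and degenerate inputs

* Frames are 1-based (R convention); all segments half-open.
* Joint dropouts of ≤3 frames are linearly interpolated at load time;
  longer or edge-touching gaps drop the affected frames, with counts in
  the load report. Files declaring millimetres are converted on read.
* Coincident points (zero-length segment or reference ray) raise
  degenerate-geometry errors rather than returning NaN.
* `acos` arguments are clamped to $[-1, 1]$; JCD to $[0, 2]$.
* A histogram track whose fitted range is degenerate (constant track)
  falls back to a half-unit pad on both sides.
* Recordings failing cycle detection are skipped and logged, never
  crash the cohort pipeline; an exercise with three repetitions falls
  back to later repetitions.

## Testing scales

The test suite exercises the full pipeline at sizes chosen to keep a
complete run in minutes on one core while preserving the qualitative
regimes: formula oracles on $10^4$ random triples; segmentation recovery
across all four exercises with 12 seeds each; selection recovery with 5
planted among 500 noise features at $n = 200$ over 20 seeds; and
end-to-end experiments on synthetic cohorts of 100–120 subjects
(sit-to-stand) and 60 subjects (all four exercises, step test shortened
to 40 s), with 5–10 repeats per cell and randomized search trimmed to
2–6 draws. The headline checks — SVC/MLP median holdout accuracy above
90% on a separable cohort, all five classifiers within 50 ± 10% on a
null cohort — are computed on those cohorts by
`tests/testthat/test-acceptance.R`.

## Known limitations

* The frail class is supported by the label machinery but excluded from
  experiments by default; community cohorts rarely contain enough frail
  subjects to train on.
* The file-based workflow (`cmd_extract` → CSV → `cmd_train_eval`)
  freezes histogram ranges over the extracted set, a small departure from
  the strictly train-fitted ranges used by the in-memory experiment path;
  the provenance block records it.
* Multi-layer (≥2 hidden layers) perceptrons are out of reach of the
  underlying `nnet` engine.
* AMPD's scale selection assumes a dominant periodicity; strongly
  aperiodic metrics will segment poorly, which the cycle-detection error
  reports per exercise.
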