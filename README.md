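# swarmcam

Does 2D imaging lose the behaviour? Mosquito mating swarms are tracked to
understand male/female/couple flight behaviour, and the tracking hardware
ranges from a calibrated stereo pair (full 3D), through a telecentric
single-camera rig (two orthogonal components, depth-independent
magnification), down to an ordinary single camera whose two pixel
coordinates mix all three world components through perspective and lens
distortion. swarmcam is an R package for entomologists and imaging
scientists weighing those options: it simulates labelled 3D swarm
trajectories, projects them through explicit camera models, extracts
per-segment flight features, classifies male vs non-male tracks with a
one-class SVM under segment voting, and quantifies how the imaging geometry
changes the features, the classifier, and its feature attributions.

## The models at the core

* **Pinhole camera** (single-camera simulation): `s p = A [R | t] P_w`, with
  intrinsic matrix `A = [[fx, 0, cx], [0, fy, cy], [0, 0, 1]]` and radial +
  tangential lens distortion `(k1, k2, p1, p2)` applied in normalized camera
  coordinates. Moving the camera from `d_ref` to `d` rescales
  `f(d) = f_ref * d / d_ref` (thin-lens refinement `1/f = 1/u + 1/v`,
  `M = v/u` available) so the swarm keeps its image extent.
* **Telecentric camera**: orthographic projection — the depth axis is
  dropped and `(y, z)` are reported in metres.
* **Flight features** per fixed-duration track segment, 136 in 2D: speed,
  velocity, acceleration, jerk, angle of flight, signed turn rate, curvature
  `k_i = (x' y'' - y' x'') / (x'^2 + y'^2)^{3/2}`, straightness
  `S = (path length) / (chord)`, step lengths, and shape descriptors, each
  series summarized by mean/std/min/max/Q1/median/Q3/IQR.
* **Classifier**: a nu one-class SVM (RBF kernel, nu = 0.2) trained on male
  segments only, with Mann-Whitney feature selection, correlation pruning,
  robust standardization, majority voting over a track's segments, and
  trial-held-out cross-validation (two male trials held out per fold).

## Worked example

```r
library(swarmcam)

# a benchmark shaped like the motivating field dataset: 12 male + 10 couple
# modelling trials (plus 1 female, 1 focal-male), 3 male + 2 couple tuning
# trials, 25 fps
bench <- make_benchmark(seed = 1)
modelling <- filter_short_tracks(bench$modelling)   # drop tracks < 3 s
#> filter_short_tracks: couple 740 -> 104; female 6 -> 3;
#>                      focal_male 6 -> 6; male 192 -> 156

# telecentric (2D, metres) view and its per-segment feature table
tele <- project_bundle(modelling, "telecentric")
feats <- segment_features(tele, window = 1, overlap = 0.5)
dim(feats)
#> [1] 2896  143     # 2896 segments, 7 provenance + 136 feature columns

# one-class segment-voting classifier, trial-held-out folds
tuning <- filter_short_tracks(bench$tuning, quiet = TRUE)
ref <- segment_features(project_bundle(tuning, "telecentric"), 1, 0.5)
ref <- ref[ref$class_name == "couple", ]
cv <- crossvalidate(tele, classifier_config(window = 1, overlap = 0.5),
                    reference_nonmale = ref, max_folds = 10, seed = 1)
cv
#> Trial-held-out cross-validation: 10 folds, window 1 s, overlap 0.5
#> Track-level classification metrics (mean [95% interval across folds])
#>   accuracy_male          0.910 [0.880-0.949]
#>   accuracy_couple        1.000 [1.000-1.000]
#>   balanced_accuracy      0.928 [0.913-0.948]
#>   roc_auc                0.977 [0.973-0.984]
#>   ...

# how fast does a single camera converge to the telecentric geometry?
sw <- distance_sweep(modelling, c(2, 5, 9, 15),
                     classifier_config(window = 1, overlap = 0.5))
sw
#>   distance_m correlation_to_telecentric
#> 1          2                  0.933
#> 2          5                  0.973
#> 3          9                  0.981
#> 4         15                  0.986
#> 5        Inf                  1.000     # telecentric baseline
```

Read: at a typical 2 m working distance the single camera's feature table
correlates 0.93 with the telecentric one; by 9–15 m (with a matched longer
focal length) the two geometries are nearly interchangeable. Balanced
accuracy (mean of male and non-male recall) of 0.93 on this synthetic
benchmark reflects the generator's clean class contrast, not field-data
performance; the per-class rows show couples are fully rejected while
focal males — generated as near-male — are predicted male.

`plot_tracks()`, `plot_sweep()`, `plot_embedding()`,
`plot_attribution_summary()` and `plot_attribution_scatter()` give ggplot
views of each result; `tidy()`/`glance()` methods summarise fitted objects;
`explain()` produces Shapley-value attributions of the one-class decision
function. See the methods vignette
(`vignettes/imaging-geometry-and-classification.Rmd`) for the model
assumptions, parameter choices, and known limitations.

## Acceptance script

`scripts/acceptance.R` recomputes the package's geometry headline from
scratch against the installed package: it builds the published camera model
(fx = 1993.208, fy = 1986.203, cx = 705.234, cy = 515.751, k1 = -0.088547,
k2 = 0.292341), aims it at a 1 m-per-axis cuboid from 2 m, and decomposes
the image displacement over a uniform 9x9x9 grid into perspective and
lens-distortion shares, reporting the perspective share as a percentage.

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
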