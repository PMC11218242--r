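Package: swarmcam
Title: Imaging-Geometry Effects on Machine-Learning Analysis of Mosquito
    Swarm Trajectories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates three-dimensional mosquito mating-swarm trajectories,
    projects them through explicit camera models (telecentric and
    single-camera pinhole with radial/tangential lens distortion, including
    distance-dependent focal-length scaling), extracts per-segment flight
    features (speed, acceleration, angle of flight, curvature, straightness
    and shape descriptors), and classifies male versus non-male tracks with a
    one-class support vector machine under segment voting and trial-held-out
    cross-validation. Evaluation tools quantify how imaging geometry changes
    feature values (mean absolute Pearson correlation between paired feature
    tables, distance sweeps, low-dimensional embeddings) and model behaviour
    (Shapley-value feature attributions).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    grDevices,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
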