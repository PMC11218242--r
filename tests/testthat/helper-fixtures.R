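# Shared fixtures, all generated in code. Helpers are sourced once per run,
# so the heavier fixtures are built lazily and cached in this environment.

.fixtures <- new.env(parent = emptyenv())

# wrap a numeric position matrix as a 3D (n x 3) or 2D (n x 2) track tibble
as_track_tbl <- function(m, fps = 25, trial_id = "t1", track_id = "a",
                         class_name = "male", unit = "m") {
  m <- as.matrix(m)
  n <- nrow(m)
  base <- tibble::tibble(
    trial_id = trial_id, track_id = track_id, class_name = class_name,
    frame = seq_len(n) - 1L, t_s = (seq_len(n) - 1L) / fps
  )
  if (ncol(m) == 3) {
    dplyr::mutate(base, x_m = m[, 1], y_m = m[, 2], z_m = m[, 3])
  } else {
    dplyr::mutate(base, u = m[, 1], v = m[, 2], unit = unit)
  }
}

# planar circle in the YZ plane (constant depth), radius r
circle_track_yz <- function(n = 251, r = 0.5, fps = 25, depth = 0,
                            turns = 1) {
  th <- seq(0, 2 * pi * turns, length.out = n)
  as_track_tbl(cbind(depth, r * cos(th), r * sin(th)), fps = fps)
}

# random rotation matrix via axis-angle (Rodrigues), deterministic given seed
random_rotation <- function(seed) {
  set.seed(seed)
  axis <- rnorm(3)
  axis <- axis / sqrt(sum(axis^2))
  th <- runif(1, 0, pi)
  kx <- matrix(c(0, -axis[3], axis[2],
                 axis[3], 0, -axis[1],
                 -axis[2], axis[1], 0), 3, 3, byrow = TRUE)
  diag(3) + sin(th) * kx + (1 - cos(th)) * (kx %*% kx)
}

# small benchmark for unit tests (reduced trial/track counts for speed);
# the acceptance suite builds the full default benchmark itself
small_benchmark <- function() {
  if (is.null(.fixtures$small_bench)) {
    configs <- list(
      male = swarm_sim_config("male", n_tracks = 8,
                              duration_range = c(3.5, 8)),
      couple = swarm_sim_config("couple", n_tracks = 12,
                                duration_range = c(2, 5)),
      female = swarm_sim_config("female", n_tracks = 4),
      focal_male = swarm_sim_config("focal_male", n_tracks = 4)
    )
    .fixtures$small_bench <- make_benchmark(
      n_male_trials = 7, n_couple_trials = 5,
      n_female_trials = 1, n_focal_trials = 1,
      seed = 99, configs = configs
    )
  }
  .fixtures$small_bench
}

# telecentric segment features of the small benchmark, cached
small_bench_features <- function(window = 1, overlap = 0.5) {
  key <- paste0("feat_", window, "_", overlap)
  if (is.null(.fixtures[[key]])) {
    b <- small_benchmark()
    filt <- filter_short_tracks(b$modelling, quiet = TRUE)
    .fixtures[[key]] <- segment_features(project_bundle(filt, "telecentric"),
                                         window, overlap)
  }
  .fixtures[[key]]
}

small_bench_reference_couples <- function(window = 1, overlap = 0.5) {
  key <- paste0("ref_", window, "_", overlap)
  if (is.null(.fixtures[[key]])) {
    b <- small_benchmark()
    filt <- filter_short_tracks(b$tuning, quiet = TRUE)
    segs <- segment_features(project_bundle(filt, "telecentric"),
                             window, overlap)
    .fixtures[[key]] <- segs[segs$class_name == "couple", ]
  }
  .fixtures[[key]]
}

python_available <- function() {
  nzchar(Sys.which("python"))
}

oracle_path <- function(script) {
  p <- system.file("oracle", script, package = "swarmcam")
  if (!nzchar(p)) stop("oracle script not found: ", script)
  p
}

run_python_oracle <- function(script, payload) {
  infile <- tempfile(fileext = ".json")
  outfile <- tempfile(fileext = ".json")
  jsonlite::write_json(payload, infile, auto_unbox = TRUE, digits = NA)
  status <- system2("python", oracle_path(script),
                    stdin = infile, stdout = outfile, stderr = FALSE)
  if (status != 0) stop("python oracle failed")
  jsonlite::read_json(outfile, simplifyVector = TRUE)
}
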