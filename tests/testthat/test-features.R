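test_that("the 2D feature registry has exactly 136 uniquely named entries", {
  reg <- feature_registry(2)
  expect_equal(nrow(reg), 136)
  expect_equal(anyDuplicated(reg$name), 0)
  # 16 series x 8 statistics + 8 scalars
  expect_equal(sum(reg$kind == "series"), 128)
  expect_equal(sum(reg$kind == "scalar"), 8)
})

test_that("the 3D registry adds per-plane entries for plane-dependent features", {
  reg <- feature_registry(3)
  expect_equal(anyDuplicated(reg$name), 0)
  planes <- reg[!is.na(reg$plane), ]
  expect_setequal(unique(planes$plane), c("xy", "yz", "xz"))
  expect_true(all(c("curvature_yz_mean", "turn_rate_xy_q3", "hull_area_xz")
                  %in% reg$name))
})

test_that("filter_short_tracks excludes strictly below the threshold", {
  fps <- 10
  mk <- function(id, dur) {
    n <- dur * fps + 1
    as_track_tbl(matrix(rnorm(n * 3, sd = 0.01), ncol = 3), fps = fps,
                 track_id = id)
  }
  tracks <- dplyr::bind_rows(mk("a", 2.9), mk("b", 3.0), mk("c", 3.1))
  kept <- filter_short_tracks(tracks, 3, quiet = TRUE)
  expect_setequal(unique(kept$track_id), c("b", "c"))

  # all-long input is the identity
  long <- dplyr::bind_rows(mk("p", 4), mk("q", 5))
  expect_identical(filter_short_tracks(long, 3, quiet = TRUE), long)
})

test_that("filtered counts equal a brute-force recount on a seeded trial", {
  cfg <- swarm_sim_config("couple")
  trial <- simulate_trial(cfg, "trX", seed = 31, n_tracks = 40,
                          duration_range = c(1, 6))
  durs <- dplyr::summarise(dplyr::group_by(trial, track_id),
                           d = max(t_s) - min(t_s), .groups = "drop")
  expected <- sum(durs$d >= 3 - 1e-9)
  kept <- filter_short_tracks(trial, 3, quiet = TRUE)
  expect_equal(dplyr::n_distinct(kept$track_id), expected)
})

test_that("segmentation arithmetic matches the stride formula", {
  trk <- as_track_tbl(matrix(rnorm(251 * 3, sd = 0.01), ncol = 3))  # 10 s
  s0 <- segment_tracks(trk, window = 2, overlap = 0)
  expect_equal(dplyr::n_distinct(s0$window_id), 5)
  s50 <- segment_tracks(trk, window = 2, overlap = 0.5)
  expect_equal(dplyr::n_distinct(s50$window_id), 9)

  short <- as_track_tbl(matrix(rnorm(38 * 3), ncol = 3))  # 1.5 s
  expect_equal(nrow(segment_tracks(short, window = 2)), 0)

  expect_error(segment_tracks(trk, window = 2, overlap = 0.95), "overlap")
  expect_error(segment_tracks(trk, window = 0.04), "window")

  # every segment spans the window within one frame interval
  spans <- dplyr::summarise(
    dplyr::group_by(s50, window_id),
    span = max(t_s) - min(t_s), n = dplyr::n(), .groups = "drop"
  )
  expect_true(all(abs(spans$span - 2) <= 0.04 + 1e-9))
  expect_true(all(spans$n >= 3))
})

test_that("straightness matches analytic values", {
  # uniform straight line
  line <- cbind(seq(0, 1, length.out = 50), seq(0, 2, length.out = 50))
  expect_equal(straightness(line), 1.0, tolerance = 1e-12)

  # dense semicircle: arc pi*r over chord 2r = pi/2
  th <- seq(0, pi, length.out = 1000)
  semi <- cbind(cos(th), sin(th))
  expect_equal(straightness(semi), pi / 2, tolerance = 1e-4)

  # 3-point right angle: (2 steps of length 1) / sqrt(2)
  expect_equal(straightness(rbind(c(0, 0), c(1, 0), c(1, 1))),
               2 / sqrt(2), tolerance = 1e-12)

  # closed loop: capped and flagged, not dropped
  s <- straightness(rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 0)))
  expect_equal(as.numeric(s), 1e6)
  expect_true(attr(s, "flagged"))
})

test_that("curvature matches analytic values on circle, line, and parabola", {
  th <- seq(0, 2 * pi, length.out = 2000)
  circ <- cbind(0.5 * cos(th), 0.5 * sin(th))
  k <- curvature_series(circ, dt = 0.001)
  inner <- k[5:(length(k) - 5)]
  expect_true(all(abs(abs(inner) - 2) < 0.02))

  line <- cbind(seq(0, 1, length.out = 100), seq(0, 3, length.out = 100))
  expect_true(all(abs(curvature_series(line, dt = 0.04)) < 1e-9))

  # parabola y = x^2: k(x) = 2 / (1 + 4x^2)^(3/2) -> 2 at the vertex
  x <- seq(-0.5, 0.5, length.out = 2001)
  par <- cbind(x, x^2)
  k <- curvature_series(par, dt = 0.001)
  vertex <- which.min(abs(x))
  expect_equal(k[vertex], 2, tolerance = 0.01)

  # reversal flips sign, keeps magnitude
  k_fwd <- curvature_series(circ, dt = 0.001)
  k_rev <- curvature_series(circ[nrow(circ):1, ], dt = 0.001)
  expect_equal(k_fwd[10], -k_rev[length(k_rev) - 9], tolerance = 1e-6)
})

test_that("step angles match polygon geometry", {
  line <- cbind(seq(0, 1, length.out = 20), 0)
  expect_equal(step_angles(line), rep(0, 18), tolerance = 1e-12)

  # regular hexagon: exterior angle pi/3 at every vertex
  th <- seq(0, 2 * pi, length.out = 7)[1:6]
  hexagon <- cbind(cos(th), sin(th))
  expect_equal(step_angles(hexagon), rep(pi / 3, 4), tolerance = 1e-12)

  # square path: angles pi/2, Q3 of the constant series is pi/2
  sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1), c(0, 0))
  a <- step_angles(sq)
  expect_equal(a, rep(pi / 2, 3), tolerance = 1e-12)
  expect_equal(unname(quantile(a, 0.75)), pi / 2, tolerance = 1e-12)

  # zero-length step leaves the angle undefined
  z <- rbind(c(0, 0), c(0, 0), c(1, 0))
  expect_true(is.na(step_angles(z)[1]))
})

test_that("constant-velocity segments give degenerate statistics", {
  m <- cbind(seq(0, 2, length.out = 51), seq(0, 1, length.out = 51))
  fv <- extract_features(m, dt = 0.04)
  expect_equal(unname(fv["speed_std"]), 0, tolerance = 1e-9)
  expect_equal(unname(fv["straightness"]), 1, tolerance = 1e-9)
  expect_equal(unname(fv["angle_change_max"]), 0, tolerance = 1e-6)
  expect_equal(unname(fv["curvature_abs_max"]), 0, tolerance = 1e-9)
})

test_that("feature vector length equals the registry length and has no NAs", {
  trk <- simulate_track(swarm_sim_config("couple"), 2, seed = 6)
  seg3 <- extract_features(cbind(trk$x_m, trk$y_m, trk$z_m))
  expect_length(seg3, nrow(feature_registry(3)))
  expect_false(anyNA(seg3))

  tele <- telecentric_project(trk)
  seg2 <- extract_features(cbind(tele$u, tele$v))
  expect_length(seg2, 136)
  expect_false(anyNA(seg2))
  expect_named(seg2, feature_registry(2)$name)
})

test_that("features agree with an independent naive reimplementation", {
  # naive oracle: statistics computed with base stats:: functions over
  # series derived with explicit loops
  naive_features <- function(m, dt) {
    n <- nrow(m)
    grad <- function(x) {
      g <- numeric(n)
      g[1] <- (x[2] - x[1]) / dt
      g[n] <- (x[n] - x[n - 1]) / dt
      for (i in 2:(n - 1)) g[i] <- (x[i + 1] - x[i - 1]) / (2 * dt)
      g
    }
    vx <- grad(m[, 1]); vy <- grad(m[, 2])
    speed <- sqrt(vx^2 + vy^2)
    ax <- grad(vx); ay <- grad(vy)
    stats <- function(x) c(
      mean(x), sd(x), min(x), max(x),
      unname(quantile(x, 0.25)), median(x), unname(quantile(x, 0.75)),
      unname(diff(quantile(x, c(0.25, 0.75)))))
    list(speed = stats(speed),
         vel_u = stats(vx),
         accel_v = stats(ay),
         curvature = {
           sp2 <- vx^2 + vy^2
           k <- (vx * ay - vy * ax) / sp2^1.5
           stats(k[sp2 >= 0.01 * median(sp2)])
         })
  }
  set.seed(42)
  for (i in 1:50) {
    n <- sample(30:80, 1)
    t <- seq(0, by = 0.04, length.out = n)
    m <- cbind(cumsum(rnorm(n, sd = 0.05)) + sin(t),
               cumsum(rnorm(n, sd = 0.05)) + cos(2 * t))
    fv <- extract_features(m, dt = 0.04)
    nv <- naive_features(m, 0.04)
    stat_names <- c("mean", "std", "min", "max", "q1", "median", "q3", "iqr")
    for (s in names(nv)) {
      got <- unname(fv[paste(s, stat_names, sep = "_")])
      expect_equal(got, unname(nv[[s]]), tolerance = 1e-9)
    }
  }
})

test_that("feature extraction is translation-invariant", {
  set.seed(3)
  m <- cbind(cumsum(rnorm(60, sd = 0.03)), cumsum(rnorm(60, sd = 0.03)))
  f1 <- extract_features(m, dt = 0.04)
  f2 <- extract_features(sweep(m, 2, c(5, -3), "+"), dt = 0.04)
  expect_equal(unclass(f1), unclass(f2), tolerance = 1e-7)
})

test_that("telecentric features of a YZ-planar track equal 3D YZ-plane features", {
  # constant-depth 3D track: YZ-plane-dependent 3D features must equal the
  # 2D features computed on the telecentric projection exactly
  set.seed(9)
  m3 <- cbind(1.7, cumsum(rnorm(75, sd = 0.04)), cumsum(rnorm(75, sd = 0.04)))
  f3 <- extract_features(m3, dt = 0.04)
  f2 <- extract_features(m3[, 2:3], dt = 0.04)

  pairs <- c(
    speed_mean = "speed_mean", speed_q3 = "speed_q3",
    vel_u_std = "vel_y_std", vel_v_max = "vel_z_max",
    accel_mag_median = "accel_mag_median",
    angle_change_q3 = "angle_change_q3",
    curvature_mean = "curvature_yz_mean",
    curvature_abs_iqr = "curvature_abs_yz_iqr",
    turn_rate_q1 = "turn_rate_yz_q1",
    straightness = "straightness",
    path_length = "path_length",
    hull_area = "hull_area_yz",
    radius_gyration = "radius_gyration"
  )
  for (nm2 in names(pairs)) {
    expect_equal(unname(f2[nm2]), unname(f3[pairs[nm2]]), tolerance = 1e-12,
                 label = nm2)
  }
})

test_that("segment_features returns provenance plus registry columns", {
  b <- small_benchmark()
  one_trial <- b$modelling[b$modelling$trial_id ==
                             b$modelling$trial_id[1], ]
  one_trial <- filter_short_tracks(one_trial, 3, quiet = TRUE)
  sf <- segment_features(telecentric_project(one_trial), 1, 0.5)
  expect_identical(names(sf)[1:7],
                   c("trial_id", "track_id", "class_name", "window_id",
                     "t_start", "t_end", "flag_degenerate"))
  expect_identical(names(sf)[-(1:7)], feature_registry(2)$name)
  expect_false(anyNA(sf))
})
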