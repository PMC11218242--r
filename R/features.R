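#' The flight-feature registry
#'
#' Every per-segment feature is an entry in the registry: either a summary
#' statistic (mean, std, min, max, Q1, median, Q3, IQR) of a per-sample
#' kinematic series, or a whole-segment scalar. The 2D registry has exactly
#' 136 entries: 16 series (speed, per-axis velocity, acceleration magnitude
#' and per-axis acceleration, jerk magnitude and per-axis jerk, tangential
#' acceleration, unsigned angle of flight change, signed turn rate, signed
#' curvature and its magnitude, step length, distance from the segment
#' centroid) x 8 statistics, plus 8 whole-segment scalars (straightness,
#' path length, net displacement, bounding-box extents and aspect, radius of
#' gyration, convex-hull area). The 3D registry computes dimension-free
#' series from full 3D vectors and adds per-plane (XY, YZ, XZ) entries for
#' the plane-dependent features (signed turn rate, curvature, hull area).
#'
#' The exact feature list used by the original field analysis is not public;
#' this registry is a reconstruction from the named feature families and is
#' the package's documented default. It can be subset or reordered and passed
#' to [segment_features()].
#'
#' @param dims 2 or 3.
#' @return A tibble with columns `name`, `kind` (`"series"` or `"scalar"`),
#'   `series` (series name or scalar name), `stat` (statistic or NA), and
#'   `plane` (NA, `"xy"`, `"yz"`, `"xz"`).
#' @export
feature_registry <- function(dims = 2) {
  stopifnot(dims %in% c(2, 3))
  stats <- c("mean", "std", "min", "max", "q1", "median", "q3", "iqr")
  if (dims == 2) {
    series <- c("speed", "vel_u", "vel_v", "accel_mag", "accel_u", "accel_v",
                "jerk_mag", "jerk_u", "jerk_v", "tangential_accel",
                "angle_change", "turn_rate", "curvature", "curvature_abs",
                "step_length", "dist_centroid")
    scalars <- c("straightness", "path_length", "net_displacement",
                 "bbox_extent_u", "bbox_extent_v", "bbox_aspect",
                 "radius_gyration", "hull_area")
    reg <- bind_rows(
      tidyr::expand_grid(series = series, stat = stats) |>
        mutate(name = paste(series, .data$stat, sep = "_"),
               kind = "series", plane = NA_character_),
      tibble(series = scalars, stat = NA_character_, name = scalars,
             kind = "scalar", plane = NA_character_)
    )
  } else {
    free_series <- c("speed", "vel_x", "vel_y", "vel_z",
                     "accel_mag", "accel_x", "accel_y", "accel_z",
                     "jerk_mag", "jerk_x", "jerk_y", "jerk_z",
                     "tangential_accel", "angle_change",
                     "step_length", "dist_centroid")
    plane_series <- c("turn_rate", "curvature", "curvature_abs")
    planes <- c("xy", "yz", "xz")
    reg <- bind_rows(
      tidyr::expand_grid(series = free_series, stat = stats) |>
        mutate(name = paste(series, .data$stat, sep = "_"),
               kind = "series", plane = NA_character_),
      tidyr::expand_grid(series = plane_series, plane = planes, stat = stats) |>
        mutate(name = paste(series, .data$plane, .data$stat, sep = "_"),
               kind = "series"),
      tibble(series = c("straightness", "path_length", "net_displacement",
                        "bbox_extent_x", "bbox_extent_y", "bbox_extent_z",
                        "bbox_aspect", "radius_gyration"),
             stat = NA_character_, kind = "scalar", plane = NA_character_) |>
        mutate(name = .data$series),
      tidyr::expand_grid(series = "hull_area", plane = planes) |>
        mutate(stat = NA_character_, kind = "scalar",
               name = paste(.data$series, .data$plane, sep = "_"))
    )
  }
  stopifnot(!anyDuplicated(reg$name))
  reg[, c("name", "kind", "series", "stat", "plane")]
}

#' Filter out short tracks
#'
#' Removes tracks whose duration (time from first to last frame) is below
#' `min_duration` seconds, the low-information-content filter applied before
#' all analysis; tracks of exactly the threshold duration are retained
#' (only `< min_duration` is excluded). Counts before/after per class are
#' reported as a message.
#'
#' @param tracks A track tibble (2D or 3D).
#' @param min_duration Seconds, default 3.
#' @param quiet Suppress the per-class count message.
#' @return The filtered track tibble.
#' @export
filter_short_tracks <- function(tracks, min_duration = 3, quiet = FALSE) {
  durs <- track_durations(tracks)
  keep <- durs[durs$duration_s >= min_duration - 1e-9, ]
  if (!quiet) {
    before <- table(durs$class_name)
    after <- table(factor(keep$class_name, levels = names(before)))
    inform(paste0(
      "filter_short_tracks: ",
      paste(sprintf("%s %d -> %d", names(before), as.integer(before),
                    as.integer(after)), collapse = "; ")
    ))
  }
  key <- paste(tracks$trial_id, tracks$track_id, sep = "\x1f")
  tracks[key %in% paste(keep$trial_id, keep$track_id, sep = "\x1f"), ]
}

# Window start offsets (0-based sample indices) for a track of n samples.
segment_starts <- function(n_samples, n_win, stride) {
  if (n_samples < n_win) return(integer(0))
  seq.int(0L, n_samples - n_win, by = stride)
}

segment_geometry <- function(window, overlap, fps) {
  if (overlap < 0 || overlap > 0.9) {
    abort("`overlap` must lie in [0, 0.9].")
  }
  n_steps <- round(window * fps)
  if (n_steps < 2) {
    abort("`window` must span at least two frame intervals (three samples).")
  }
  stride <- max(1L, as.integer(round(n_steps * (1 - overlap))))
  list(n_win = as.integer(n_steps + 1L), stride = stride)
}

#' Split tracks into fixed-duration segments
#'
#' Windows of `window` seconds are laid along each track with stride
#' `window * (1 - overlap)`, aligned to frames; the trailing partial window
#' is dropped, and a track shorter than one window yields no segments.
#'
#' @param tracks A track tibble (2D or 3D).
#' @param window Window length, seconds.
#' @param overlap Overlap fraction in \[0, 0.9\].
#' @param fps Frames per second; inferred from the time grid if `NULL`.
#' @return The track tibble replicated per window with an extra `window_id`
#'   column (frames falling in several overlapping windows appear once per
#'   window).
#' @export
segment_tracks <- function(tracks, window, overlap = 0, fps = NULL) {
  validate_tracks(tracks)
  fps <- fps %||% track_fps(tracks)
  geo <- segment_geometry(window, overlap, fps)
  tracks |>
    group_by(.data$trial_id, .data$track_id) |>
    dplyr::group_modify(function(df, key) {
      df <- df[order(df$frame), ]
      starts <- segment_starts(nrow(df), geo$n_win, geo$stride)
      if (length(starts) == 0) {
        return(df[0, , drop = FALSE] |> mutate(window_id = integer(0)))
      }
      purrr::map2(starts, seq_along(starts), function(s, w) {
        df[(s + 1):(s + geo$n_win), , drop = FALSE] |>
          mutate(window_id = as.integer(w))
      }) |> bind_rows()
    }) |>
    ungroup()
}

# ---- kinematic primitives ---------------------------------------------

# central-difference gradient along columns, one-sided at the ends
finite_gradient <- function(m, dt) {
  m <- as.matrix(m)
  n <- nrow(m)
  if (n < 2) return(m * 0)
  g <- m
  g[1, ] <- (m[2, ] - m[1, ]) / dt
  g[n, ] <- (m[n, ] - m[n - 1, ]) / dt
  if (n > 2) {
    g[2:(n - 1), ] <- (m[3:n, , drop = FALSE] -
                         m[1:(n - 2), , drop = FALSE]) / (2 * dt)
  }
  g
}

coerce_segment_matrix <- function(segment) {
  if (is.matrix(segment) || is.data.frame(segment) && !is_tibble(segment) &&
      all(vapply(segment, is.numeric, TRUE))) {
    return(as.matrix(segment))
  }
  if (is.data.frame(segment)) {
    if (all(c("x_m", "y_m", "z_m") %in% names(segment))) {
      return(cbind(segment$x_m, segment$y_m, segment$z_m))
    }
    if (all(c("u", "v") %in% names(segment))) {
      return(cbind(segment$u, segment$v))
    }
    num <- segment[vapply(segment, is.numeric, TRUE)]
    return(as.matrix(num))
  }
  as.matrix(segment)
}

#' Straightness (tortuosity) of a segment
#'
#' The ratio of the actual distance travelled (sum of consecutive Euclidean
#' steps) to the straight-line distance between start and end positions,
#' \deqn{S = \frac{\sum_i \| P_{i+1} - P_i \|}{\| P_N - P_0 \|} \ge 1,}
#' computed with all available axes (2 or 3). Coincident endpoints make the
#' denominator zero; the configured cap is returned and flagged rather than
#' dropping the segment, since closed loops are real flight behaviour.
#'
#' @param segment A track tibble, data frame, or numeric matrix of positions
#'   (rows = samples, columns = axes).
#' @param cap Value returned when the endpoints coincide (default 1e6).
#' @return A scalar >= 1, with attribute `flagged = TRUE` when capped.
#' @export
straightness <- function(segment, cap = 1e6) {
  m <- coerce_segment_matrix(segment)
  if (nrow(m) < 2) abort("Straightness needs at least two samples.")
  steps <- sqrt(rowSums((m[-1, , drop = FALSE] -
                           m[-nrow(m), , drop = FALSE])^2))
  chord <- sqrt(sum((m[nrow(m), ] - m[1, ])^2))
  if (chord == 0) {
    return(structure(cap, flagged = TRUE))
  }
  max(sum(steps) / chord, 1)
}

#' Signed planar curvature series
#'
#' Per-sample curvature
#' \deqn{k_i = \frac{\dot x_i \ddot y_i - \dot y_i \ddot x_i}
#'                  {(\dot x_i^2 + \dot y_i^2)^{3/2}}}
#' with first and second derivatives from central finite differences at the
#' sampling rate (one-sided at the ends). 3D segments are projected onto the
#' requested plane first.
#'
#' Curvature is undefined at zero planar speed, and numerically meaningless
#' just above it: with 1/speed^3 in the denominator and a planar-speed
#' density that is positive at zero, the per-sample values have power-law
#' tails with no finite variance, so any moment or extreme statistic of the
#' raw series never stabilises. Samples whose planar speed falls below
#' `speed_floor` times the segment's median planar speed are therefore
#' returned as `NA` (excluded from downstream statistics and flagged), the
#' same treatment the exact-zero case receives. The default floor of 0.1
#' bounds the tail while leaving typical flight samples untouched; it is a
#' documented numerical choice, not a fitted constant.
#'
#' @inheritParams straightness
#' @param plane For 3D segments: `"xy"`, `"yz"`, or `"xz"`.
#' @param dt Sample interval, seconds (default 0.04, i.e. 25 fps); ignored
#'   when `segment` is a track tibble carrying its own time grid.
#' @param speed_floor Fraction of the segment's median planar speed below
#'   which curvature is treated as undefined (default 0.1; 0 disables).
#' @return Numeric vector of per-sample curvature (1/m or 1/px).
#' @export
curvature_series <- function(segment, plane = c("xy", "yz", "xz"), dt = 0.04,
                             speed_floor = 0.1) {
  plane <- match.arg(plane)
  m <- coerce_segment_matrix(segment)
  if (is.data.frame(segment) && "t_s" %in% names(segment) &&
      nrow(segment) > 1) {
    dt <- median(diff(segment$t_s))
  }
  if (ncol(m) == 3) {
    idx <- switch(plane, xy = c(1, 2), yz = c(2, 3), xz = c(1, 3))
    m <- m[, idx, drop = FALSE]
  }
  if (nrow(m) < 3) abort("Curvature needs at least three samples.")
  v <- finite_gradient(m, dt)
  a <- finite_gradient(v, dt)
  sp2 <- v[, 1]^2 + v[, 2]^2
  k <- (v[, 1] * a[, 2] - v[, 2] * a[, 1]) / sp2^1.5
  floor2 <- (speed_floor^2) * median(sp2)
  k[sp2 == 0 | sp2 < floor2] <- NA_real_
  k
}

#' Per-step change in flight direction
#'
#' The unsigned angle (radians, in \[0, pi\]) between successive displacement
#' vectors, from the arccosine of their normalized dot product — the same
#' convention in 2D and 3D so the feature is dimension-comparable. Steps of
#' zero length leave the angle undefined (`NA`, excluded downstream).
#'
#' @inheritParams straightness
#' @return Numeric vector of length `n - 2`.
#' @export
step_angles <- function(segment) {
  m <- coerce_segment_matrix(segment)
  if (nrow(m) < 3) abort("Step angles need at least three samples.")
  d <- m[-1, , drop = FALSE] - m[-nrow(m), , drop = FALSE]
  a <- d[-nrow(d), , drop = FALSE]
  b <- d[-1, , drop = FALSE]
  na <- sqrt(rowSums(a^2))
  nb <- sqrt(rowSums(b^2))
  cosang <- rowSums(a * b) / (na * nb)
  ang <- acos(pmin(1, pmax(-1, cosang)))
  ang[na == 0 | nb == 0] <- NA_real_
  ang
}

# signed turn rate (rad/s) on a 2-column matrix
signed_turn_rate <- function(m, dt) {
  d <- m[-1, , drop = FALSE] - m[-nrow(m), , drop = FALSE]
  a <- d[-nrow(d), , drop = FALSE]
  b <- d[-1, , drop = FALSE]
  cross <- a[, 1] * b[, 2] - a[, 2] * b[, 1]
  dot <- rowSums(a * b)
  ang <- atan2(cross, dot)
  ang[rowSums(a^2) == 0 | rowSums(b^2) == 0] <- NA_real_
  ang / dt
}

# convex hull area of a 2-column matrix (shoelace); 0 for degenerate hulls
hull_area_2d <- function(m) {
  m <- unique(m)
  if (nrow(m) < 3) return(0)
  h <- grDevices::chull(m)
  p <- m[h, , drop = FALSE]
  n <- nrow(p)
  if (n < 3) return(0)
  j <- c(2:n, 1)
  abs(sum(p[, 1] * p[j, 2] - p[j, 1] * p[, 2])) / 2
}

stat_funs <- list(
  mean = function(x) mean(x),
  std = function(x) if (length(x) > 1) sd(x) else 0,
  min = function(x) min(x),
  max = function(x) max(x),
  q1 = function(x) unname(quantile(x, 0.25)),
  median = function(x) median(x),
  q3 = function(x) unname(quantile(x, 0.75)),
  iqr = function(x) unname(quantile(x, 0.75) - quantile(x, 0.25))
)

# all eight summary statistics from one sort (quantiles are type 7,
# matching stats::quantile defaults)
stat8 <- function(x) {
  n <- length(x)
  xs <- sort.int(x, method = "quick")
  q <- function(p) {
    h <- (n - 1) * p + 1
    lo <- floor(h)
    hi <- ceiling(h)
    xs[lo] + (h - lo) * (xs[hi] - xs[lo])
  }
  q1 <- q(0.25); q2 <- q(0.5); q3 <- q(0.75)
  c(mean = sum(xs) / n,
    std = if (n > 1) sqrt(sum((x - sum(xs) / n)^2) / (n - 1)) else 0,
    min = xs[1], max = xs[n],
    q1 = q1, median = q2, q3 = q3, iqr = q3 - q1)
}

# All per-sample series for one segment. m: n x d matrix, dt seconds.
segment_series <- function(m, dt) {
  d <- ncol(m)
  n <- nrow(m)
  vel <- finite_gradient(m, dt)
  acc <- finite_gradient(vel, dt)
  jrk <- finite_gradient(acc, dt)
  speed <- sqrt(rowSums(vel^2))
  centroid <- colMeans(m)
  out <- list(
    speed = speed,
    accel_mag = sqrt(rowSums(acc^2)),
    jerk_mag = sqrt(rowSums(jrk^2)),
    tangential_accel = as.numeric(finite_gradient(matrix(speed), dt)),
    angle_change = step_angles(m),
    step_length = sqrt(rowSums((m[-1, , drop = FALSE] -
                                  m[-n, , drop = FALSE])^2)),
    dist_centroid = sqrt(rowSums((m - matrix(centroid, n, d, byrow = TRUE))^2))
  )
  axis_names <- if (d == 2) c("u", "v") else c("x", "y", "z")
  for (j in seq_len(d)) {
    out[[paste0("vel_", axis_names[j])]] <- vel[, j]
    out[[paste0("accel_", axis_names[j])]] <- acc[, j]
    out[[paste0("jerk_", axis_names[j])]] <- jrk[, j]
  }
  if (d == 2) {
    out$turn_rate <- signed_turn_rate(m, dt)
    out$curvature <- curvature_series(m, dt = dt)
    out$curvature_abs <- abs(out$curvature)
  } else {
    for (pl in c("xy", "yz", "xz")) {
      idx <- switch(pl, xy = c(1, 2), yz = c(2, 3), xz = c(1, 3))
      mp <- m[, idx, drop = FALSE]
      out[[paste0("turn_rate_", pl)]] <- signed_turn_rate(mp, dt)
      k <- curvature_series(mp, dt = dt)
      out[[paste0("curvature_", pl)]] <- k
      out[[paste0("curvature_abs_", pl)]] <- abs(k)
    }
  }
  out
}

segment_scalars <- function(m, dt) {
  d <- ncol(m)
  n <- nrow(m)
  steps <- sqrt(rowSums((m[-1, , drop = FALSE] - m[-n, , drop = FALSE])^2))
  chord <- sqrt(sum((m[n, ] - m[1, ])^2))
  s <- straightness(m)
  flagged <- isTRUE(attr(s, "flagged"))
  ext <- apply(m, 2, function(x) diff(range(x)))
  aspect <- if (max(ext) == 0) {
    flagged <- TRUE
    1
  } else {
    min(ext) / max(ext)
  }
  centroid <- colMeans(m)
  rg <- sqrt(mean(rowSums((m - matrix(centroid, n, d, byrow = TRUE))^2)))
  axis_names <- if (d == 2) c("u", "v") else c("x", "y", "z")
  out <- c(
    straightness = as.numeric(s),
    path_length = sum(steps),
    net_displacement = chord,
    setNames(ext, paste0("bbox_extent_", axis_names)),
    bbox_aspect = aspect,
    radius_gyration = rg
  )
  if (d == 2) {
    out["hull_area"] <- hull_area_2d(m)
  } else {
    for (pl in c("xy", "yz", "xz")) {
      idx <- switch(pl, xy = c(1, 2), yz = c(2, 3), xz = c(1, 3))
      out[paste0("hull_area_", pl)] <- hull_area_2d(m[, idx, drop = FALSE])
    }
  }
  attr(out, "flagged") <- flagged
  out
}

#' Extract the registry feature vector from one segment
#'
#' Evaluates every registry entry on a single segment: per-sample kinematic
#' series are summarized by \{mean, std, min, max, Q1, median, Q3, IQR\}
#' (undefined samples such as zero-speed curvature are excluded first), and
#' whole-segment scalars are computed directly. Degenerate cases (all-NA
#' series, coincident endpoints) are imputed — 0 for series statistics, the
#' straightness cap for straightness — and flagged, never silently missing.
#'
#' @param segment A track tibble, data frame, or numeric position matrix for
#'   one segment (>= 3 samples).
#' @param registry A [feature_registry()]; defaults to the registry matching
#'   the segment's dimensionality.
#' @param dt Sample interval, seconds; inferred from a `t_s` column if
#'   present.
#' @return A named numeric vector in registry order, with attribute
#'   `flagged` (logical).
#' @export
extract_features <- function(segment, registry = NULL, dt = 0.04) {
  m <- coerce_segment_matrix(segment)
  if (is.data.frame(segment) && "t_s" %in% names(segment) &&
      nrow(segment) > 1) {
    dt <- median(diff(segment$t_s))
  }
  if (nrow(m) < 3) abort("A segment needs at least three samples.")
  registry <- registry %||% feature_registry(ncol(m))
  series <- segment_series(m, dt)
  scalars <- segment_scalars(m, dt)
  flagged <- isTRUE(attr(scalars, "flagged"))

  vals <- numeric(nrow(registry))
  is_scalar <- registry$kind == "scalar"
  if (any(is_scalar)) {
    vals[is_scalar] <- scalars[registry$name[is_scalar]]
  }
  ser_rows <- which(!is_scalar)
  if (length(ser_rows) > 0) {
    key <- registry$series[ser_rows]
    has_plane <- !is.na(registry$plane[ser_rows])
    key[has_plane] <- paste(key[has_plane], registry$plane[ser_rows][has_plane],
                            sep = "_")
    stat <- registry$stat[ser_rows]
    for (k in unique(key)) {
      x <- series[[k]]
      x <- x[is.finite(x)]
      rows <- ser_rows[key == k]
      if (length(x) == 0) {
        vals[rows] <- 0
        flagged <- TRUE
      } else {
        s8 <- stat8(x)
        vals[rows] <- s8[stat[key == k]]
      }
    }
  }
  structure(setNames(vals, registry$name), flagged = flagged)
}

#' Per-segment feature table for a track bundle
#'
#' The workhorse of the pipeline: filters nothing, segments every track with
#' [segment_tracks()] geometry, and evaluates the full [feature_registry()]
#' on each window, returning one row per segment with provenance columns
#' first (`trial_id`, `track_id`, `class_name`, `window_id`, `t_start`,
#' `t_end`, `flag_degenerate`) and one column per registry feature in
#' registry order.
#'
#' @param tracks A track tibble (2D or 3D).
#' @param window Segment length, seconds.
#' @param overlap Overlap fraction in \[0, 0.9\].
#' @param registry Optional [feature_registry()] subset.
#' @param fps Frames per second; inferred if `NULL`.
#' @return A segment feature tibble.
#' @export
segment_features <- function(tracks, window, overlap = 0, registry = NULL,
                             fps = NULL) {
  validate_tracks(tracks)
  dims <- track_dims(tracks)
  fps <- fps %||% track_fps(tracks)
  dt <- 1 / fps
  registry <- registry %||% feature_registry(dims)
  geo <- segment_geometry(window, overlap, fps)

  coords <- if (dims == 3L) c("x_m", "y_m", "z_m") else c("u", "v")
  key <- paste(tracks$trial_id, tracks$track_id, sep = "\x1f")
  pieces <- split(seq_len(nrow(tracks)), key)

  rows <- purrr::map(pieces, function(idx) {
    df <- tracks[idx, ]
    df <- df[order(df$frame), ]
    m <- as.matrix(df[, coords])
    starts <- segment_starts(nrow(df), geo$n_win, geo$stride)
    if (length(starts) == 0) return(NULL)
    feats <- t(vapply(starts, function(s) {
      fv <- extract_features(m[(s + 1):(s + geo$n_win), , drop = FALSE],
                             registry, dt = dt)
      c(fv, flag = as.numeric(isTRUE(attr(fv, "flagged"))))
    }, numeric(nrow(registry) + 1L)))
    tibble(
      trial_id = df$trial_id[1],
      track_id = df$track_id[1],
      class_name = df$class_name[1],
      window_id = seq_along(starts),
      t_start = df$t_s[starts + 1],
      t_end = df$t_s[starts + geo$n_win],
      flag_degenerate = feats[, "flag"] > 0
    ) |> bind_cols(as_tibble(feats[, seq_len(nrow(registry)), drop = FALSE]))
  })
  out <- bind_rows(rows)
  if (nrow(out) == 0) {
    abort("No segments: every track is shorter than one window.")
  }
  out
}

#' @importFrom dplyr bind_cols
NULL

# names of the non-feature provenance columns in a segment feature table
provenance_cols <- function() {
  c("trial_id", "track_id", "class_name", "window_id", "t_start", "t_end",
    "flag_degenerate")
}

feature_cols <- function(tbl) setdiff(names(tbl), provenance_cols())
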