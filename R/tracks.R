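#' Track tables
#'
#' All trajectory data in swarmcam travels as a long-format tibble, one row
#' per video frame per track. Two dialects exist:
#'
#' * **3D tracks**: columns `trial_id`, `track_id`, `class_name`, `frame`,
#'   `t_s`, `x_m`, `y_m`, `z_m`. The world frame is X = depth (the optical
#'   axis of the simulated single camera), Y horizontal, Z vertical, so the
#'   camera-facing plane of view is YZ.
#' * **2D tracks**: columns `trial_id`, `track_id`, `class_name`, `frame`,
#'   `t_s`, `u`, `v`, `unit`, where `unit` is `"m"` (telecentric: `u`, `v`
#'   are the world Y, Z coordinates in metres) or `"px"` (single camera:
#'   image-plane pixel coordinates).
#'
#' Frames are contiguous integers per track and `t_s` lies on a uniform grid
#' (default 25 frames/s). `track_dims()` infers the dialect; `validate_tracks()`
#' checks the invariants and is called by every consumer.
#'
#' @param tracks A track tibble in either dialect.
#' @return `track_dims()` returns 2 or 3; `validate_tracks()` returns its
#'   input invisibly after validation.
#' @name track-tables
NULL

track_cols_3d <- c("trial_id", "track_id", "class_name", "frame", "t_s",
                   "x_m", "y_m", "z_m")
track_cols_2d <- c("trial_id", "track_id", "class_name", "frame", "t_s",
                   "u", "v", "unit")

#' @rdname track-tables
#' @export
track_dims <- function(tracks) {
  if (all(c("x_m", "y_m", "z_m") %in% names(tracks))) {
    if (any(c("u", "v") %in% names(tracks))) {
      abort("Track table mixes 2D and 3D coordinate columns.")
    }
    return(3L)
  }
  if (all(c("u", "v", "unit") %in% names(tracks))) {
    return(2L)
  }
  abort(paste0(
    "Not a track table: expected columns x_m/y_m/z_m (3D) or u/v/unit (2D); ",
    "got: ", paste(names(tracks), collapse = ", ")
  ))
}

#' @rdname track-tables
#' @export
validate_tracks <- function(tracks) {
  dims <- track_dims(tracks)
  required <- if (dims == 3L) track_cols_3d else track_cols_2d
  missing <- setdiff(required, names(tracks))
  if (length(missing) > 0) {
    abort(paste0("Track table is missing columns: ",
                 paste(missing, collapse = ", ")))
  }
  coords <- if (dims == 3L) c("x_m", "y_m", "z_m") else c("u", "v")
  for (col in c("t_s", coords)) {
    if (!all(is.finite(tracks[[col]]))) {
      abort(sprintf("Track table column `%s` has non-finite values.", col))
    }
  }
  if (dims == 2L) {
    bad <- setdiff(unique(tracks$unit), c("px", "m"))
    if (length(bad) > 0) {
      abort(sprintf("Unknown 2D unit tag(s): %s (must be 'px' or 'm').",
                    paste(bad, collapse = ", ")))
    }
    if (length(unique(tracks$unit)) > 1) {
      abort("2D track table mixes unit tags; one unit per table.")
    }
  }
  key <- paste(tracks$trial_id, tracks$track_id, sep = "\x1f")
  if (anyDuplicated(paste(key, tracks$frame, sep = "\x1f")) > 0) {
    abort("Duplicate (trial_id, track_id, frame) rows in track table.")
  }
  frame_gap <- vapply(
    split(tracks$frame, key),
    function(f) any(diff(sort(f)) != 1L),
    logical(1)
  )
  if (any(frame_gap)) {
    bad <- names(frame_gap)[frame_gap][1]
    parts <- strsplit(bad, "\x1f", fixed = TRUE)[[1]]
    abort(sprintf(
      "Non-contiguous frames in trial '%s', track '%s'.", parts[1], parts[2]
    ))
  }
  invisible(tracks)
}

# frames per second of a track table, from the time grid
track_fps <- function(tracks) {
  one <- tracks[tracks$trial_id == tracks$trial_id[1] &
                  tracks$track_id == tracks$track_id[1], ]
  if (nrow(one) < 2) {
    abort("Cannot infer fps from a single-sample track.")
  }
  dt <- diff(one$t_s[order(one$frame)])
  1 / median(dt)
}

# per-track durations (seconds spanned from first to last frame)
track_durations <- function(tracks) {
  tracks |>
    group_by(.data$trial_id, .data$track_id, .data$class_name) |>
    summarise(
      duration_s = max(.data$t_s) - min(.data$t_s),
      n_frames = dplyr::n(),
      .groups = "drop"
    )
}

#' @importFrom rlang .data
NULL
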