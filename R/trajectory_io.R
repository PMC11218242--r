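#' Read and write track tables
#'
#' Tracks are stored as long-format CSV (comma-separated, '.' decimal, UTF-8,
#' header row), one row per frame, with the column order and float formatting
#' fixed so that writing the same table twice produces byte-identical files.
#' 3D files carry `x_m,y_m,z_m`; 2D files carry `u,v,unit`. Both store the
#' frame index and the time in seconds so the frame-rate assumption is
#' explicit.
#'
#' @param path File path.
#' @param expected_dims Optional 2 or 3; reading a file of the other
#'   dimensionality is an error.
#' @param tracks A track tibble (see [track-tables]).
#' @return `read_tracks()` returns a validated track tibble; `write_tracks()`
#'   returns `path` invisibly.
#' @name trajectory-io
NULL

#' @rdname trajectory-io
#' @export
read_tracks <- function(path, expected_dims = NULL) {
  if (!file.exists(path)) abort(sprintf("No such file: %s", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = NA, check.names = FALSE)
  df <- as_tibble(df)
  dims <- track_dims(df)
  if (!is.null(expected_dims) && dims != expected_dims) {
    abort(sprintf("Expected a %dD track file but %s is %dD.",
                  expected_dims, path, dims))
  }
  num_cols <- if (dims == 3L) c("t_s", "x_m", "y_m", "z_m") else c("t_s", "u", "v")
  for (col in c("frame", num_cols)) {
    vals <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(vals) & !is.na(df[[col]]))
    if (length(bad) > 0 || anyNA(df[[col]])) {
      rows <- sort(unique(c(bad, which(is.na(df[[col]])))))
      abort(sprintf("Malformed values in column `%s` at data row(s): %s",
                    col, paste(head(rows, 5), collapse = ", ")))
    }
    df[[col]] <- vals
  }
  df$frame <- as.integer(df$frame)
  for (col in c("trial_id", "track_id", "class_name")) {
    df[[col]] <- as.character(df[[col]])
  }
  if (dims == 2L) df$unit <- as.character(df$unit)
  validate_tracks(df)
  df
}

#' @rdname trajectory-io
#' @export
write_tracks <- function(tracks, path) {
  dims <- track_dims(tracks)
  if (nrow(tracks) > 0) validate_tracks(tracks)
  cols <- if (dims == 3L) track_cols_3d else track_cols_2d
  out <- tracks[, cols]
  fmt <- function(x) {
    if (is.numeric(x) && !is.integer(x)) sprintf("%.9g", x) else as.character(x)
  }
  lines <- c(
    paste(cols, collapse = ","),
    if (nrow(out) > 0) {
      do.call(paste, c(lapply(out, fmt), sep = ","))
    }
  )
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, useBytes = TRUE)
  invisible(path)
}

config_defaults <- function() {
  list(
    seed = 1L,
    camera = list(
      fx = 1993.208, fy = 1986.203, cx = 705.234, cy = 515.751,
      k1 = -0.088547, k2 = 0.292341, p1 = 0, p2 = 0,
      distance_m = 2, mode = "single_camera"
    ),
    classifier = list(
      nu = 0.2, window_s = 1, overlap = 0.5, gamma_mult = 1,
      alpha = 0.05, r_max = 0.9
    ),
    filter = list(min_duration_s = 3)
  )
}

#' Load and validate an experiment configuration
#'
#' Configurations are YAML with nested sections (`camera`, `classifier`,
#' `filter`). Missing keys take documented defaults; unknown keys and
#' duplicate keys are rejected with their key paths; constraint violations
#' (e.g. `nu` outside (0, 1]) name the offending key.
#'
#' @param path Path to a YAML config file.
#' @return The fully resolved configuration list.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("No such file: %s", path))
  txt <- readLines(path, warn = FALSE)
  check_duplicate_yaml_keys(txt)
  user <- yaml::yaml.load(paste(txt, collapse = "\n")) %||% list()
  defaults <- config_defaults()

  merge_section <- function(def, usr, prefix) {
    unknown <- setdiff(names(usr), names(def))
    if (length(unknown) > 0) {
      abort(sprintf("Unknown config key(s): %s",
                    paste0(prefix, unknown, collapse = ", ")))
    }
    for (k in names(usr)) {
      if (is.list(def[[k]])) {
        if (!is.list(usr[[k]])) {
          abort(sprintf("Config key `%s%s` must be a section.", prefix, k))
        }
        def[[k]] <- merge_section(def[[k]], usr[[k]], paste0(prefix, k, "."))
      } else {
        def[[k]] <- usr[[k]]
      }
    }
    def
  }
  cfg <- merge_section(defaults, user, "")

  cl <- cfg$classifier
  if (!is.numeric(cl$nu) || cl$nu <= 0 || cl$nu > 1) {
    abort("Config key `classifier.nu` must lie in (0, 1].")
  }
  if (cl$overlap < 0 || cl$overlap > 0.9) {
    abort("Config key `classifier.overlap` must lie in [0, 0.9].")
  }
  if (cl$window_s <= 0) abort("Config key `classifier.window_s` must be > 0.")
  if (cfg$camera$fx <= 0 || cfg$camera$fy <= 0) {
    abort("Config keys `camera.fx`/`camera.fy` must be > 0.")
  }
  if (!cfg$camera$mode %in% c("telecentric", "single_camera")) {
    abort("Config key `camera.mode` must be 'telecentric' or 'single_camera'.")
  }
  if (cfg$filter$min_duration_s < 0) {
    abort("Config key `filter.min_duration_s` must be >= 0.")
  }
  cfg
}

# yaml::yaml.load silently keeps the last duplicate; detect duplicates by
# indentation-scoped key scan so they error with the key path instead.
check_duplicate_yaml_keys <- function(lines) {
  stack <- list()  # (indent, name)
  seen <- new.env(parent = emptyenv())
  for (i in seq_along(lines)) {
    line <- lines[i]
    if (grepl("^\\s*(#|$)", line)) next
    m <- regmatches(line, regexec("^(\\s*)([A-Za-z0-9_.-]+)\\s*:", line))[[1]]
    if (length(m) == 0) next
    indent <- nchar(m[2])
    key <- m[3]
    while (length(stack) > 0 && stack[[length(stack)]]$indent >= indent) {
      stack[[length(stack)]] <- NULL
    }
    path <- paste(c(vapply(stack, `[[`, "", "name"), key), collapse = ".")
    if (!is.null(seen[[path]])) {
      abort(sprintf("Duplicate config key `%s` (lines %d and %d).",
                    path, seen[[path]], i))
    }
    seen[[path]] <- i
    stack[[length(stack) + 1]] <- list(indent = indent, name = key)
  }
  invisible(TRUE)
}
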