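#' Plot helpers
#'
#' ggplot2 views of the package's result types: trajectories, distance
#' sweeps, embeddings, and attribution summary/scatter data. Each returns a
#' ggplot object for further styling.
#'
#' @param tracks A track tibble (2D or 3D; 3D tracks are drawn in the YZ
#'   plane of view).
#' @param max_tracks Cap on the number of tracks drawn.
#' @name plots
NULL

#' @rdname plots
#' @export
plot_tracks <- function(tracks, max_tracks = 12) {
  validate_tracks(tracks)
  dims <- track_dims(tracks)
  ids <- unique(paste(tracks$trial_id, tracks$track_id, sep = "\x1f"))
  keep <- head(ids, max_tracks)
  df <- tracks[paste(tracks$trial_id, tracks$track_id, sep = "\x1f") %in% keep, ]
  if (dims == 3L) {
    ggplot2::ggplot(df, ggplot2::aes(.data$y_m, .data$z_m,
                                     group = interaction(.data$trial_id,
                                                         .data$track_id),
                                     colour = .data$class_name)) +
      ggplot2::geom_path(alpha = 0.8) +
      ggplot2::coord_equal() +
      ggplot2::labs(x = "y (m)", y = "z (m)", colour = "class",
                    title = "Trajectories (YZ plane of view)")
  } else {
    unit <- df$unit[1]
    ggplot2::ggplot(df, ggplot2::aes(.data$u, .data$v,
                                     group = interaction(.data$trial_id,
                                                         .data$track_id),
                                     colour = .data$class_name)) +
      ggplot2::geom_path(alpha = 0.8) +
      ggplot2::coord_equal() +
      ggplot2::scale_y_reverse() +
      ggplot2::labs(x = sprintf("u (%s)", unit), y = sprintf("v (%s)", unit),
                    colour = "class", title = "Projected trajectories")
  }
}

#' @rdname plots
#' @param sweep A [distance_sweep()] result.
#' @export
plot_sweep <- function(sweep) {
  finite <- sweep[is.finite(sweep$distance_m), ]
  baseline <- sweep[!is.finite(sweep$distance_m), ]
  metric <- if ("balanced_accuracy" %in% names(sweep)) {
    "balanced_accuracy"
  } else {
    "correlation_to_telecentric"
  }
  p <- ggplot2::ggplot(finite,
                       ggplot2::aes(.data$distance_m, .data[[metric]])) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "camera distance (m)", y = gsub("_", " ", metric))
  if (nrow(baseline) > 0 && is.finite(baseline[[metric]][1])) {
    p <- p + ggplot2::geom_hline(yintercept = baseline[[metric]][1],
                                 linetype = "dashed")
  }
  p
}

#' @rdname plots
#' @param embedding An [embed_features()] result.
#' @export
plot_embedding <- function(embedding) {
  colour <- if ("dataset" %in% names(embedding) &&
                length(unique(embedding$dataset)) > 1) {
    "dataset"
  } else {
    "class_name"
  }
  ggplot2::ggplot(embedding, ggplot2::aes(.data$dim1, .data$dim2,
                                          colour = .data[[colour]])) +
    ggplot2::geom_point(alpha = 0.7, size = 1) +
    ggplot2::labs(x = "dim 1", y = "dim 2", colour = colour,
                  title = "Feature-space embedding")
}

#' @rdname plots
#' @param attr An `attribution_matrix` from [explain()].
#' @param top_n Features shown in the summary plot.
#' @export
plot_attribution_summary <- function(attr, top_n = 15) {
  s <- head(attribution_summary(attr), top_n)
  s$feature <- factor(s$feature, levels = rev(s$feature))
  ggplot2::ggplot(s, ggplot2::aes(.data$mean_abs_attribution, .data$feature)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "mean |attribution|", y = NULL,
                  title = "Feature attribution ranking")
}

#' @rdname plots
#' @param feature Feature name for the scatter plot.
#' @export
plot_attribution_scatter <- function(attr, feature) {
  df <- attribution_scatter(attr, feature)
  ggplot2::ggplot(df, ggplot2::aes(.data$feature_value, .data$attribution)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dotted") +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::geom_rug(sides = "b", alpha = 0.2) +
    ggplot2::labs(x = sprintf("%s (normalised)", feature),
                  y = "attribution")
}
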