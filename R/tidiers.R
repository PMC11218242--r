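#' Broom-style tidiers
#'
#' `tidy()` and `glance()` methods for the package's fitted objects:
#' an `oc_cv` cross-validation result tidies to its metric table and glances
#' to a one-row summary; an `oc_track_model` tidies to its selected features;
#' an `attribution_matrix` tidies to long-format attributions.
#'
#' @param x The object to tidy.
#' @param ... Unused.
#' @return A tibble.
#' @name tidiers
NULL

#' @rdname tidiers
#' @method tidy oc_cv
#' @export
tidy.oc_cv <- function(x, ...) {
  as_tibble(x$metrics)
}

#' @rdname tidiers
#' @method glance oc_cv
#' @export
glance.oc_cv <- function(x, ...) {
  m <- x$metrics
  get <- function(name) m$value[m$metric == name]
  tibble(
    n_folds = length(x$fold_trials),
    n_tracks = length(unique(paste(x$folds$trial_id, x$folds$track_id))),
    balanced_accuracy = get("balanced_accuracy"),
    roc_auc = get("roc_auc"),
    window = x$config$window,
    overlap = x$config$overlap,
    nu = x$config$nu
  )
}

#' @rdname tidiers
#' @method tidy oc_track_model
#' @export
tidy.oc_track_model <- function(x, ...) {
  tibble(
    feature = x$features,
    centre = unname(x$scaler$centre),
    scale = unname(x$scaler$scale)
  )
}

#' @rdname tidiers
#' @method glance oc_track_model
#' @export
glance.oc_track_model <- function(x, ...) {
  tibble(
    n_features = length(x$features),
    n_train = x$svm$n_train,
    n_support_vectors = nrow(x$svm$sv),
    nu = x$svm$nu,
    gamma = x$svm$gamma,
    rho = x$svm$rho
  )
}

#' @rdname tidiers
#' @method tidy attribution_matrix
#' @export
tidy.attribution_matrix <- function(x, ...) {
  as_tibble(x$values) |>
    mutate(segment = dplyr::row_number(), score = x$scores) |>
    tidyr::pivot_longer(-c("segment", "score"),
                        names_to = "feature", values_to = "attribution")
}

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @export
print.metrics_report <- function(x, ...) {
  cat("Track-level classification metrics (mean [95% interval across folds])\n")
  for (i in seq_len(nrow(x))) {
    if (is.na(x$value[i])) next
    cat(sprintf("  %-22s %.3f [%.3f-%.3f]\n",
                x$metric[i], x$value[i], x$lo[i], x$hi[i]))
  }
  invisible(x)
}

#' @export
print.oc_cv <- function(x, ...) {
  cat(sprintf("Trial-held-out cross-validation: %d folds, window %.2g s, overlap %.2g\n",
              length(x$fold_trials), x$config$window, x$config$overlap))
  print(x$metrics)
  invisible(x)
}

#' @export
print.oc_svm <- function(x, ...) {
  cat(sprintf("nu one-class SVM: nu = %.2g, gamma = %.3g, %d/%d support vectors\n",
              x$nu, x$gamma, nrow(x$sv), x$n_train))
  invisible(x)
}

#' @export
print.swarm_sim_config <- function(x, ...) {
  cat(sprintf("Swarm simulation config: class '%s'\n", x$class_name))
  cat(sprintf("  omega %.3g rad/s, damping %.3g /s, noise %.3g m/s^2\n",
              x$omega, x$damping, x$noise_sigma))
  cat(sprintf("  bursts: rate %.3g /s, scale %.3g m/s^2; depth factor %.3g\n",
              x$burst_rate, x$burst_scale, x$depth_variance_factor))
  cat(sprintf("  fps %g, durations %.3g-%.3g s, %d tracks/trial\n",
              x$fps, x$duration_range[1], x$duration_range[2], x$n_tracks))
  invisible(x)
}
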