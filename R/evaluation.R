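#' Mean absolute Pearson correlation between two feature tables
#'
#' Quantifies how well one imaging geometry preserves the flight features of
#' another: segments are paired by their (trial, track, window) key — both
#' tables must come from the same source tracks under a fixed shared
#' segmentation — and for every feature column in the intersection of the two
#' registries the absolute Pearson correlation over paired segments is
#' computed, then averaged over features. Constant features are excluded
#' with a message.
#'
#' @param bundle_a,bundle_b Segment feature tibbles ([segment_features()])
#'   sharing row keys.
#' @return A scalar in \[0, 1\], with the per-feature correlations in
#'   attribute `per_feature`.
#' @export
mean_abs_feature_correlation <- function(bundle_a, bundle_b) {
  key <- function(t) paste(t$trial_id, t$track_id, t$window_id, sep = "\x1f")
  ka <- key(bundle_a)
  kb <- key(bundle_b)
  common <- intersect(ka, kb)
  if (length(common) < 3) abort("Fewer than 3 paired segments.")
  a <- bundle_a[match(common, ka), ]
  b <- bundle_b[match(common, kb), ]
  feats <- intersect(feature_cols(bundle_a), feature_cols(bundle_b))
  if (length(feats) == 0) abort("No shared feature columns.")

  r <- vapply(feats, function(f) {
    x <- a[[f]]; y <- b[[f]]
    if (var(x) == 0 || var(y) == 0) return(NA_real_)
    abs(cor(x, y))
  }, numeric(1))
  dropped <- names(r)[is.na(r)]
  if (length(dropped) > 0) {
    inform(paste0("mean_abs_feature_correlation: excluded constant ",
                  "feature(s): ", paste(head(dropped, 8), collapse = ", "),
                  if (length(dropped) > 8) ", ..."))
  }
  structure(mean(r, na.rm = TRUE),
            per_feature = tibble(feature = feats, abs_r = unname(r)))
}

#' Sweep the single-camera distance
#'
#' For each camera distance, projects the source 3D tracks through the
#' single-camera model (with focal-length rescaling so the swarm keeps its
#' image extent) and measures how the resulting feature table compares with
#' the telecentric baseline: the mean absolute feature correlation under a
#' fixed shared segmentation, and optionally the tuned pipeline's
#' cross-validated classification metrics. A telecentric baseline row is
#' always emitted (distance = Inf).
#'
#' @param source_tracks 3D track tibble (the modelling bundle).
#' @param distances Positive sorted camera distances, metres.
#' @param config A [classifier_config()] supplying the fixed window/overlap
#'   for the correlation pairing (and defaults for classification).
#' @param what `"correlation"` (default) and/or `"classification"`.
#' @param tuning_tracks 3D tuning bundle; required when `what` includes
#'   `"classification"` (tuned per distance, as in the study design).
#' @param grid Tuning grid forwarded to [tune()].
#' @param reference_nonmale Non-male reference feature table builder for
#'   cross-validation; if `NULL` it is derived from the tuning couples at
#'   each distance's tuned segmentation.
#' @param max_folds,seed Forwarded to [crossvalidate()].
#' @param min_duration Track duration filter, seconds.
#' @return A tibble with one row per distance plus the telecentric baseline:
#'   `distance_m`, `correlation_to_telecentric`, and (when requested)
#'   `balanced_accuracy`, `roc_auc`, `tuned_window`, `tuned_overlap`.
#' @export
distance_sweep <- function(source_tracks, distances,
                           config = classifier_config(),
                           what = "correlation",
                           tuning_tracks = NULL, grid = NULL,
                           reference_nonmale = NULL,
                           max_folds = 10, seed = 1, min_duration = 3) {
  if (any(distances <= 0)) abort("`distances` must be > 0.")
  if (is.unsorted(distances)) abort("`distances` must be sorted increasing.")
  what <- match.arg(what, c("correlation", "classification"),
                    several.ok = TRUE)
  tracks <- filter_short_tracks(source_tracks, min_duration, quiet = TRUE)
  tele <- project_bundle(tracks, "telecentric")
  tele_feats <- segment_features(tele, config$window, config$overlap)

  run_distance <- function(d, tracks2d, label) {
    row <- tibble(distance_m = d)
    if ("correlation" %in% what) {
      feats <- segment_features(tracks2d, config$window, config$overlap)
      row$correlation_to_telecentric <- if (identical(label, "telecentric")) {
        1
      } else {
        as.numeric(mean_abs_feature_correlation(feats, tele_feats))
      }
    }
    if ("classification" %in% what) {
      if (is.null(tuning_tracks)) {
        abort("`tuning_tracks` is required for classification sweeps.")
      }
      tuning2d <- if (identical(label, "telecentric")) {
        project_bundle(tuning_tracks, "telecentric")
      } else {
        project_bundle(tuning_tracks, "single_camera", distance = d)
      }
      best <- tune(tuning2d, grid = grid, nu = config$nu,
                   alpha = config$alpha, r_max = config$r_max,
                   min_duration = min_duration)
      ref <- reference_nonmale %||% {
        tune_f <- filter_short_tracks(tuning2d, min_duration, quiet = TRUE)
        segs <- segment_features(tune_f, best$window, best$overlap)
        segs[segs$class_name == "couple", ]
      }
      cv <- crossvalidate(tracks2d, best, ref,
                          max_folds = max_folds, seed = seed,
                          min_duration = min_duration)
      rep <- cv$metrics
      row$balanced_accuracy <- rep$value[rep$metric == "balanced_accuracy"]
      row$roc_auc <- rep$value[rep$metric == "roc_auc"]
      row$tuned_window <- best$window
      row$tuned_overlap <- best$overlap
    }
    row
  }

  rows <- purrr::map(distances, function(d) {
    run_distance(d, project_bundle(tracks, "single_camera", distance = d),
                 label = "single")
  })
  baseline <- run_distance(Inf, tele, label = "telecentric")
  bind_rows(rows, list(baseline))
}

#' Low-dimensional embedding of pooled feature tables
#'
#' Embeds standardized feature rows into 2D with a deterministic spectral
#' (Laplacian eigenmap) embedding of the symmetrized k-nearest-neighbour
#' graph: a nonlinear, neighbourhood-preserving map in the same family as
#' UMAP/t-SNE, used to visualise how feature tables from different imaging
#' geometries cluster. Rows from several tables can be pooled; pass a
#' `dataset` label column to track origin.
#'
#' @param feature_tables A segment feature tibble or named list of them
#'   (names become the `dataset` label).
#' @param n_neighbors Neighbourhood size (default 15).
#' @param seed Integer; the embedding is deterministic, the seed only fixes
#'   the (rare) tie-break sign convention.
#' @return A tibble with `dataset`, the provenance columns, and `dim1`,
#'   `dim2`.
#' @export
embed_features <- function(feature_tables, n_neighbors = 15, seed = 1) {
  if (is.data.frame(feature_tables)) {
    feature_tables <- list(pooled = feature_tables)
  }
  feats <- Reduce(intersect, lapply(feature_tables, feature_cols))
  pooled <- purrr::imap(feature_tables, function(t, nm) {
    t |> mutate(dataset = nm)
  }) |> bind_rows()
  x <- as.matrix(pooled[, feats])
  if (nrow(x) < 10) abort("Need at least 10 rows to embed.")
  keep <- apply(x, 2, var) > 0
  if (!any(keep)) abort("Degenerate input: all features constant.")
  x <- scale(x[, keep, drop = FALSE])

  n <- nrow(x)
  k <- min(n_neighbors, n - 1)
  d2 <- outer(rowSums(x^2), rowSums(x^2), `+`) - 2 * tcrossprod(x)
  d2[d2 < 0] <- 0
  # symmetrized kNN adjacency with Gaussian weights at the local scale
  w <- matrix(0, n, n)
  sigma2 <- numeric(n)
  for (i in seq_len(n)) {
    ord <- order(d2[i, ])
    nb <- ord[ord != i][seq_len(k)]
    sigma2[i] <- max(d2[i, nb[k]], 1e-12)
    w[i, nb] <- exp(-d2[i, nb] / sigma2[i])
  }
  w <- pmax(w, t(w))
  deg <- rowSums(w)
  deg[deg == 0] <- 1
  # symmetric normalized Laplacian; bottom non-trivial eigenvectors
  s <- 1 / sqrt(deg)
  lap <- diag(n) - (s * w) %*% diag(s)
  eig <- eigen((lap + t(lap)) / 2, symmetric = TRUE)
  idx <- order(eig$values)[2:3]
  coords <- eig$vectors[, idx, drop = FALSE] * s
  # deterministic sign convention: largest-magnitude loading positive
  for (j in 1:2) {
    pivot <- which.max(abs(coords[, j]))
    if (coords[pivot, j] < 0) coords[, j] <- -coords[, j]
  }
  pooled |>
    select(dplyr::any_of(c("dataset", provenance_cols()))) |>
    mutate(dim1 = coords[, 1], dim2 = coords[, 2])
}
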