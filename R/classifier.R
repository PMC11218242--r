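#' Classifier configuration
#'
#' Bundles the tunable parameters of the one-class segment-voting framework:
#' the segmentation window and overlap, the RBF kernel width multiplier, the
#' Mann-Whitney selection level and the correlation pruning threshold. The
#' regularisation parameter `nu` is fixed at 0.2 by default — strong
#' regularisation that tolerates large errors on the male class (the only
#' class seen in training) to limit overfitting.
#'
#' @param nu In (0, 1].
#' @param window Segment length, seconds.
#' @param overlap Overlap fraction in \[0, 0.9\].
#' @param gamma_mult RBF width multiplier on the median-heuristic gamma.
#' @param alpha Mann-Whitney selection level.
#' @param r_max Correlation pruning threshold.
#' @return A `classifier_config` list.
#' @export
classifier_config <- function(nu = 0.2, window = 1, overlap = 0.5,
                              gamma_mult = 1, alpha = 0.05, r_max = 0.9) {
  if (nu <= 0 || nu > 1) abort("`nu` must lie in (0, 1].")
  if (overlap < 0 || overlap > 0.9) abort("`overlap` must lie in [0, 0.9].")
  if (window <= 0) abort("`window` must be > 0.")
  structure(list(nu = nu, window = window, overlap = overlap,
                 gamma_mult = gamma_mult, alpha = alpha, r_max = r_max),
            class = "classifier_config")
}

#' Select discriminative, non-redundant features
#'
#' Per feature, a two-sided Mann-Whitney U test compares male training
#' segments against reference non-male segments; features with p < `alpha`
#' are kept. Kept features are then ordered by ascending p-value and greedily
#' pruned: a feature is dropped if its absolute Pearson correlation (on the
#' pooled rows) with an already-retained feature exceeds `r_max`. The result
#' is deterministic given the input tables. Zero-variance features are
#' dropped up front.
#'
#' @param train_table Segment feature tibble of male training segments.
#' @param reference_nonmale_table Segment feature tibble of non-male
#'   reference segments.
#' @param alpha Selection level (default 0.05).
#' @param r_max Pruning threshold (default 0.9).
#' @return Character vector of selected feature names, with the per-feature
#'   test table in attribute `tests`.
#' @export
select_features <- function(train_table, reference_nonmale_table,
                            alpha = 0.05, r_max = 0.9) {
  feats <- intersect(feature_cols(train_table),
                     feature_cols(reference_nonmale_table))
  if (length(feats) == 0) abort("No shared feature columns.")
  if (nrow(train_table) < 5 || nrow(reference_nonmale_table) < 5) {
    abort("Need at least 5 segments per side for selection.")
  }
  a <- as.matrix(train_table[, feats])
  b <- as.matrix(reference_nonmale_table[, feats])

  const <- vapply(feats, function(f) {
    var(c(a[, f], b[, f])) == 0
  }, logical(1))
  if (any(const)) {
    inform(paste0("select_features: dropping zero-variance feature(s): ",
                  paste(feats[const], collapse = ", ")))
  }
  feats <- feats[!const]

  p <- vapply(feats, function(f) {
    suppressWarnings(wilcox.test(a[, f], b[, f], exact = FALSE)$p.value)
  }, numeric(1))
  kept <- feats[!is.na(p) & p < alpha]
  kept <- kept[order(p[kept])]

  pooled <- rbind(a, b)
  retained <- character(0)
  for (f in kept) {
    if (length(retained) == 0) {
      retained <- f
      next
    }
    r <- suppressWarnings(abs(cor(pooled[, f], pooled[, retained])))
    if (all(is.na(r) | r <= r_max)) retained <- c(retained, f)
  }
  structure(retained,
            tests = tibble(feature = feats, p_value = unname(p),
                           selected = feats %in% retained))
}

# robust per-feature scaler: centre = median, scale = IQR (unit scale where
# IQR is 0). Fit on training male segments only.
robust_scaler <- function(x) {
  centre <- apply(x, 2, median)
  scale <- apply(x, 2, function(col) {
    s <- unname(diff(quantile(col, c(0.25, 0.75))))
    if (s == 0) 1 else s
  })
  list(centre = centre, scale = scale)
}

apply_scaler <- function(x, scaler) {
  sweep(sweep(as.matrix(x), 2, scaler$centre), 2, scaler$scale, "/")
}

#' Fit the one-class track model
#'
#' Standardizes the selected features with a robust scaler (median/IQR,
#' fitted on the male training segments only — heavy-tailed non-male
#' kinematics would distort a mean/sd scaler) and trains a nu one-class SVM
#' with RBF kernel on the standardized male segments.
#'
#' @param train_table Segment feature tibble of male training segments.
#' @param features Character vector of feature columns to use (e.g. from
#'   [select_features()]).
#' @param config A [classifier_config()].
#' @return An object of class `oc_track_model`: the scaler, the selected
#'   features, and the underlying [oc_svm()].
#' @export
fit_one_class <- function(train_table, features, config = classifier_config()) {
  if (nrow(train_table) < 10) {
    abort("Need at least 10 training segments to fit the one-class model.")
  }
  if (length(features) == 0) abort("`features` is empty.")
  if (nrow(train_table) < length(features)) {
    warn("Fewer training segments than features; the fit may be unstable.")
  }
  x <- as.matrix(train_table[, features])
  scaler <- robust_scaler(x)
  xs <- apply_scaler(x, scaler)
  svm <- oc_svm(xs, nu = config$nu, gamma_mult = config$gamma_mult)
  structure(
    list(svm = svm, scaler = scaler, features = features, config = config),
    class = "oc_track_model"
  )
}

# segment-level decision scores for a feature table
segment_scores <- function(model, table) {
  missing <- setdiff(model$features, names(table))
  if (length(missing) > 0) {
    abort(paste0("Feature table lacks model feature(s): ",
                 paste(missing, collapse = ", ")))
  }
  xs <- apply_scaler(as.matrix(table[, model$features]), model$scaler)
  predict(model$svm, xs, type = "score")
}

#' Track-level predictions by segment voting
#'
#' Scores every segment with the one-class model, then votes within each
#' track: a track is labelled male iff strictly more than half its segments
#' are inliers (decision score >= 0). Ties are labelled non-male — equivocal
#' evidence fails membership in the single trained class. The mean signed
#' decision score per track is retained for ROC analysis.
#'
#' @param model An [fit_one_class()] model.
#' @param segment_table Segment feature tibble of the tracks to predict.
#' @return One row per track: `trial_id`, `track_id`, `class_name`,
#'   `n_segments`, `vote_fraction`, `mean_score`, `predicted`
#'   (`"male"`/`"nonmale"`).
#' @export
predict_tracks <- function(model, segment_table) {
  if (nrow(segment_table) == 0) abort("No segments to predict.")
  segment_table$..score <- segment_scores(model, segment_table)
  segment_table |>
    group_by(.data$trial_id, .data$track_id, .data$class_name) |>
    summarise(
      n_segments = dplyr::n(),
      vote_fraction = mean(.data$..score >= 0),
      mean_score = mean(.data$..score),
      .groups = "drop"
    ) |>
    mutate(predicted = ifelse(.data$vote_fraction > 0.5, "male", "nonmale"))
}

#' Performance metrics for track-level predictions
#'
#' Computes, per fold and pooled: per-class accuracy (the recall of each true
#' class), balanced accuracy (mean of male and non-male recall, where all
#' non-male classes are pooled), ROC AUC from the mean track decision scores
#' with male as the positive label, and F1/precision/recall under both
#' positive-class conventions plus their average. The 95% interval is the
#' 2.5/97.5 percentile across folds.
#'
#' @param fold_results Tibble of track predictions with a `fold` column (as
#'   returned by [crossvalidate()]), or a single fold without one.
#' @return A `metrics_report` tibble: `metric`, `value` (mean across folds),
#'   `lo`, `hi` (95% percentile interval across folds).
#' @export
compute_metrics <- function(fold_results) {
  if (nrow(fold_results) == 0) abort("No predictions to score.")
  if (!"fold" %in% names(fold_results)) fold_results$fold <- 1L
  per_fold <- fold_results |>
    group_by(.data$fold) |>
    dplyr::group_modify(~ fold_metric_row(.x)) |>
    ungroup()
  metrics <- setdiff(names(per_fold), "fold")
  report <- purrr::map_dfr(metrics, function(m) {
    v <- per_fold[[m]]
    tibble(
      metric = m,
      value = mean(v, na.rm = TRUE),
      lo = unname(quantile(v, 0.025, na.rm = TRUE)),
      hi = unname(quantile(v, 0.975, na.rm = TRUE))
    )
  })
  structure(report, class = c("metrics_report", class(report)),
            per_fold = per_fold)
}

fold_metric_row <- function(df) {
  truth_male <- df$class_name == "male"
  pred_male <- df$predicted == "male"

  class_acc <- function(cls) {
    sel <- df$class_name == cls
    if (!any(sel)) return(NA_real_)
    correct <- ifelse(truth_male[sel], pred_male[sel], !pred_male[sel])
    mean(correct)
  }
  recall_male <- if (any(truth_male)) mean(pred_male[truth_male]) else NA_real_
  recall_nonmale <- if (any(!truth_male)) mean(!pred_male[!truth_male]) else NA_real_

  prf <- function(truth_pos, pred_pos) {
    tp <- sum(truth_pos & pred_pos)
    precision <- if (sum(pred_pos) > 0) tp / sum(pred_pos) else NA_real_
    recall <- if (sum(truth_pos) > 0) tp / sum(truth_pos) else NA_real_
    f1 <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0) {
      2 * precision * recall / (precision + recall)
    } else {
      NA_real_
    }
    c(precision = precision, recall = recall, f1 = f1)
  }
  m <- prf(truth_male, pred_male)
  nm <- prf(!truth_male, !pred_male)

  auc <- roc_auc(truth_male, df$mean_score)

  tibble(
    accuracy_male = class_acc("male"),
    accuracy_couple = class_acc("couple"),
    accuracy_female = class_acc("female"),
    accuracy_focal_male = class_acc("focal_male"),
    balanced_accuracy = mean(c(recall_male, recall_nonmale)),
    roc_auc = auc,
    f1_average = mean(c(m["f1"], nm["f1"])),
    f1_male = unname(m["f1"]),
    f1_nonmale = unname(nm["f1"]),
    recall_average = mean(c(m["recall"], nm["recall"])),
    recall_male = unname(m["recall"]),
    recall_nonmale = unname(nm["recall"]),
    precision_average = mean(c(m["precision"], nm["precision"])),
    precision_male = unname(m["precision"]),
    precision_nonmale = unname(nm["precision"])
  )
}

# ROC AUC by the Mann-Whitney identity (ties counted half). NA when the
# test set is single-class: undefined, flagged rather than fabricated.
roc_auc <- function(truth_pos, score) {
  n_pos <- sum(truth_pos)
  n_neg <- sum(!truth_pos)
  if (n_pos == 0 || n_neg == 0) return(NA_real_)
  r <- rank(score)
  (sum(r[truth_pos]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Trial-held-out cross-validation of the segment-voting classifier
#'
#' Folds enumerate combinations of two held-out male trials (all `C(n, 2)`
#' combinations by default, subsampled with `seed` when more than `max_folds`).
#' In each fold the model is trained on the male segments of the remaining
#' male trials — feature selection against the non-male reference table,
#' robust standardization and SVM fit all use training data only — and tested
#' on the held-out male tracks plus every non-male track in the modelling
#' bundle.
#'
#' @param modelling_tracks 3D or 2D track tibble of the modelling set (male
#'   trials plus non-male test classes), already duration-filtered or not
#'   (tracks shorter than 3 s are removed here).
#' @param config A [classifier_config()].
#' @param reference_nonmale Segment feature table used as the non-male side
#'   of the Mann-Whitney selection; by convention the tuning-set couples
#'   (pass e.g. `segment_features(filter_short_tracks(tuning), ...)` of the
#'   couple rows). Required.
#' @param max_folds Fold cap (default 30); combinations beyond this are
#'   subsampled deterministically with `seed`.
#' @param seed Integer seed for the fold subsample.
#' @param min_duration Track duration filter, seconds (default 3).
#' @return An `oc_cv` list: `folds` (per-track predictions with `fold`),
#'   `metrics` (a [compute_metrics()] report), `fold_trials` (held-out trial
#'   ids per fold), and `config`.
#' @export
crossvalidate <- function(modelling_tracks, config, reference_nonmale,
                          max_folds = 30, seed = 1, min_duration = 3) {
  stopifnot(inherits(config, "classifier_config"))
  tracks <- filter_short_tracks(modelling_tracks, min_duration, quiet = TRUE)
  segs <- segment_features(tracks, config$window, config$overlap)
  male_trials <- sort(unique(segs$trial_id[segs$class_name == "male"]))
  if (length(male_trials) < 3) {
    abort("Cross-validation needs at least 3 male trials.")
  }
  combos <- combn(male_trials, 2, simplify = FALSE)
  if (length(combos) > max_folds) {
    pick <- with_local_seed(derive_seed(seed, "cv-folds"), {
      sample(seq_along(combos), max_folds)
    })
    combos <- combos[sort(pick)]
  }

  nonmale_segs <- segs[segs$class_name != "male", ]
  fold_rows <- purrr::imap(combos, function(held_out, k) {
    train <- segs[segs$class_name == "male" &
                    !segs$trial_id %in% held_out, ]
    test <- bind_rows(
      segs[segs$class_name == "male" & segs$trial_id %in% held_out, ],
      nonmale_segs
    )
    if (any(unique(train$trial_id) %in% unique(test$trial_id))) {
      abort("Internal error: a trial appears in both training and testing.")
    }
    sel <- select_features(train, reference_nonmale,
                           alpha = config$alpha, r_max = config$r_max)
    if (length(sel) == 0) {
      # no feature separates the classes at this alpha; fall back to the
      # full registry so the fold still produces predictions
      sel <- feature_cols(train)
    }
    model <- fit_one_class(train, sel, config)
    predict_tracks(model, test) |>
      mutate(fold = k,
             held_out = paste(held_out, collapse = "+"))
  })
  folds <- bind_rows(fold_rows)
  structure(
    list(
      folds = folds,
      metrics = compute_metrics(folds),
      fold_trials = purrr::map_chr(combos, paste, collapse = "+"),
      config = config
    ),
    class = "oc_cv"
  )
}

#' Grid-search tuning on the independent tuning set
#'
#' Exhaustive search over segmentation window, overlap and kernel width
#' (`nu` stays fixed) maximizing cross-validated balanced accuracy on the
#' tuning bundle (3 male + 2 couple trials; folds hold out one male trial at
#' a time). Ties break deterministically to the smallest window, then the
#' smallest overlap, then the smallest `gamma_mult`.
#'
#' @param tuning_tracks 3D or 2D track tibble of the tuning bundle.
#' @param grid Data frame with columns `window`, `overlap`, `gamma_mult`
#'   (a default grid is built with [tuning_grid()] if `NULL`).
#' @param nu Fixed regularisation parameter (default 0.2).
#' @param alpha,r_max Selection parameters passed through.
#' @param min_duration Track duration filter, seconds.
#' @return The best [classifier_config()], with the scored grid in attribute
#'   `scores`.
#' @export
tune <- function(tuning_tracks, grid = NULL, nu = 0.2,
                 alpha = 0.05, r_max = 0.9, min_duration = 3) {
  grid <- grid %||% tuning_grid()
  if (nrow(grid) == 0) abort("Empty tuning grid.")
  tracks <- filter_short_tracks(tuning_tracks, min_duration, quiet = TRUE)
  male_trials <- sort(unique(tracks$trial_id[tracks$class_name == "male"]))
  if (length(male_trials) < 2) {
    abort("Tuning needs at least 2 male trials.")
  }

  scores <- purrr::pmap_dbl(grid, function(window, overlap, gamma_mult, ...) {
    segs <- tryCatch(
      segment_features(tracks, window, overlap),
      error = function(e) NULL
    )
    if (is.null(segs)) return(NA_real_)
    couple_segs <- segs[segs$class_name == "couple", ]
    if (nrow(couple_segs) < 5) return(NA_real_)
    fold_rows <- purrr::imap(male_trials, function(held_out, k) {
      train <- segs[segs$class_name == "male" & segs$trial_id != held_out, ]
      test <- bind_rows(
        segs[segs$class_name == "male" & segs$trial_id == held_out, ],
        couple_segs
      )
      if (nrow(train) < 10) return(NULL)
      cfg <- classifier_config(nu = nu, window = window, overlap = overlap,
                               gamma_mult = gamma_mult,
                               alpha = alpha, r_max = r_max)
      sel <- select_features(train, couple_segs, alpha = alpha, r_max = r_max)
      if (length(sel) == 0) sel <- feature_cols(train)
      model <- fit_one_class(train, sel, cfg)
      predict_tracks(model, test) |> mutate(fold = k)
    })
    folds <- bind_rows(fold_rows)
    if (nrow(folds) == 0) return(NA_real_)
    rep <- compute_metrics(folds)
    rep$value[rep$metric == "balanced_accuracy"]
  })

  scored <- grid |> mutate(balanced_accuracy = scores)
  if (all(is.na(scores))) abort("No grid point produced a valid fit.")
  ranked <- scored |>
    arrange(dplyr::desc(.data$balanced_accuracy), .data$window,
            .data$overlap, .data$gamma_mult)
  best <- ranked[1, ]
  structure(
    classifier_config(nu = nu, window = best$window, overlap = best$overlap,
                      gamma_mult = best$gamma_mult,
                      alpha = alpha, r_max = r_max),
    scores = scored
  )
}

#' Default tuning grid
#'
#' Windows 0.5-3 s in 0.25 s steps, overlaps \{0, 0.25, 0.5, 0.75\}, kernel
#' width multipliers 2^-4..2^2 around the median heuristic. The original
#' study's grid is not public; this default matches its described shape and
#' is configurable.
#'
#' @param windows,overlaps,gamma_mults Grid axes.
#' @return A tibble with one row per grid point.
#' @export
tuning_grid <- function(windows = seq(0.5, 3, by = 0.25),
                        overlaps = c(0, 0.25, 0.5, 0.75),
                        gamma_mults = 2^seq(-4, 2)) {
  tidyr::expand_grid(window = windows, overlap = overlaps,
                     gamma_mult = gamma_mults)
}

#' @importFrom dplyr arrange
NULL
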