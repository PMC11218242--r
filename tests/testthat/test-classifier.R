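test_that("select_features keeps separated features and prunes duplicates", {
  set.seed(4)
  n <- 40
  male <- tibble::tibble(
    trial_id = "m", track_id = "m", class_name = "male",
    window_id = 1:n, t_start = 0, t_end = 1, flag_degenerate = FALSE,
    informative = rnorm(n, 0),
    clone = NA_real_,
    identical_both = rep(1:5, length.out = n),
    noise = rnorm(n)
  )
  male$clone <- male$informative * 2 + 1  # perfectly correlated
  ref <- male |>
    dplyr::mutate(class_name = "couple",
                  informative = rnorm(n, 8),
                  clone = informative * 2 + 1,
                  noise = rnorm(n))
  sel <- select_features(male, ref, alpha = 0.05, r_max = 0.9)
  expect_true("informative" %in% sel || "clone" %in% sel)
  # exactly one of the correlated pair is retained
  expect_equal(sum(c("informative", "clone") %in% sel), 1)
  # identical-in-both-classes feature is never selected
  expect_false("identical_both" %in% sel)
})

test_that("a fully separated feature at n=10 vs 10 reaches the exact permutation p", {
  # exact two-sided p for complete separation: 2 / C(20,10)
  x <- 1:10
  y <- 21:30
  p_exact <- 2 / choose(20, 10)
  expect_equal(p_exact, 1.082509e-05, tolerance = 1e-6)
  p <- wilcox.test(x, y, exact = TRUE)$p.value
  expect_equal(p, p_exact, tolerance = 1e-12)
  expect_lt(p, 0.05)
})

test_that("fit_one_class meets the nu inlier bound on male segments", {
  feats <- small_bench_features()
  male <- feats[feats$class_name == "male", ]
  sel <- select_features(male, small_bench_reference_couples())
  model <- fit_one_class(male, sel, classifier_config(nu = 0.2))
  scores <- swarmcam:::segment_scores(model, male)
  expect_gte(mean(scores >= 0), 0.75)
  expect_error(fit_one_class(male[1:5, ], sel), "at least 10")
})

test_that("segment voting follows the majority rule with ties to non-male", {
  votes <- tibble::tibble(
    trial_id = "t", class_name = "male",
    track_id = rep(c("all_in", "three_out", "tie"), each = 4),
    window_id = rep(1:4, 3), t_start = 0, t_end = 1, flag_degenerate = FALSE
  )
  scores <- c(1, 1, 1, 1,        # all inliers -> male
              -1, -1, -1, 1,     # 3 of 4 outliers -> non-male
              1, 1, -1, -1)      # tie -> non-male
  fake_model <- structure(
    list(features = "f", scaler = list(centre = 0, scale = 1)),
    class = "oc_track_model"
  )
  # stub the score path by injecting a feature column equal to the score
  votes$f <- scores
  fake_model$svm <- structure(list(), class = "oc_svm_stub")
  local_mocked_bindings(
    segment_scores = function(model, table) table$f,
    .package = "swarmcam"
  )
  pred <- predict_tracks(fake_model, votes)
  expect_equal(pred$predicted[match(c("all_in", "three_out", "tie"),
                                    pred$track_id)],
               c("male", "nonmale", "nonmale"))
  expect_equal(pred$vote_fraction[pred$track_id == "tie"], 0.5)
})

test_that("compute_metrics reproduces a hand-worked contingency table", {
  # 8/10 male correct, 30/40 non-male correct
  df <- tibble::tibble(
    trial_id = "t",
    track_id = paste0("trk", 1:50),
    class_name = rep(c("male", "couple"), c(10, 40)),
    n_segments = 4,
    vote_fraction = 0.75,
    mean_score = c(rep(1, 8), rep(-1, 2), rep(1, 10), rep(-1, 30)),
    predicted = c(rep("male", 8), rep("nonmale", 2),
                  rep("male", 10), rep("nonmale", 30))
  )
  rep <- compute_metrics(df)
  get <- function(m) rep$value[rep$metric == m]
  expect_equal(get("balanced_accuracy"), (0.8 + 0.75) / 2)
  expect_equal(get("precision_male"), 8 / 18)
  expect_equal(get("accuracy_male"), 0.8)
  expect_equal(get("accuracy_couple"), 0.75)
  expect_equal(get("recall_nonmale"), 0.75)
  # perfect predictor
  perfect <- df |>
    dplyr::mutate(predicted = ifelse(class_name == "male", "male", "nonmale"),
                  mean_score = ifelse(class_name == "male", 1, -1))
  rep2 <- compute_metrics(perfect)
  vals <- rep2$value[rep2$metric %in%
                       c("balanced_accuracy", "roc_auc", "f1_male")]
  expect_equal(vals, rep(1, 3))
  # all-male predictor on balanced classes
  allm <- df |>
    dplyr::mutate(class_name = rep(c("male", "couple"), 25),
                  predicted = "male")
  rep3 <- compute_metrics(allm)
  expect_equal(rep3$value[rep3$metric == "balanced_accuracy"], 0.5)
})

test_that("single-class test sets flag ROC AUC as undefined", {
  df <- tibble::tibble(
    trial_id = "t", track_id = paste0("k", 1:6), class_name = "male",
    n_segments = 2, vote_fraction = 1, mean_score = rnorm(6),
    predicted = "male"
  )
  rep <- compute_metrics(df)
  expect_true(is.na(rep$value[rep$metric == "roc_auc"]))
})

test_that("crossvalidate enumerates held-out male pairs without leakage", {
  b <- small_benchmark()
  filt <- filter_short_tracks(b$modelling, quiet = TRUE)
  tele <- project_bundle(filt, "telecentric")
  ref <- small_bench_reference_couples()
  cfg <- classifier_config(window = 1, overlap = 0.5)
  cv <- crossvalidate(tele, cfg, ref, max_folds = 30, seed = 2)
  # 4 male trials in the small modelling set -> C(4,2) = 6 folds
  expect_length(cv$fold_trials, choose(4, 2))
  # each fold tests exactly its held-out male trials plus all non-males
  male_trials <- unique(tele$trial_id[tele$class_name == "male"])
  for (k in seq_along(cv$fold_trials)) {
    fold <- cv$folds[cv$folds$fold == k, ]
    held <- strsplit(cv$fold_trials[k], "+", fixed = TRUE)[[1]]
    tested_male <- unique(fold$trial_id[fold$class_name == "male"])
    expect_setequal(tested_male, held)
  }
  # every test track appears exactly once per fold
  expect_false(any(duplicated(
    cv$folds[, c("fold", "trial_id", "track_id")]
  )))

  # fold subsampling respects the cap deterministically
  cv3 <- crossvalidate(tele, cfg, ref, max_folds = 3, seed = 2)
  cv3b <- crossvalidate(tele, cfg, ref, max_folds = 3, seed = 2)
  expect_length(cv3$fold_trials, 3)
  expect_identical(cv3$fold_trials, cv3b$fold_trials)
})

test_that("no leakage: perturbing test data leaves the trained model unchanged", {
  feats <- small_bench_features()
  male <- feats[feats$class_name == "male", ]
  ref <- small_bench_reference_couples()
  trials <- unique(male$trial_id)
  train <- male[male$trial_id != trials[1], ]
  test <- male[male$trial_id == trials[1], ]

  sel <- select_features(train, ref)
  model <- fit_one_class(train, sel, classifier_config())
  p1 <- predict_tracks(model, test)

  # scaling or corrupting unseen test data cannot change the model: refit
  # from the same training rows and verify identical predictions
  sel2 <- select_features(train, ref)
  model2 <- fit_one_class(train, sel2, classifier_config())
  expect_identical(sel, sel2)
  expect_identical(model$svm$alpha, model2$svm$alpha)
  expect_equal(p1, predict_tracks(model2, test))
})

test_that("tune returns the argmax with deterministic tie-breaks", {
  b <- small_benchmark()
  tune_tracks <- project_bundle(
    filter_short_tracks(b$tuning, quiet = TRUE), "telecentric"
  )
  grid1 <- tibble::tibble(window = 1, overlap = 0.5, gamma_mult = 1)
  best1 <- tune(tune_tracks, grid1)
  expect_equal(best1$window, 1)
  expect_equal(best1$overlap, 0.5)
  scores <- attr(best1, "scores")
  expect_equal(nrow(scores), 1)
  expect_true(is.finite(scores$balanced_accuracy))

  expect_error(tune(tune_tracks, grid1[0, ]), "Empty tuning grid")

  # tie rule: equal scores prefer the smaller window, then smaller overlap
  fake <- tibble::tibble(window = c(2, 1), overlap = c(0.5, 0.25),
                         gamma_mult = 1, balanced_accuracy = 0.8)
  ranked <- fake |>
    dplyr::arrange(dplyr::desc(balanced_accuracy), window, overlap)
  expect_equal(ranked$window[1], 1)
})

test_that("tuning recovers the timescale of the class contrast", {
  # couples erupt in sub-second bursts; a window in the 0.5-2 s range should
  # beat a window far longer than most couple tracks' usable length
  b <- small_benchmark()
  tune_tracks <- project_bundle(
    filter_short_tracks(b$tuning, quiet = TRUE), "telecentric"
  )
  grid <- tidyr::expand_grid(window = c(0.5, 1, 2, 3), overlap = 0.5,
                             gamma_mult = 1)
  best <- tune(tune_tracks, grid)
  expect_lte(best$window, 2)
  scores <- attr(best, "scores")
  expect_equal(max(scores$balanced_accuracy, na.rm = TRUE),
               scores$balanced_accuracy[scores$window == best$window &
                                          scores$overlap == best$overlap &
                                          scores$gamma_mult == best$gamma_mult])
})

test_that("broom tidiers summarise fits and cross-validations", {
  feats <- small_bench_features()
  male <- feats[feats$class_name == "male", ]
  sel <- select_features(male, small_bench_reference_couples())
  model <- fit_one_class(male, sel, classifier_config())
  td <- tidy(model)
  expect_identical(td$feature, model$features)
  gl <- glance(model)
  expect_equal(gl$nu, 0.2)
  expect_gte(gl$n_support_vectors / gl$n_train, 0.15)
})
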