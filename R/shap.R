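#' Shapley-value feature attributions for the one-class model
#'
#' Kernel SHAP: for each explained segment, the model's decision score is
#' decomposed into one additive attribution per feature plus a base value
#' (the mean score over the background set), satisfying local accuracy —
#' attributions sum to the score minus the base value — by construction.
#' Absent features in a coalition are replaced by background-sample values
#' and the model output averaged over the background. With up to
#' `exact_limit` features all coalitions are enumerated and the attributions
#' are exact Shapley values; beyond that, coalitions are sampled (paired with
#' their complements) under `seed` with total budget `nsamples`.
#'
#' @param model An `oc_track_model` ([fit_one_class()]), an [oc_svm()], or a
#'   plain function mapping a numeric matrix to scores.
#' @param segments_features Feature tibble or matrix of segments to explain.
#' @param background Feature tibble or matrix of background segments
#'   (>= 20 rows recommended; typically training male segments).
#' @param nsamples Coalition budget when sampling (default
#'   `2 * n_features + 2048`).
#' @param exact_limit Enumerate all coalitions when the feature count is at
#'   most this (default 11).
#' @param seed Integer seed for coalition sampling.
#' @return An `attribution_matrix`: list with `values` (segments x features),
#'   `base_value`, `scores` (model outputs), `data` (feature values), and
#'   `feature_names`.
#' @export
explain <- function(model, segments_features, background,
                    nsamples = NULL, exact_limit = 11, seed = 1) {
  f <- as_score_function(model)
  x <- explain_matrix(segments_features, model)
  bg <- explain_matrix(background, model)
  if (nrow(bg) < 2) abort("`background` needs at least 2 rows.")
  m <- ncol(x)
  if (ncol(bg) != m) abort("Background feature count mismatch with model.")
  nsamples <- nsamples %||% (2 * m + 2048)

  base_value <- mean(f(bg))
  scores <- f(x)

  # coalition matrix z (rows: coalitions, cols: features), excluding the
  # empty and full coalitions which are handled by the constraint
  if (m <= exact_limit) {
    z <- as.matrix(expand.grid(rep(list(c(0, 1)), m)))
    z <- z[rowSums(z) > 0 & rowSums(z) < m, , drop = FALSE]
    sz <- rowSums(z)
    wts <- (m - 1) / (choose(m, sz) * sz * (m - sz))
  } else {
    z <- sample_coalitions(m, nsamples, seed)
    sz <- rowSums(z)
    wts <- (m - 1) / (choose(m, sz) * sz * (m - sz))
  }

  values <- matrix(NA_real_, nrow(x), m,
                   dimnames = list(NULL, colnames(x)))
  nbg <- nrow(bg)
  nz <- nrow(z)
  if (m == 1) {
    values[, 1] <- scores - base_value
  } else {
    # masked inputs: for each coalition, x where z==1, background otherwise;
    # expectation over all background rows. Rows are blocked by coalition.
    big0 <- bg[rep(seq_len(nbg), times = nz), , drop = FALSE]
    zi <- z[rep(seq_len(nz), each = nbg), , drop = FALSE] == 1
    for (i in seq_len(nrow(x))) {
      big <- big0
      xi <- matrix(x[i, ], nrow(big), m, byrow = TRUE)
      big[zi] <- xi[zi]
      fz <- colMeans(matrix(f(big), nrow = nbg))
      values[i, ] <- solve_kernel_shap(z, wts, fz, scores[i], base_value)
    }
  }
  structure(
    list(values = values, base_value = base_value, scores = scores,
         data = x, feature_names = colnames(x)),
    class = "attribution_matrix"
  )
}

as_score_function <- function(model) {
  if (is.function(model)) return(model)
  if (inherits(model, "oc_track_model")) {
    return(function(mat) {
      xs <- apply_scaler(mat, model$scaler)
      predict(model$svm, xs, type = "score")
    })
  }
  if (inherits(model, "oc_svm")) {
    return(function(mat) predict(model, mat, type = "score"))
  }
  abort("`model` must be an oc_track_model, oc_svm, or function.")
}

explain_matrix <- function(tbl, model) {
  if (is.matrix(tbl)) return(tbl)
  cols <- if (inherits(model, "oc_track_model")) {
    model$features
  } else {
    feature_cols(tbl)
  }
  missing <- setdiff(cols, names(tbl))
  if (length(missing) > 0) {
    abort(paste0("Feature count mismatch with model; missing: ",
                 paste(missing, collapse = ", ")))
  }
  as.matrix(tbl[, cols])
}

# Paired coalition sampling: each draw is emitted with its complement so the
# estimator respects the symmetry of the Shapley kernel.
sample_coalitions <- function(m, nsamples, seed) {
  with_local_seed(derive_seed(seed, "shap-coalitions"), {
    half <- ceiling(nsamples / 2)
    sizes <- sample.int(m - 1, half, replace = TRUE,
                        prob = 1 / (seq_len(m - 1) * (m - seq_len(m - 1))))
    rows <- matrix(0L, 2 * half, m)
    for (r in seq_len(half)) {
      on <- sample.int(m, sizes[r])
      rows[2 * r - 1, on] <- 1L
      rows[2 * r, -on] <- 1L
    }
    unique(rows)
  })
}

# Weighted least squares for phi with the local-accuracy constraint
# sum(phi) = fx - base eliminated through the last feature.
solve_kernel_shap <- function(z, wts, fz, fx, base) {
  m <- ncol(z)
  total <- fx - base
  y <- fz - base - z[, m] * total
  zt <- z[, -m, drop = FALSE] - z[, m]
  a <- crossprod(zt * wts, zt)
  b <- crossprod(zt * wts, y)
  phi_head <- tryCatch(
    as.numeric(solve(a, b)),
    error = function(e) as.numeric(qr.coef(qr(a), b))
  )
  phi_head[is.na(phi_head)] <- 0
  c(phi_head, total - sum(phi_head))
}

#' Summary and scatter data from an attribution matrix
#'
#' `attribution_summary()` ranks features by mean absolute attribution (the
#' ordering of a SHAP summary plot). `attribution_scatter()` extracts, for
#' one feature, the per-segment feature value (optionally min-max normalised)
#' and attribution — the data behind a SHAP scatter plot with its feature-
#' value histogram.
#'
#' @param attr An `attribution_matrix` from [explain()].
#' @param feature Feature name for the scatter data.
#' @param normalise Min-max normalise the feature values (default TRUE).
#' @return Tibbles ready for plotting.
#' @export
attribution_summary <- function(attr) {
  stopifnot(inherits(attr, "attribution_matrix"))
  tibble(
    feature = attr$feature_names,
    mean_abs_attribution = colMeans(abs(attr$values))
  ) |> arrange(dplyr::desc(.data$mean_abs_attribution))
}

#' @rdname attribution_summary
#' @export
attribution_scatter <- function(attr, feature, normalise = TRUE) {
  stopifnot(inherits(attr, "attribution_matrix"))
  if (!feature %in% attr$feature_names) {
    abort(sprintf("Unknown feature `%s`.", feature))
  }
  v <- attr$data[, feature]
  if (normalise) {
    rng <- range(v)
    v <- if (diff(rng) == 0) rep(0.5, length(v)) else (v - rng[1]) / diff(rng)
  }
  tibble(
    feature_value = v,
    attribution = attr$values[, feature],
    score = attr$scores
  )
}
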