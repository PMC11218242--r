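#' nu one-class support vector machine
#'
#' A margin-based novelty detector trained on a single class. With an RBF
#' kernel `k(x, y) = exp(-gamma ||x - y||^2)` the model solves the standard
#' dual
#' \deqn{\min_\alpha \tfrac12 \alpha^\top K \alpha \quad
#'       \text{s.t. } 0 \le \alpha_i \le \tfrac{1}{\nu n},\; \sum_i \alpha_i = 1,}
#' giving the decision function \eqn{f(x) = \sum_i \alpha_i k(x_i, x) - \rho}
#' with inliers at \eqn{f(x) \ge 0}. The parameter `nu` is an upper bound on
#' the fraction of training errors and a lower bound on the fraction of
#' support vectors. The solver is a deterministic maximal-violating-pair SMO
#' (sequential minimal optimization) on the precomputed kernel matrix.
#'
#' @param x Numeric matrix of training rows (already standardized).
#' @param nu In (0, 1]; default 0.2.
#' @param gamma RBF kernel precision; `NULL` uses the median heuristic
#'   `1 / (2 * median(pairwise distance)^2)` scaled by `gamma_mult`.
#' @param gamma_mult Multiplier applied to the median-heuristic gamma.
#' @param tol KKT violation tolerance for SMO convergence.
#' @param max_iter Iteration cap (a warning is raised if reached).
#' @return An object of class `oc_svm` with elements `alpha`, `rho`, `sv`
#'   (support-vector matrix), `sv_alpha`, `gamma`, `nu`.
#' @export
oc_svm <- function(x, nu = 0.2, gamma = NULL, gamma_mult = 1,
                   tol = 1e-8, max_iter = 100000L) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < 2) abort("One-class SVM needs at least two training rows.")
  if (!is.numeric(nu) || nu <= 0 || nu > 1) abort("`nu` must lie in (0, 1].")
  assert_finite(x, "x")

  if (is.null(gamma)) {
    gamma <- median_heuristic_gamma(x) * gamma_mult
  }
  K <- rbf_kernel(x, x, gamma)
  C <- 1 / (nu * n)

  # libsvm-style feasible start: the first floor(nu*n) points at the upper
  # bound, the remainder fraction on the next point
  alpha <- numeric(n)
  nfull <- floor(nu * n)
  if (nfull > 0) alpha[seq_len(nfull)] <- C
  if (nfull < n) alpha[nfull + 1] <- 1 - nfull * C

  g <- as.numeric(K %*% alpha)
  eps_a <- C * 1e-12
  iter <- 0L
  repeat {
    iter <- iter + 1L
    up <- alpha < C - eps_a      # can increase
    dn <- alpha > eps_a          # can decrease
    if (!any(up) || !any(dn)) break
    i <- which(up)[which.min(g[up])]
    j <- which(dn)[which.max(g[dn])]
    viol <- g[j] - g[i]
    if (viol < tol || iter > max_iter) break
    eta <- K[i, i] + K[j, j] - 2 * K[i, j]
    delta <- if (eta > 0) viol / eta else C
    delta <- min(delta, C - alpha[i], alpha[j])
    alpha[i] <- alpha[i] + delta
    alpha[j] <- alpha[j] - delta
    g <- g + delta * (K[, i] - K[, j])
  }
  if (iter > max_iter) {
    warn("oc_svm: SMO reached max_iter before meeting the KKT tolerance.")
  }

  free <- alpha > eps_a & alpha < C - eps_a
  rho <- if (any(free)) {
    mean(g[free])
  } else {
    (min(g[alpha >= C - eps_a]) + max(g[alpha <= eps_a])) / 2
  }
  keep <- alpha > eps_a
  structure(
    list(alpha = alpha, rho = rho, sv = x[keep, , drop = FALSE],
         sv_alpha = alpha[keep], gamma = gamma, nu = nu,
         n_train = n, iterations = iter),
    class = "oc_svm"
  )
}

rbf_kernel <- function(a, b, gamma) {
  a <- as.matrix(a); b <- as.matrix(b)
  d2 <- outer(rowSums(a^2), rowSums(b^2), `+`) - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  exp(-gamma * d2)
}

median_heuristic_gamma <- function(x, max_rows = 500L) {
  n <- nrow(x)
  idx <- if (n > max_rows) {
    as.integer(round(seq(1, n, length.out = max_rows)))
  } else {
    seq_len(n)
  }
  xs <- x[idx, , drop = FALSE]
  d2 <- outer(rowSums(xs^2), rowSums(xs^2), `+`) - 2 * tcrossprod(xs)
  d2 <- d2[upper.tri(d2)]
  d2 <- d2[d2 > 0]
  med <- if (length(d2) == 0) 1 else median(d2)
  1 / (2 * med)
}

#' Decision scores and labels from a one-class SVM
#'
#' @param object An [oc_svm()] fit.
#' @param newdata Numeric matrix of rows to score (same columns as training).
#' @param type `"score"` for the signed decision value (>= 0 means inlier)
#'   or `"label"` for logical inlier flags.
#' @param ... Unused.
#' @return Numeric scores or logical labels, one per row of `newdata`.
#' @export
predict.oc_svm <- function(object, newdata, type = c("score", "label"), ...) {
  type <- match.arg(type)
  newdata <- as.matrix(newdata)
  k <- rbf_kernel(newdata, object$sv, object$gamma)
  score <- as.numeric(k %*% object$sv_alpha) - object$rho
  if (type == "score") score else score >= 0
}
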