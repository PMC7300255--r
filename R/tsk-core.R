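#' First-order TSK fuzzy system primitives
#'
#' A first-order Takagi-Sugeno-Kang (TSK) fuzzy classifier consists of K
#' if-then rules. Rule k has a Gaussian antecedent per feature (center
#' c_jk, width delta_jk) and a linear consequent
#' f_k(x) = p_0k + p_1k x_1 + ... + p_dk x_d. The model output is the
#' firing-level-weighted sum of the rule consequents, which is linear in the
#' stacked consequent vector p_g once the input is mapped to the
#' rule-expanded design vector x_g. All estimators in this package therefore
#' reduce to (regularized) linear algebra on the design matrix X_g.
#'
#' @name tsk-core
NULL

#' Fuzzy c-means clustering of the feature rows
#'
#' Thin, seeded wrapper around [e1071::cmeans()] used to place the rule
#' antecedents. Initial centers are K distinct rows drawn under `seed`, so
#' the result is deterministic for a given seed.
#'
#' @param features Numeric matrix (n x d).
#' @param K Number of clusters (fuzzy rules), `1 <= K <= n`.
#' @param fuzzifier Fuzziness exponent m > 1 (default 2).
#' @param seed Integer seed for the center initialization.
#' @param tol Relative convergence tolerance on the objective.
#' @param max_iter Maximum number of iterations.
#' @return List with `membership` (n x K, rows sum to 1) and `centers` (K x d).
#' @examples
#' x <- rbind(matrix(rnorm(20, -5), 10, 2), matrix(rnorm(20, 5), 10, 2))
#' fit <- fit_fcm(x, K = 2, seed = 1)
#' range(rowSums(fit$membership))
#' @export
fit_fcm <- function(features, K, fuzzifier = 2, seed = 1,
                    tol = 1e-5, max_iter = 300L) {
  features <- as_feature_matrix(features)
  n <- nrow(features)
  if (K < 1L) stop("K must be at least 1", call. = FALSE)
  if (n < K) stop("need at least K rows to fit K clusters", call. = FALSE)
  if (fuzzifier <= 1) stop("fuzzifier must exceed 1", call. = FALSE)
  if (K == 1L) {
    return(list(membership = matrix(1, n, 1L),
                centers = matrix(colMeans(features), 1L, ncol(features))))
  }
  uniq <- unique(features)
  if (nrow(uniq) < K) {
    stop("clustering did not converge: fewer than K distinct rows", call. = FALSE)
  }
  # cmeans consumes RNG state internally, so the whole call is seeded
  fit <- with_seed(seed, {
    init <- uniq[sample.int(nrow(uniq), K), , drop = FALSE]
    e1071::cmeans(features, centers = init, iter.max = max_iter,
                  m = fuzzifier, method = "cmeans",
                  control = list(reltol = tol))
  })
  u <- unname(fit$membership)
  if (anyNA(u) || !all(is.finite(u))) {
    stop("clustering did not converge: degenerate memberships", call. = FALSE)
  }
  list(membership = u, centers = unname(fit$centers))
}

#' Estimate Gaussian antecedent parameters from fuzzy memberships
#'
#' Each rule center is the membership-weighted mean of the features and each
#' squared width is `h` times the membership-weighted variance around that
#' center; the width is stored as the square root so that it enters the
#' Gaussian membership function directly. Widths that collapse on (near-)
#' constant features are floored at `1e-6 * max(feature range, 1)`.
#'
#' @param features Numeric matrix (n x d).
#' @param membership Membership matrix (n x K) from [fit_fcm()]; any positive
#'   rescaling gives the same result.
#' @param h Positive width-scale parameter; 0.5 is the conventional default.
#' @return Object of class `tsk_antecedents`: `centers` (K x d), `widths`
#'   (K x d, strictly positive), `h`, `K`, `d`.
#' @examples
#' a <- estimate_antecedents(matrix(c(0, 2), 2, 1), matrix(1, 2, 1), h = 0.5)
#' a$centers   # 1
#' a$widths^2  # 0.5
#' @export
estimate_antecedents <- function(features, membership, h = 0.5) {
  features <- as_feature_matrix(features)
  membership <- as.matrix(membership)
  if (h <= 0) stop("h must be positive", call. = FALSE)
  if (nrow(membership) != nrow(features)) {
    stop("membership and features must have the same number of rows", call. = FALSE)
  }
  tot <- colSums(membership)
  if (any(tot <= 0)) {
    stop("a cluster has zero total membership", call. = FALSE)
  }
  centers <- sweep(crossprod(membership, features), 1L, tot, "/")
  K <- nrow(centers)
  d <- ncol(features)
  widths <- matrix(0, K, d)
  for (k in seq_len(K)) {
    dev2 <- sweep(features, 2L, centers[k, ], "-")^2
    widths[k, ] <- sqrt(h * colSums(membership[, k] * dev2) / tot[k])
  }
  rng <- apply(features, 2L, function(col) diff(range(col)))
  floor_j <- 1e-6 * pmax(rng, 1)
  widths <- sweep(widths, 2L, floor_j, pmax)
  structure(list(centers = centers, widths = widths, h = h, K = K, d = d),
            class = "tsk_antecedents")
}

#' Fit antecedents by fuzzy c-means in one call
#' @inheritParams fit_fcm
#' @inheritParams estimate_antecedents
#' @return A `tsk_antecedents` object.
#' @export
fit_antecedents <- function(features, K, h = 0.5, fuzzifier = 2, seed = 1) {
  fcm <- fit_fcm(features, K = K, fuzzifier = fuzzifier, seed = seed)
  estimate_antecedents(features, fcm$membership, h = h)
}

#' @export
print.tsk_antecedents <- function(x, ...) {
  cat(sprintf("<tsk_antecedents: K = %d rules, d = %d features, h = %g>\n",
              x$K, x$d, x$h))
  invisible(x)
}

# Normalized firing levels for a matrix of inputs, computed in the log
# domain so that points far from every center renormalize cleanly instead of
# underflowing to 0/0.
firing_matrix <- function(features, antecedents) {
  features <- as_feature_matrix(features)
  if (ncol(features) != antecedents$d) {
    stop("feature dimension does not match the antecedent model", call. = FALSE)
  }
  K <- antecedents$K
  n <- nrow(features)
  logmu <- matrix(0, n, K)
  for (k in seq_len(K)) {
    dev2 <- sweep(features, 2L, antecedents$centers[k, ], "-")^2
    logmu[, k] <- -rowSums(sweep(dev2, 2L, 2 * antecedents$widths[k, ]^2, "/"))
  }
  logmu <- logmu - apply(logmu, 1L, max)
  mu <- exp(logmu)
  mu / rowSums(mu)
}

#' Normalized rule firing levels at a single input
#'
#' The firing level of rule k is the product of its per-feature Gaussian
#' memberships, normalized over rules; the returned vector is nonnegative
#' and sums to 1.
#'
#' @param x Numeric vector of length d.
#' @param antecedents A `tsk_antecedents` object.
#' @return Numeric vector of length K summing to 1.
#' @export
firing_levels <- function(x, antecedents) {
  as.numeric(firing_matrix(matrix(x, nrow = 1L), antecedents))
}

#' Map inputs to the rule-expanded design matrix
#'
#' Row i is the concatenation over rules k of
#' `firing_k(x_i) * c(1, x_i)`, giving `K * (d + 1)` columns. On this design
#' matrix the TSK output is linear in the stacked consequent vector.
#'
#' @param features Numeric matrix (n x d).
#' @param antecedents A `tsk_antecedents` object.
#' @return Numeric matrix (n x K(d+1)).
#' @export
map_to_g <- function(features, antecedents) {
  features <- as_feature_matrix(features)
  mu <- firing_matrix(features, antecedents)
  xe <- cbind(1, features)
  K <- antecedents$K
  d1 <- antecedents$d + 1L
  g <- matrix(0, nrow(features), K * d1)
  for (k in seq_len(K)) {
    g[, ((k - 1L) * d1 + 1L):(k * d1)] <- mu[, k] * xe
  }
  g
}

#' TSK model outputs on a design matrix
#'
#' @param g_rows Design matrix from [map_to_g()] (n x K(d+1)).
#' @param p_g Consequent matrix (K(d+1) x C_out); one column per output.
#' @return Numeric matrix (n x C_out) of model outputs.
#' @export
tsk_output <- function(g_rows, p_g) {
  g_rows <- as.matrix(g_rows)
  p_g <- as.matrix(p_g)
  if (ncol(g_rows) != nrow(p_g)) {
    stop("design matrix and consequent dimensions disagree", call. = FALSE)
  }
  g_rows %*% p_g
}

#' Class labels from output scores
#'
#' Argmax over the one-hot output columns; ties are broken toward the lowest
#' class index, so an all-zero score row yields class 1.
#'
#' @param scores Numeric matrix (n x C).
#' @return Integer vector of class labels in `1..C`.
#' @export
scores_to_labels <- function(scores) {
  scores <- as.matrix(scores)
  apply(scores, 1L, which.max)
}

#' Ridge-regularized consequent solver
#'
#' Minimizes `0.5 * ||p||^2 + (eta/2) * sum_i ||p' x_gi - y_i||^2`, the
#' stand-alone TSK training criterion used by the baselines, via the normal
#' equations `(I/eta + Xg'Xg) p = Xg'y`. Well defined for rank-deficient
#' designs because of the ridge term.
#'
#' @param g_rows Design matrix (n x K(d+1)).
#' @param targets Numeric matrix (n x C_out) of regression targets (one-hot
#'   class codes for classification).
#' @param eta Positive error-weight parameter; larger values approach the
#'   unregularized least-squares fit.
#' @return Consequent matrix (K(d+1) x C_out).
#' @export
solve_ridge <- function(g_rows, targets, eta = 100) {
  if (eta <= 0) stop("eta must be positive", call. = FALSE)
  g_rows <- as.matrix(g_rows)
  targets <- as.matrix(targets)
  if (nrow(targets) != nrow(g_rows)) {
    stop("targets must have one row per design row", call. = FALSE)
  }
  p <- ncol(g_rows)
  A <- diag(1 / eta, p) + crossprod(g_rows)
  solve(A, crossprod(g_rows, targets))
}
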