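#' Structural matrices and closed-form solver for transfer training
#'
#' One transfer fit uses N source rows followed by M target-calibration rows
#' (this source-first row ordering is a contract shared by every matrix
#' here). Four structural matrices enter the objective:
#' * Theta — diagonal loss weights, 1 on source rows and omega_t on
#'   calibration rows, emphasizing the scarce target data;
#' * Phi — the marginal maximum-mean-discrepancy (MMD) matrix, whose
#'   quadratic form in the model outputs is the squared gap between mean
#'   source and mean target predictions;
#' * Delta — the class-conditional MMD matrix, the per-class sum of the
#'   analogous quadratic forms;
#' * L — the normalized graph Laplacian of a v-nearest-neighbor cosine
#'   affinity graph over all N + M rows, penalizing output differences
#'   between nearby objects.
#'
#' The transfer objective is
#' `(y - Xg p)' Theta (y - Xg p) + p' Xg' (lambda1 (Phi + Delta) + lambda2 L) Xg p`
#' and is minimized in closed form by [solve_transfer()].
#'
#' @name adaptation
NULL

#' Configuration of the transfer objective
#'
#' @param lambda1 Nonnegative weight of the joint (marginal + conditional)
#'   distribution-adaptation penalty.
#' @param lambda2 Nonnegative weight of the manifold penalty.
#' @param sigma Scale in `(0, 1]` of the calibration loss weight
#'   `omega_t = max(2, sigma * N / M)`.
#' @param v Neighbor count of the affinity graph (>= 1).
#' @param jitter Nonnegative ridge added inside the closed-form inversion,
#'   needed when the system is singular (e.g. `K(d+1) > N + M`). `NULL`
#'   (default) solves unjittered and escalates through
#'   `trace(A)/ncol(A) * c(1e-12, ..., 1e-6)` only if the factorization
#'   fails, so well-posed systems keep an exact stationarity condition.
#' @param seed Integer seed forwarded to seeded internals (antecedent
#'   clustering).
#' @return Object of class `adaptation_config`.
#' @export
adaptation_config <- function(lambda1 = 1, lambda2 = 1, sigma = 0.25,
                              v = 5L, jitter = NULL, seed = 1L) {
  if (lambda1 < 0 || lambda2 < 0) stop("lambda1 and lambda2 must be nonnegative", call. = FALSE)
  if (sigma <= 0 || sigma > 1) stop("sigma must lie in (0, 1]", call. = FALSE)
  if (v < 1L) stop("v must be at least 1", call. = FALSE)
  if (!is.null(jitter) && jitter < 0) stop("jitter must be nonnegative", call. = FALSE)
  structure(list(lambda1 = lambda1, lambda2 = lambda2, sigma = sigma,
                 v = as.integer(v), jitter = jitter, seed = as.integer(seed)),
            class = "adaptation_config")
}

#' Calibration loss weight omega_t
#'
#' `omega_t = max(2, sigma * N / M)`; with no calibration rows (`M = 0`) the
#' weight is 2 by convention (it then multiplies nothing).
#'
#' @param sigma Scale in `(0, 1]`.
#' @param N Number of source rows.
#' @param M Number of target-calibration rows.
#' @return Scalar weight `>= 2`.
#' @export
compute_omega_t <- function(sigma, N, M) {
  if (N < 1 || M < 0 || sigma < 0) stop("invalid omega_t arguments", call. = FALSE)
  if (M == 0) return(2)
  max(2, sigma * N / M)
}

#' Diagonal loss-weight matrix
#' @param N Source row count.
#' @param M Calibration row count.
#' @param omega_t Weight on calibration rows (>= 1).
#' @return Diagonal matrix of size N + M.
#' @export
build_theta <- function(N, M, omega_t) {
  if (omega_t < 1) stop("omega_t must be at least 1", call. = FALSE)
  diag(c(rep(1, N), rep(omega_t, M)), N + M)
}

#' Marginal MMD matrix
#'
#' Equals the outer product `a a'` of the signed indicator
#' `a = (1/N, ..., 1/N, -1/M, ..., -1/M)`, so that
#' `p' Xg' Phi Xg p = (mean source output - mean target output)^2`.
#' With `M = 0` the marginal adaptation is disabled and a zero matrix of
#' size N is returned.
#'
#' @param N Source row count (>= 1).
#' @param M Calibration row count.
#' @return Symmetric PSD matrix of size N + M whose entries sum to 0.
#' @export
build_phi <- function(N, M) {
  if (N < 1) stop("need at least one source row", call. = FALSE)
  if (M == 0) return(matrix(0, N, N))
  a <- c(rep(1 / N, N), rep(-1 / M, M))
  tcrossprod(a)
}

#' Class-conditional MMD matrix
#'
#' Sum over classes c of the outer products `a_c a_c'` where `a_c` holds
#' `1/N_c` on source rows of class c, `-1/M_c` on calibration rows of class
#' c and 0 elsewhere. A class absent from either side contributes a zero
#' term (its per-class MMD is undefined and is dropped).
#'
#' @param source_labels Integer labels of the N source rows.
#' @param target_labels Integer labels of the M calibration rows (may be
#'   empty).
#' @param C Class count.
#' @return Symmetric PSD matrix of size N + M.
#' @export
build_delta <- function(source_labels, target_labels, C) {
  if (length(source_labels) == 0L) stop("source labels must be non-empty", call. = FALSE)
  source_labels <- check_labels(source_labels, C)
  target_labels <- if (length(target_labels)) check_labels(target_labels, C) else integer(0)
  n <- length(source_labels) + length(target_labels)
  delta <- matrix(0, n, n)
  for (c in seq_len(C)) {
    sc <- source_labels == c
    tc <- target_labels == c
    Nc <- sum(sc)
    Mc <- sum(tc)
    if (Nc == 0L || Mc == 0L) next
    a <- c(ifelse(sc, 1 / Nc, 0), ifelse(tc, -1 / Mc, 0))
    delta <- delta + tcrossprod(a)
  }
  delta
}

#' Mutual-or-neighbor cosine affinity graph
#'
#' `w_ij = cos(x_i, x_j)` when j is among the v nearest Euclidean neighbors
#' of i or vice versa (hence symmetric), 0 otherwise. Negative cosines are
#' clamped to 0 so the graph is a proper nonnegative affinity and its
#' normalized Laplacian is PSD; the diagonal is 0 and a zero-norm row has
#' cosine 0 with everything.
#'
#' @param features Numeric matrix (rows = objects).
#' @param v Neighbor count, `v < nrow(features)`.
#' @return Symmetric nonnegative matrix with zero diagonal.
#' @export
build_affinity <- function(features, v = 5L) {
  features <- as_feature_matrix(features)
  n <- nrow(features)
  if (v >= n) stop("v must be smaller than the number of objects", call. = FALSE)
  dmat <- as.matrix(stats::dist(features))
  diag(dmat) <- Inf
  nbr <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    nbr[i, order(dmat[i, ])[seq_len(v)]] <- TRUE
  }
  mask <- nbr | t(nbr)
  norms <- sqrt(rowSums(features^2))
  cosine <- tcrossprod(features)
  denom <- tcrossprod(norms)
  cosine <- ifelse(denom > 0, cosine / pmax(denom, .Machine$double.xmin), 0)
  w <- ifelse(mask, pmax(cosine, 0), 0)
  diag(w) <- 0
  (w + t(w)) / 2
}

#' Normalized graph Laplacian
#'
#' `L = I - D^{-1/2} W D^{-1/2}` with degree `d_ii = sum_j w_ij`; an
#' isolated vertex (zero degree) keeps the identity row/column. For a valid
#' nonnegative affinity the result is symmetric PSD with eigenvalues in
#' `[0, 2]`.
#'
#' @param W Symmetric nonnegative affinity matrix.
#' @return Symmetric PSD matrix of the same size.
#' @export
build_laplacian <- function(W) {
  W <- as.matrix(W)
  if (any(W < 0)) stop("affinity matrix must be nonnegative", call. = FALSE)
  deg <- rowSums(W)
  s <- ifelse(deg > 0, 1 / sqrt(deg), 0)
  L <- diag(nrow(W)) - (s %o% s) * W
  (L + t(L)) / 2
}

#' Bundle the four structural matrices for one source + calibration pair
#'
#' @param source `domain_table` of the source domain (N rows).
#' @param target_calib `domain_table` of the calibration rows (M rows) or
#'   `NULL` for the source-only degenerate case.
#' @param config An [adaptation_config()].
#' @param C Class count.
#' @return List with `theta`, `phi`, `delta`, `laplacian`, `omega_t`, `N`, `M`.
#' @export
build_adaptation_matrices <- function(source, target_calib, config, C) {
  N <- nrow(source$features)
  M <- if (is.null(target_calib)) 0L else nrow(target_calib$features)
  omega_t <- compute_omega_t(config$sigma, N, M)
  feats <- if (M > 0) rbind(source$features, target_calib$features) else source$features
  tlab <- if (M > 0) target_calib$labels else integer(0)
  v <- min(config$v, N + M - 1L)
  list(
    theta = build_theta(N, M, omega_t),
    phi = build_phi(N, M),
    delta = if (M > 0) build_delta(source$labels, tlab, C) else matrix(0, N, N),
    laplacian = build_laplacian(build_affinity(feats, v)),
    omega_t = omega_t, N = N, M = M
  )
}

#' Closed-form transfer solver
#'
#' Minimizes the transfer objective (weighted squared loss plus joint-MMD
#' and manifold penalties) over the consequent matrix:
#' `p_g = [Xg'(Theta + lambda1 Phi + lambda1 Delta + lambda2 L) Xg + jitter I]^{-1} Xg' Theta y`.
#' With the default `jitter = NULL` the system is solved exactly and a
#' ridge is introduced only if the factorization reports singularity; if
#' even the largest jitter fails the system is solved by Moore-Penrose
#' pseudo-inverse with a warning.
#'
#' @param g_rows Design matrix over the N + M rows (source rows first).
#' @param targets Encoded label matrix (n x C), e.g. from [encode_labels()].
#' @param mats Structural matrices from [build_adaptation_matrices()] (or a
#'   list with `theta`, `phi`, `delta`, `laplacian`).
#' @param config An [adaptation_config()].
#' @return Consequent matrix (K(d+1) x C).
#' @export
solve_transfer <- function(g_rows, targets, mats, config) {
  g_rows <- as.matrix(g_rows)
  targets <- as.matrix(targets)
  n <- nrow(g_rows)
  stopifnot(nrow(targets) == n, nrow(mats$theta) == n)
  mid <- mats$theta + config$lambda1 * (mats$phi + mats$delta) +
    config$lambda2 * mats$laplacian
  A <- crossprod(g_rows, mid %*% g_rows)
  A <- (A + t(A)) / 2
  b <- crossprod(g_rows, mats$theta %*% targets)
  scale <- sum(diag(A)) / ncol(A)
  jits <- if (is.null(config$jitter)) {
    c(0, scale * c(1e-12, 1e-10, 1e-8, 1e-6))
  } else {
    config$jitter
  }
  for (jit in jits) {
    out <- tryCatch(solve(A + diag(jit, ncol(A)), b), error = function(e) NULL)
    if (!is.null(out)) return(out)
  }
  warning("transfer system singular even with jitter; using pseudo-inverse")
  MASS::ginv(A + diag(jits[length(jits)], ncol(A))) %*% b
}

#' Evaluate the transfer objective at a consequent matrix
#'
#' Exposed for diagnostics and optimality checking.
#' @inheritParams solve_transfer
#' @param p_g Consequent matrix.
#' @return Scalar objective value.
#' @export
transfer_objective <- function(p_g, g_rows, targets, mats, config) {
  p_g <- as.matrix(p_g)
  resid <- targets - g_rows %*% p_g
  pen <- config$lambda1 * (mats$phi + mats$delta) + config$lambda2 * mats$laplacian
  out <- g_rows %*% p_g
  sum(resid * (mats$theta %*% resid)) + sum(out * (pen %*% out))
}
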