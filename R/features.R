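#' Band-energy feature extraction from raw EEG segments
#'
#' Three extractors map a raw single-channel segment to six features:
#' a dyadic wavelet decomposition (Daubechies-4), a short-time Fourier
#' transform with equal-width spectral bands, and Gaussian-kernel PCA on the
#' raw sample vectors. Wavelet and STFT features are `log10(band energy +
#' 1e-12)`; energies of real EEG bands span orders of magnitude, and the
#' log compresses them to a scale on which Gaussian antecedents are
#' meaningful. Per-feature standardization against reference (source
#' domain) statistics is provided by [zscore_features()].
#'
#' @name features
NULL

LOG_EPS <- 1e-12

# Daubechies-4 (8-tap) orthonormal scaling filter.
DB4_H <- c(0.230377813308855, 0.714846570552542, 0.630880767929590,
           -0.027983769416984, -0.187034811718881, 0.030841381835987,
           0.032883011666983, -0.010597401784997)
# Quadrature-mirror wavelet filter g_k = (-1)^k h_{L-1-k}.
DB4_G <- rev(DB4_H) * c(1, -1)

# One level of the periodized orthogonal DWT: returns approximation and
# detail coefficients of half length. Orthonormality + circular extension
# conserve energy exactly.
dwt_step <- function(x, h, g) {
  n <- length(x)
  half <- n %/% 2L
  idx <- outer(2L * (seq_len(half) - 1L), seq_along(h) - 1L, "+") %% n + 1L
  xs <- matrix(x[idx], half, length(h))
  list(approx = as.numeric(xs %*% h), detail = as.numeric(xs %*% g))
}

#' Wavelet band-energy features
#'
#' Five levels of the periodized Daubechies-4 wavelet transform split the
#' segment into six dyadic frequency bands (approximation plus five detail
#' levels). The features are the log10 band energies, ordered from the
#' lowest band (feature 1, the depth-5 approximation covering
#' `[0, fs/64]`) to the highest (feature 6, the first detail level covering
#' `[fs/4, fs/2]`). The segment is truncated to the largest multiple of 32
#' samples; pre-log band energies then sum to the truncated signal energy.
#'
#' @param segment Numeric vector of raw samples, length >= 64.
#' @param depth Decomposition depth (default 5, giving 6 bands).
#' @return Numeric vector of `depth + 1` log10 band energies, low to high
#'   frequency.
#' @export
extract_wpd <- function(segment, depth = 5L) {
  segment <- as.numeric(segment)
  if (length(segment) < 2^(depth + 1L)) {
    stop("segment too short for a depth-", depth, " decomposition", call. = FALSE)
  }
  if (!all(is.finite(segment))) stop("segment contains non-finite samples", call. = FALSE)
  n <- (length(segment) %/% 2^depth) * 2^depth
  x <- segment[seq_len(n)]
  energies <- numeric(depth + 1L)
  for (lev in seq_len(depth)) {
    st <- dwt_step(x, DB4_H, DB4_G)
    energies[depth + 2L - lev] <- sum(st$detail^2)
    x <- st$approx
  }
  energies[1L] <- sum(x^2)
  log10(energies + LOG_EPS)
}

#' Short-time Fourier band-energy features
#'
#' Hann-windowed spectrogram (via [signal::specgram()]) with 50% overlap;
#' per-frame power spectra are averaged over time and pooled into six
#' equal-width bands from 0 to the Nyquist frequency. Features are the
#' log10 band powers, low to high frequency.
#'
#' @param segment Numeric vector of raw samples.
#' @param sampling_rate Sampling rate in Hz.
#' @param window Window length in samples (default 256).
#' @param n_bands Number of equal-width bands (default 6).
#' @return Numeric vector of `n_bands` log10 band powers.
#' @export
extract_stft <- function(segment, sampling_rate, window = 256L, n_bands = 6L) {
  segment <- as.numeric(segment)
  if (length(segment) < window) {
    stop("segment shorter than the analysis window", call. = FALSE)
  }
  sp <- signal::specgram(segment, n = window, Fs = sampling_rate,
                         window = signal::hanning(window),
                         overlap = window %/% 2L)
  power <- rowMeans(Mod(sp$S)^2)
  edges <- seq(0, sampling_rate / 2, length.out = n_bands + 1L)
  band <- pmin(findInterval(sp$f, edges, rightmost.closed = TRUE), n_bands)
  e <- vapply(seq_len(n_bands), function(b) sum(power[band == b]), numeric(1))
  log10(e + LOG_EPS)
}

#' Gaussian-kernel PCA features
#'
#' Fits kernel PCA (via [kernlab::kpca()]) with the Gaussian kernel
#' `exp(-gamma * ||x - y||^2)` on the raw sample vectors and projects onto
#' the top `n_comp` eigenvectors of the double-centered kernel matrix.
#' `gamma` defaults to the median heuristic `1 / median(||x_i - x_j||^2)`.
#' Components whose eigenvalue is below `1e-10 * max eigenvalue` are
#' dropped with a warning.
#'
#' @param segments Numeric matrix, one raw segment per row; at least
#'   `n_comp + 1` rows.
#' @param gamma Gaussian kernel width; `NULL` for the median heuristic.
#' @param n_comp Number of components (default 6).
#' @return Object of class `kpca_features` with `model` (the kernlab fit),
#'   `gamma`, `eigenvalues` (descending) and `projection` (training rows x
#'   kept components).
#' @export
fit_kpca <- function(segments, gamma = NULL, n_comp = 6L) {
  segments <- as_feature_matrix(segments)
  if (nrow(segments) < n_comp + 1L) {
    stop("need at least ", n_comp + 1L, " segments to extract ", n_comp,
         " components", call. = FALSE)
  }
  if (is.null(gamma)) {
    med <- stats::median(stats::dist(segments)^2)
    gamma <- 1 / max(med, .Machine$double.eps)
  }
  model <- kernlab::kpca(segments, kernel = "rbfdot",
                         kpar = list(sigma = gamma), features = n_comp)
  ev <- kernlab::eig(model)
  keep <- ev > 1e-10 * max(ev)
  if (!all(keep)) {
    warning(sum(!keep), " near-zero-eigenvalue component(s) dropped")
  }
  structure(list(model = model, gamma = gamma,
                 eigenvalues = unname(ev[keep]),
                 projection = unname(kernlab::rotated(model)[, keep, drop = FALSE])),
            class = "kpca_features")
}

#' Project segments with a fitted kernel PCA model
#' @param model A `kpca_features` object.
#' @param segments Numeric matrix of raw segments (rows).
#' @return Numeric matrix (rows x kept components).
#' @export
transform_kpca <- function(model, segments) {
  segments <- as_feature_matrix(segments)
  proj <- kernlab::predict(model$model, segments)
  unname(proj[, seq_along(model$eigenvalues), drop = FALSE])
}

#' Extract a feature matrix from a set of segments
#'
#' Convenience wrapper applying one extractor to every row of a segment
#' matrix. For `method = "kpca"` the model is fit on the segments
#' themselves (or supply a fitted model via `kpca_model` to project new
#' segments consistently).
#'
#' @param segments Numeric matrix, one segment per row.
#' @param method `"wpd"`, `"stft"` or `"kpca"`.
#' @param sampling_rate Required for `"stft"`.
#' @param kpca_model Optional fitted `kpca_features` for `"kpca"`.
#' @param ... Passed to the extractor.
#' @return Numeric feature matrix (one row per segment).
#' @export
extract_features <- function(segments, method = c("wpd", "stft", "kpca"),
                             sampling_rate = NULL, kpca_model = NULL, ...) {
  method <- match.arg(method)
  segments <- as_feature_matrix(segments)
  switch(method,
    wpd = t(apply(segments, 1L, extract_wpd, ...)),
    stft = {
      if (is.null(sampling_rate)) stop("sampling_rate required for stft", call. = FALSE)
      t(apply(segments, 1L, extract_stft, sampling_rate = sampling_rate, ...))
    },
    kpca = {
      if (is.null(kpca_model)) kpca_model <- fit_kpca(segments, ...)
      transform_kpca(kpca_model, segments)
    }
  )
}

#' Standardize features against reference statistics
#'
#' Centers and scales each feature column by the mean and standard
#' deviation of a reference matrix (typically the pooled source domains),
#' so source and target features share one scale. Zero-variance reference
#' columns are left unscaled.
#'
#' @param x Feature matrix to standardize.
#' @param reference Matrix supplying the per-column statistics (default `x`).
#' @return Standardized matrix of the same shape as `x`.
#' @export
zscore_features <- function(x, reference = x) {
  x <- as_feature_matrix(x)
  reference <- as_feature_matrix(reference)
  mu <- colMeans(reference)
  sdv <- apply(reference, 2L, stats::sd)
  sdv[!is.finite(sdv) | sdv == 0] <- 1
  sweep(sweep(x, 2L, mu, "-"), 2L, sdv, "/")
}
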