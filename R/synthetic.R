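#' Synthetic multi-domain data with controllable distribution shift
#'
#' The generator emulates the two transfer hypotheses the method is built
#' for: a marginal shift (all target objects translated relative to the
#' sources, P_s(x) != P_t(x)) and a conditional shift (class-dependent
#' translation, P_s(y|x) != P_t(y|x)). Class-conditional distributions are
#' Gaussian, so class means, maximum-mean-discrepancy terms and domain
#' distances all have closed-form expectations, which is what makes
#' oracle-style testing of the transfer machinery possible. It also
#' produces raw oscillatory EEG-like segments with class-dependent dominant
#' frequency bands for exercising the feature extractors.
#'
#' @name synthetic-data
NULL

#' Specification of a synthetic multi-domain scenario
#'
#' Scalars for `marginal_shift` and `conditional_shift` are expanded to
#' vectors of that Euclidean norm: the marginal shift points along the
#' leading class-discriminant direction (the difference of the first two
#' base class means), so that the target cloud is displaced where it
#' matters for a classifier trained on the sources; the class-c conditional
#' shift points along feature axis `min(c, d)` with alternating sign, so
#' different classes are displaced differently (changing P(y|x), not just
#' P(x)).
#'
#' @param d Feature dimension (default 6).
#' @param C Class count (default 2).
#' @param Z Number of source domains (default 5).
#' @param n_per_class Objects per class per domain (default 100, the size
#'   of one Bonn-style recording group).
#' @param marginal_shift Norm of the target translation (default 1), or a
#'   length-d vector.
#' @param conditional_shift Norm of each class-dependent target translation
#'   (default 0.5), or a list of length-d vectors (one per class).
#' @param noise_sd Class-conditional standard deviation (default 1).
#' @param class_sep Base class-mean separation scale: class c sits at
#'   `class_sep` on feature axis `min(c, d)` (default 2).
#' @param domain_jitter_sd Standard deviation of the per-domain, per-class
#'   mean offsets of the sources; scalar or length-Z vector (default 0.2).
#' @param seed Integer seed.
#' @return Object of class `shift_spec`.
#' @export
shift_spec <- function(d = 6L, C = 2L, Z = 5L, n_per_class = 100L,
                       marginal_shift = 1, conditional_shift = 0.5,
                       noise_sd = 1, class_sep = 2,
                       domain_jitter_sd = 0.2, seed = 1L) {
  if (noise_sd <= 0) stop("noise_sd must be positive", call. = FALSE)
  if (n_per_class < 2L) stop("need at least 2 objects per class", call. = FALSE)
  if (length(marginal_shift) == 1L) {
    if (C >= 2L && d >= 2L) {
      dir <- numeric(d)
      dir[1L] <- 1
      dir[2L] <- -1
      marginal_shift <- marginal_shift * dir / sqrt(2)
    } else {
      marginal_shift <- rep(marginal_shift / sqrt(d), d)
    }
  }
  stopifnot(length(marginal_shift) == d)
  if (!is.list(conditional_shift)) {
    stopifnot(length(conditional_shift) == 1L)
    norm_c <- conditional_shift
    conditional_shift <- lapply(seq_len(C), function(c) {
      v <- numeric(d)
      v[min(c, d)] <- norm_c * (-1)^c
      v
    })
  }
  stopifnot(length(conditional_shift) == C)
  if (length(domain_jitter_sd) == 1L) domain_jitter_sd <- rep(domain_jitter_sd, Z)
  stopifnot(length(domain_jitter_sd) == Z)
  structure(list(d = as.integer(d), C = as.integer(C), Z = as.integer(Z),
                 n_per_class = as.integer(n_per_class),
                 marginal_shift = marginal_shift,
                 conditional_shift = conditional_shift,
                 noise_sd = noise_sd, class_sep = class_sep,
                 domain_jitter_sd = domain_jitter_sd,
                 seed = as.integer(seed)),
            class = "shift_spec")
}

base_class_means <- function(spec) {
  m <- matrix(0, spec$C, spec$d)
  for (c in seq_len(spec$C)) m[c, min(c, spec$d)] <- spec$class_sep
  m
}

sample_class_block <- function(mean_vec, n, sd) {
  matrix(stats::rnorm(n * length(mean_vec), sd = sd), n, length(mean_vec)) +
    matrix(mean_vec, n, length(mean_vec), byrow = TRUE)
}

#' Generate shifted source and target domain tables
#'
#' Class c of source z is Gaussian around the base class mean plus a
#' per-domain jitter offset; class c of the target is Gaussian around the
#' base mean plus the marginal and class-conditional shifts. Deterministic
#' for a given `spec$seed`.
#'
#' @param spec A [shift_spec()].
#' @return List with `sources` (list of Z `domain_table`s named
#'   `src1..srcZ`), `target` (`domain_table` `"target"`), and
#'   `true_means` (list of the generating mean vectors).
#' @export
make_domains <- function(spec) {
  stopifnot(inherits(spec, "shift_spec"))
  base <- base_class_means(spec)
  with_seed(spec$seed, {
    sources <- vector("list", spec$Z)
    src_means <- vector("list", spec$Z)
    for (z in seq_len(spec$Z)) {
      offs <- matrix(stats::rnorm(spec$C * spec$d, sd = spec$domain_jitter_sd[z]),
                     spec$C, spec$d)
      means_z <- base + offs
      feats <- do.call(rbind, lapply(seq_len(spec$C), function(c) {
        sample_class_block(means_z[c, ], spec$n_per_class, spec$noise_sd)
      }))
      labels <- rep(seq_len(spec$C), each = spec$n_per_class)
      sources[[z]] <- domain_table(feats, labels, paste0("src", z), C = spec$C)
      src_means[[z]] <- means_z
    }
    tgt_means <- base +
      matrix(spec$marginal_shift, spec$C, spec$d, byrow = TRUE) +
      do.call(rbind, spec$conditional_shift)
    tfeats <- do.call(rbind, lapply(seq_len(spec$C), function(c) {
      sample_class_block(tgt_means[c, ], spec$n_per_class, spec$noise_sd)
    }))
    tlabels <- rep(seq_len(spec$C), each = spec$n_per_class)
    names(sources) <- paste0("src", seq_len(spec$Z))
    list(sources = sources,
         target = domain_table(tfeats, tlabels, "target", C = spec$C),
         true_means = list(sources = src_means, target = tgt_means))
  })
}

#' Generate raw EEG-like segments with a class-dependent dominant band
#'
#' Each segment is a unit-amplitude sinusoid at the center of the class's
#' dyadic frequency band (band `((class_id - 1) mod 6) + 1` of the 6-band
#' wavelet split of `[0, fs/2]`), a weaker second tone in the same band,
#' and white noise — random phases and noise per segment, deterministic for
#' a given seed.
#'
#' @param class_id Integer class code; determines the dominant band.
#' @param n Number of segments.
#' @param length Samples per segment (>= 256, default 1024).
#' @param sampling_rate Sampling rate in Hz (default 173.61, the classic
#'   single-channel epilepsy-recording rate).
#' @param noise_sd White-noise standard deviation (default 0.3).
#' @param seed Integer seed.
#' @return Numeric matrix (n x length), one segment per row, with
#'   attributes `sampling_rate` and `band`.
#' @export
make_eeg_segments <- function(class_id, n, length = 1024L,
                              sampling_rate = 173.61, noise_sd = 0.3,
                              seed = 1L) {
  if (length < 256L) stop("segments must have at least 256 samples", call. = FALSE)
  band <- ((as.integer(class_id) - 1L) %% 6L) + 1L
  # dyadic band edges of the depth-5 wavelet split
  lo <- if (band == 1L) 0 else sampling_rate / 2^(7L - band)
  hi <- sampling_rate / 2^(6L - band)
  f1 <- if (band == 1L) hi / 2 else sqrt(lo * hi)
  f2 <- lo + 0.75 * (hi - lo)
  t <- (seq_len(length) - 1L) / sampling_rate
  segs <- with_seed(seed, {
    out <- matrix(0, n, length)
    for (i in seq_len(n)) {
      ph <- stats::runif(2, 0, 2 * pi)
      out[i, ] <- sin(2 * pi * f1 * t + ph[1]) +
        0.25 * sin(2 * pi * f2 * t + ph[2]) +
        stats::rnorm(length, sd = noise_sd)
    }
    out
  })
  attr(segs, "sampling_rate") <- sampling_rate
  attr(segs, "band") <- band
  segs
}
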