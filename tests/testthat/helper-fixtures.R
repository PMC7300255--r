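# Small fixtures built in code; all seeded.

# Two Gaussian clouds at +/- offset along the first axis.
two_cloud_features <- function(n_per = 10, d = 2, offset = 10, seed = 1) {
  set.seed(seed)
  rbind(matrix(rnorm(n_per * d), n_per, d) - offset,
        matrix(rnorm(n_per * d), n_per, d) + offset)
}

# A linearly separable two-class domain table.
separable_domain <- function(n_per = 20, d = 3, sep = 6, id = "toy", seed = 1) {
  set.seed(seed)
  feats <- rbind(matrix(rnorm(n_per * d), n_per, d),
                 matrix(rnorm(n_per * d), n_per, d) + sep)
  domain_table(feats, rep(1:2, each = n_per), id, C = 2)
}

# A random source + target pair with consistent labels for solver tests.
random_transfer_instance <- function(N, M, d, K, C = 2, seed = 1,
                                     lambda1 = runif(1, 0, 2),
                                     lambda2 = runif(1, 0, 2)) {
  set.seed(seed)
  src_lab <- sample(seq_len(C), N, replace = TRUE)
  src_lab[seq_len(C)] <- seq_len(C)   # every class present
  src <- domain_table(matrix(rnorm(N * d), N, d), src_lab, "src", C = C)
  tgt <- domain_table(matrix(rnorm(M * d), M, d),
                      sample(seq_len(C), M, replace = TRUE), "tgt", C = C)
  cfg <- adaptation_config(lambda1 = lambda1, lambda2 = lambda2, seed = seed)
  pooled <- rbind(src$features, tgt$features)
  ant <- fit_antecedents(pooled, K = K, seed = seed)
  g <- map_to_g(pooled, ant)
  mats <- build_adaptation_matrices(src, tgt, cfg, C)
  y <- encode_labels(c(src$labels, tgt$labels), C)
  list(src = src, tgt = tgt, cfg = cfg, g = g, mats = mats, y = y)
}

# Central finite-difference gradient of the transfer objective.
fd_gradient <- function(p, g, y, mats, cfg, h = 1e-5) {
  gr <- matrix(0, nrow(p), ncol(p))
  for (i in seq_len(nrow(p))) {
    for (j in seq_len(ncol(p))) {
      pp <- p; pp[i, j] <- pp[i, j] + h
      pm <- p; pm[i, j] <- pm[i, j] - h
      gr[i, j] <- (transfer_objective(pp, g, y, mats, cfg) -
                     transfer_objective(pm, g, y, mats, cfg)) / (2 * h)
    }
  }
  gr
}

# Access to the internal seed-derivation used by the trainers.
derive_seed_for_test <- function(seed, stream) {
  tsktransfer:::derive_seed(seed, stream)
}

# Exhaustive 1-D 2-means oracle: best split of the sorted values.
oracle_two_means_low <- function(x) {
  ord <- order(x)
  xs <- x[ord]
  n <- length(xs)
  ss <- vapply(seq_len(n - 1), function(m) {
    sum((xs[1:m] - mean(xs[1:m]))^2) +
      sum((xs[(m + 1):n] - mean(xs[(m + 1):n]))^2)
  }, numeric(1))
  ord[seq_len(which.min(ss))]
}
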