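test_that("fuzzy c-means handles the single-cluster case and is deterministic", {
  x <- matrix(c(0, 2, 4, 6), 4, 1)
  f1 <- fit_fcm(x, K = 1)
  expect_equal(f1$membership, matrix(1, 4, 1))
  expect_equal(f1$centers, matrix(3, 1, 1))

  x2 <- two_cloud_features(seed = 3)
  a <- fit_fcm(x2, K = 2, seed = 9)
  b <- fit_fcm(x2, K = 2, seed = 9)
  expect_identical(a, b)
  expect_equal(rowSums(a$membership), rep(1, nrow(x2)))
})

test_that("fuzzy c-means separates well-separated clouds", {
  x <- two_cloud_features(n_per = 15, offset = 10, seed = 2)
  f <- fit_fcm(x, K = 2, seed = 1)
  # own-cloud membership > 0.9 for every point, whichever cluster label
  own <- apply(f$membership, 1L, max)
  expect_true(all(own > 0.9))
  cl <- apply(f$membership, 1L, which.max)
  expect_length(unique(cl[1:15]), 1L)
  expect_length(unique(cl[16:30]), 1L)
  expect_false(cl[1] == cl[16])
})

test_that("fuzzy c-means rejects invalid and degenerate inputs", {
  expect_error(fit_fcm(matrix(1:4, 2, 2), K = 3), "at least K rows")
  expect_error(fit_fcm(matrix(1, 10, 2), K = 2), "did not converge")
  expect_error(fit_fcm(matrix(rnorm(10), 5, 2), K = 2, fuzzifier = 1), "fuzzifier")
})

test_that("antecedent estimation matches the hand-computed weighted moments", {
  a <- estimate_antecedents(matrix(c(0, 2), 2, 1), matrix(1, 2, 1), h = 0.5)
  expect_equal(a$centers[1, 1], 1)
  expect_equal(a$widths[1, 1]^2, 0.5)
  expect_equal(a$widths[1, 1], sqrt(0.5), tolerance = 1e-12)

  # positive rescaling of memberships changes nothing
  x <- matrix(rnorm(30), 10, 3)
  u <- matrix(runif(20), 10, 2)
  a1 <- estimate_antecedents(x, u, h = 0.5)
  a2 <- estimate_antecedents(x, 7.3 * u, h = 0.5)
  expect_equal(a1$centers, a2$centers)
  expect_equal(a1$widths, a2$widths)
})

test_that("antecedent widths are floored on constant features", {
  x <- cbind(rnorm(8), rep(5, 8))
  a <- estimate_antecedents(x, matrix(1, 8, 1), h = 0.5)
  expect_true(all(a$widths > 0))
  expect_true(is.finite(firing_levels(c(0, 5), a)[1]))
})

test_that("antecedent estimation rejects empty clusters", {
  u <- cbind(rep(1, 4), rep(0, 4))
  expect_error(estimate_antecedents(matrix(rnorm(8), 4, 2), u, h = 0.5),
               "zero total membership")
})

test_that("firing levels normalize, respect symmetry and survive underflow", {
  set.seed(5)
  ant <- fit_antecedents(matrix(rnorm(40), 20, 2), K = 3, seed = 5)
  for (i in 1:50) {
    fl <- firing_levels(rnorm(2), ant)
    expect_equal(sum(fl), 1, tolerance = 1e-12)
    expect_true(all(fl >= 0 & fl <= 1))
  }
  # one rule
  a1 <- estimate_antecedents(matrix(c(0, 2), 2, 1), matrix(1, 2, 1), h = 0.5)
  expect_equal(firing_levels(3, a1), 1)
  # two rules symmetric about x with equal widths
  sym <- structure(list(centers = matrix(c(-1, 1), 2, 1),
                        widths = matrix(1, 2, 1), h = 0.5, K = 2L, d = 1L),
                   class = "tsk_antecedents")
  expect_equal(firing_levels(0, sym), c(0.5, 0.5))
  # x at the first center with the second far away
  near <- structure(list(centers = matrix(c(0, 50), 2, 1),
                         widths = matrix(1, 2, 1), h = 0.5, K = 2L, d = 1L),
                    class = "tsk_antecedents")
  expect_gt(firing_levels(0, near)[1], 0.99)
  # very far from every center: log-domain renormalization, never NaN
  far <- firing_levels(1e4, sym)
  expect_false(anyNA(far))
  expect_equal(sum(far), 1, tolerance = 1e-12)
})

test_that("design-matrix mapping has the rule-block structure", {
  set.seed(6)
  x <- matrix(rnorm(20), 10, 2)
  ant <- fit_antecedents(x, K = 3, seed = 6)
  g <- map_to_g(x, ant)
  expect_equal(dim(g), c(10L, 3L * 3L))
  # constant-column entries across rule blocks sum to 1 (firing normalization)
  expect_equal(rowSums(g[, c(1, 4, 7)]), rep(1, 10), tolerance = 1e-12)
  # K = 1: row is exactly (1, x)
  a1 <- fit_antecedents(x, K = 1)
  expect_equal(map_to_g(x, a1), cbind(1, x))
  expect_error(map_to_g(matrix(rnorm(9), 3, 3), ant), "does not match")
})

test_that("prediction is argmax with ties to the lowest class", {
  scores <- rbind(c(0.9, 0.1), c(0.1, 0.9), c(0.5, 0.5), c(0, 0))
  expect_equal(scores_to_labels(scores), c(1L, 2L, 1L, 1L))
  g <- matrix(rnorm(12), 4, 3)
  expect_equal(tsk_output(g, matrix(0, 3, 2)), matrix(0, 4, 2))
  expect_error(tsk_output(g, matrix(0, 4, 2)), "disagree")
})

test_that("the ridge solver matches a least-squares oracle and is optimal", {
  set.seed(8)
  g <- matrix(rnorm(18), 6, 3)
  y <- matrix(rnorm(6), 6, 1)
  expect_equal(solve_ridge(g, matrix(0, 6, 1), eta = 1), matrix(0, 3, 1))
  # eta -> large approaches the unregularized LS fit
  p_ls <- qr.solve(g, y)
  expect_equal(max(abs(solve_ridge(g, y, eta = 1e8) - p_ls)), 0, tolerance = 1e-6)
  # solution beats 200 random norm-0.1 perturbations
  obj <- function(p) 0.5 * sum(p^2) + 0.5 * 5 * sum((g %*% p - y)^2)
  p <- solve_ridge(g, y, eta = 5)
  J0 <- obj(p)
  for (r in 1:200) {
    dir <- rnorm(3)
    expect_lte(J0, obj(p + 0.1 * dir / sqrt(sum(dir^2))))
  }
  expect_error(solve_ridge(g, y, eta = 0), "positive")
})

test_that("a noiseless linear-in-g signal is recovered exactly", {
  set.seed(9)
  x <- matrix(rnorm(60), 20, 3)
  ant <- fit_antecedents(x, K = 2, seed = 9)
  g <- map_to_g(x, ant)
  p_true <- matrix(rnorm(ncol(g) * 2), ncol(g), 2)
  y <- tsk_output(g, p_true)
  p_hat <- solve_ridge(g, y, eta = 1e10)
  expect_equal(max(abs(tsk_output(g, p_hat) - y)), 0, tolerance = 1e-6)
})
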