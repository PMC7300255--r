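test_that("the calibration loss weight follows max(2, sigma N / M)", {
  expect_equal(compute_omega_t(0.1, 100, 20), 2)
  expect_equal(compute_omega_t(0.4, 500, 4), 50)
  expect_equal(compute_omega_t(0.25, 10, 0), 2)
  expect_error(compute_omega_t(0.25, -1, 5), "invalid")
})

test_that("the loss-weight matrix is diagonal with the contracted trace", {
  th <- build_theta(2, 1, 2)
  expect_equal(th, diag(c(1, 1, 2)))
  expect_equal(build_theta(4, 0, 2), diag(4))
  expect_equal(sum(diag(build_theta(7, 3, 5.5))), 7 + 3 * 5.5)
})

test_that("the marginal MMD matrix is the signed-indicator outer product", {
  expect_equal(build_phi(1, 1), matrix(c(1, -1, -1, 1), 2, 2))
  a <- c(rep(1 / 3, 3), rep(-1 / 2, 2))
  phi <- build_phi(3, 2)
  expect_equal(phi, tcrossprod(a))
  expect_equal(sum(phi), 0, tolerance = 1e-14)
  expect_gte(min(eigen(phi, symmetric = TRUE, only.values = TRUE)$values), -1e-10)
  expect_equal(build_phi(4, 0), matrix(0, 4, 4))
})

test_that("the conditional MMD matrix sums per-class outer products", {
  # one object per class on both sides
  d <- build_delta(c(1, 2), c(1, 2), 2)
  expect_equal(diag(d), rep(1, 4))
  expect_equal(d[1, 3], -1)
  expect_equal(d[2, 4], -1)
  expect_equal(d[1, 4], 0)
  # class absent from the target contributes nothing
  d1 <- build_delta(c(1, 2), c(1, 1), 2)
  a1 <- c(1, 0, -1 / 2, -1 / 2)
  expect_equal(d1, tcrossprod(a1))
  # random labels against the outer-product oracle
  set.seed(11)
  for (trial in 1:10) {
    C <- sample(2:3, 1)
    sl <- sample(seq_len(C), sample(3:5, 1), replace = TRUE)
    tl <- sample(seq_len(C), sample(2:3, 1), replace = TRUE)
    n <- length(sl) + length(tl)
    oracle <- matrix(0, n, n)
    for (c in seq_len(C)) {
      Nc <- sum(sl == c); Mc <- sum(tl == c)
      if (Nc == 0 || Mc == 0) next
      a <- c(ifelse(sl == c, 1 / Nc, 0), ifelse(tl == c, -1 / Mc, 0))
      oracle <- oracle + tcrossprod(a)
    }
    dd <- build_delta(sl, tl, C)
    expect_equal(dd, oracle)
    expect_gte(min(eigen(dd, symmetric = TRUE, only.values = TRUE)$values), -1e-10)
  }
  expect_error(build_delta(integer(0), c(1), 2), "non-empty")
})

test_that("the marginal MMD quadratic form equals the squared mean-output gap", {
  set.seed(12)
  N <- 9; M <- 4
  g <- matrix(rnorm((N + M) * 6), N + M, 6)
  phi <- build_phi(N, M)
  for (trial in 1:20) {
    p <- rnorm(6)
    out <- g %*% p
    gap <- (mean(out[1:N]) - mean(out[(N + 1):(N + M)]))^2
    expect_equal(drop(t(p) %*% crossprod(g, phi %*% g) %*% p), gap,
                 tolerance = 1e-10)
  }
})

test_that("identical source and target point sets zero the joint MMD penalty", {
  set.seed(13)
  x <- matrix(rnorm(12), 6, 2)
  lab <- c(1, 1, 2, 2, 1, 2)
  g <- rbind(x, x)
  phi <- build_phi(6, 6)
  delta <- build_delta(lab, lab, 2)
  for (trial in 1:10) {
    p <- rnorm(2)
    expect_equal(drop(t(p) %*% crossprod(g, (phi + delta) %*% g) %*% p), 0,
                 tolerance = 1e-12)
  }
})

test_that("the affinity graph is a symmetric clamped-cosine v-NN graph", {
  # two identical positive vectors are mutual neighbors with cosine 1
  w <- build_affinity(rbind(c(1, 2), c(1, 2), c(100, 200)), v = 1)
  expect_equal(w[1, 2], 1)
  expect_equal(w, t(w))
  expect_equal(diag(w), rep(0, 3))
  # orthogonal mutual neighbors have affinity 0
  w2 <- build_affinity(rbind(c(1, 0), c(0, 1)), v = 1)
  expect_equal(w2[1, 2], 0)
  # negative cosines are clamped; symmetry holds on random data
  set.seed(14)
  x <- matrix(rnorm(40), 20, 2)
  w3 <- build_affinity(x, v = 3)
  expect_true(all(w3 >= 0))
  expect_equal(w3, t(w3))
  # a zero-norm row gets zero affinities
  w4 <- build_affinity(rbind(c(0, 0), c(1, 1), c(2, 2)), v = 1)
  expect_equal(w4[1, ], c(0, 0, 0))
  expect_error(build_affinity(x, v = 20), "smaller")
})

test_that("the normalized Laplacian is PSD with spectrum in [0, 2]", {
  L2 <- build_laplacian(matrix(c(0, 1, 1, 0), 2, 2))
  expect_equal(L2, matrix(c(1, -1, -1, 1), 2, 2))
  expect_equal(sort(eigen(L2, symmetric = TRUE, only.values = TRUE)$values),
               c(0, 2), tolerance = 1e-12)
  expect_equal(build_laplacian(matrix(0, 3, 3)), diag(3))
  set.seed(15)
  for (trial in 1:5) {
    n <- sample(5:30, 1)
    W <- build_affinity(matrix(rnorm(n * 3), n, 3), v = 3)
    ev <- eigen(build_laplacian(W), symmetric = TRUE, only.values = TRUE)$values
    expect_gte(min(ev), -1e-10)
    expect_lte(max(ev), 2 + 1e-10)
  }
  expect_error(build_laplacian(matrix(c(0, -1, -1, 0), 2, 2)), "nonnegative")
})

test_that("the transfer solver reduces to (weighted) least squares", {
  inst <- random_transfer_instance(20, 6, 3, 2, seed = 21, lambda1 = 0, lambda2 = 0)
  cfg <- adaptation_config(lambda1 = 0, lambda2 = 0, jitter = 0, seed = 21)
  mats <- inst$mats
  # omega_t = 1: plain least squares
  mats$theta <- diag(26)
  p <- solve_transfer(inst$g, inst$y, mats, cfg)
  p_ls <- qr.solve(inst$g, inst$y)
  expect_equal(max(abs(p - p_ls)) / max(abs(p_ls)), 0, tolerance = 1e-6)
  # omega_t = 3: weighted least squares oracle
  mats$theta <- diag(c(rep(1, 20), rep(3, 6)))
  pw <- solve_transfer(inst$g, inst$y, mats, cfg)
  pw_or <- solve(crossprod(inst$g, mats$theta %*% inst$g),
                 crossprod(inst$g, mats$theta %*% inst$y))
  expect_equal(max(abs(pw - pw_or)) / max(abs(pw_or)), 0, tolerance = 1e-6)
  # zero targets give the zero consequent
  expect_equal(solve_transfer(inst$g, 0 * inst$y, inst$mats, inst$cfg),
               matrix(0, ncol(inst$g), 2))
})

test_that("the transfer solution is a stationary point of the objective", {
  inst <- random_transfer_instance(20, 6, 3, 2, seed = 22,
                                   lambda1 = 0.7, lambda2 = 1.3)
  p <- solve_transfer(inst$g, inst$y, inst$mats, inst$cfg)
  gr <- fd_gradient(p, inst$g, inst$y, inst$mats, inst$cfg)
  expect_lt(max(abs(gr)), 1e-6)
  J0 <- transfer_objective(p, inst$g, inst$y, inst$mats, inst$cfg)
  set.seed(22)
  for (r in 1:200) {
    dir <- matrix(rnorm(length(p)), nrow(p))
    pert <- p + 0.1 * dir / sqrt(sum(dir^2))
    expect_lte(J0, transfer_objective(pert, inst$g, inst$y, inst$mats, inst$cfg))
  }
})

test_that("increasing the manifold weight shrinks the manifold penalty at the optimum", {
  inst <- random_transfer_instance(25, 8, 3, 2, seed = 23, lambda1 = 0.5)
  man_pen <- function(l2) {
    cfg <- inst$cfg
    cfg$lambda2 <- l2
    p <- solve_transfer(inst$g, inst$y, inst$mats, cfg)
    out <- inst$g %*% p
    sum(out * (inst$mats$laplacian %*% out))
  }
  pens <- vapply(c(0, 0.5, 1, 2, 5, 20), man_pen, numeric(1))
  expect_true(all(diff(pens) <= 1e-10))
})
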