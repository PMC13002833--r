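test_that("local linear mean smoothing is exact on lines and constants", {
  d <- fpca_sim(80, lambda = c(0, 0), sigma = 1e-12, seed = 2)
  grid <- seq(0, 1, length.out = 31)
  mu <- estimate_mean_function(d, grid, bandwidth = 0.1)
  expect_equal(mu, 2 + 0.5 * grid, tolerance = 1e-6)

  d$value <- 3.3
  expect_equal(estimate_mean_function(d, grid, bandwidth = 0.1),
               rep(3.3, 31), tolerance = 1e-9)
})

test_that("smoothed mean tracks a quadratic on a dense design", {
  set.seed(4)
  t <- runif(3000)
  d <- data.frame(subject_id = sprintf("s%d", seq_along(t)), age = t,
                  value = t^2)
  grid <- seq(0, 1, length.out = 51)
  mu <- estimate_mean_function(d, grid, bandwidth = 0.05)
  expect_lt(max(abs(mu - grid^2)), 0.01)
})

test_that("covariance surface recovers a single-component structure", {
  # dense design: raw products z = xi^2 have SD sqrt(2) * lambda, so the
  # 5% surface tolerance needs many pairs per grid neighbourhood
  # all of a subject's raw products share one xi^2 draw, so corner accuracy
  # needs most subjects to reach every neighbourhood: a truly dense design
  d <- fpca_sim(1200, lambda = c(4, 0), sigma = 1e-6, seed = 3, n_obs = 10:14)
  grid <- seq(0, 1, length.out = 11)
  mu <- estimate_mean_function(d, grid)
  cs <- estimate_covariance_surface(d, mu, grid)
  expect_identical(cs$surface, t(cs$surface))      # symmetric by construction
  # true surface is 4 * phi1(s) phi1(t) = 4 everywhere
  expect_lt(max(abs(cs$surface - 4)) / 4, 0.05)
})

test_that("pure-noise data give a flat surface and recover sigma2", {
  d <- fpca_sim(500, lambda = c(0, 0), sigma = 1, seed = 5, n_obs = 8:10)
  grid <- seq(0, 1, length.out = 21)
  mu <- estimate_mean_function(d, grid)
  cs <- estimate_covariance_surface(d, mu, grid)
  off <- cs$surface[abs(row(cs$surface) - col(cs$surface)) > 3]
  expect_lt(max(abs(off)), 0.1)
  expect_gt(cs$sigma2, 0.8)
  expect_lt(cs$sigma2, 1.2)
})

test_that("single-visit-only collections are flagged as unidentifiable", {
  d <- fpca_sim(50, seed = 6, n_obs = 1)
  grid <- seq(0, 1, length.out = 11)
  mu <- estimate_mean_function(d, grid)
  expect_error(estimate_covariance_surface(d, mu, grid),
               class = "perialps_unidentifiable_covariance")
})

test_that("eigendecomposition: FVE rule, rank-1 surfaces, oracle equivalence", {
  grid <- seq(0, 1, length.out = 41)
  h <- mean(diff(grid))
  # eigenvalues (9, 0.5, 0.5): cumulative FVE (0.90, 0.95, 1.0) -> K = 2;
  # basis vectors orthonormalized under the discrete quadrature norm
  u1 <- rep(1, 41); u2 <- grid - 0.5; u3 <- (grid - 0.5)^2 - sum((grid - 0.5)^2) / 41
  gs <- qr.Q(qr(cbind(u1, u2, u3))) / sqrt(h)
  u1 <- gs[, 1]; u2 <- gs[, 2]; u3 <- gs[, 3]
  S <- 9 * outer(u1, u1) + 0.5 * outer(u2, u2) + 0.5 * outer(u3, u3)
  eg <- eigendecompose(S, grid)
  expect_equal(eg$fve[1:2], c(0.90, 0.95), tolerance = 1e-6)
  expect_equal(eg$K, 2L)
  expect_true(all(diff(eg$fve) >= 0) && all(eg$fve <= 1 + 1e-12))

  # rank-1 separable surface with unit-norm factor
  S1 <- 4 * outer(u2, u2)
  e1 <- eigendecompose(S1, grid)
  expect_equal(e1$lambda[1], 4, tolerance = 1e-9)
  expect_equal(e1$K, 1L)
  # orthonormality under the quadrature norm
  G <- crossprod(eg$phi_all[, 1:3]) * h
  expect_lt(max(abs(G - diag(3))), 1e-6)
  expect_true(all(colSums(eg$phi_all) * h >= -1e-9))   # sign convention

  # oracle: dense eigendecomposition with uniform quadrature weights
  set.seed(9)
  A <- matrix(rnorm(41 * 6), 41, 6)
  Sr <- tcrossprod(A)
  er <- eigendecompose(Sr, grid)
  oracle <- eigen(Sr, symmetric = TRUE)$values * h
  expect_equal(er$lambda, oracle[oracle > 0][seq_along(er$lambda)],
               tolerance = 1e-8)
})

test_that("BLUP scores: zero residual, projection limit, shrinkage", {
  d <- fpca_sim(300, lambda = c(1, 0.2), sigma = 0.05, seed = 11, n_obs = 2:3)
  m <- fit_fpca(d, n_grid = 31)
  # a subject lying exactly on the mean has all-zero scores
  xi <- fpc_scores(m$grid[c(5, 20, 30)], m$mu[c(5, 20, 30)], m)
  expect_equal(unname(xi), rep(0, m$K), tolerance = 1e-10)

  # dense noiseless single-component subject: BLUP ~ quadrature projection
  dense_t <- m$grid
  y <- m$mu + 0.8 * m$phi[, 1]
  m0 <- m; m0$sigma2 <- 1e-10
  xi_d <- fpc_scores(dense_t, y, m0)
  proj <- sum((y - m$mu) * m$phi[, 1]) * mean(diff(m$grid))
  expect_equal(xi_d[1], proj, tolerance = 0.01)

  # scores shrink monotonically toward zero as sigma2 grows
  norms <- vapply(c(0.01, 0.1, 1, 10), function(s2) {
    mm <- m; mm$sigma2 <- s2
    sqrt(sum(fpc_scores(dense_t, y, mm)^2))
  }, numeric(1))
  expect_true(all(diff(norms) < 0))
})

test_that("dense balanced designs reduce to multivariate PCA", {
  set.seed(13)
  grid <- seq(0, 1, length.out = 21)
  n <- 60
  phi1 <- rep(1, 21); phi2 <- sqrt(12) * (grid - 0.5)
  Y <- outer(rep(1, n), 2 + 0.5 * grid) +
    outer(rnorm(n, sd = 1), phi1) + outer(rnorm(n, sd = 0.5), phi2)
  d <- data.frame(subject_id = rep(sprintf("s%03d", 1:n), each = 21),
                  age = rep(grid, n), value = as.vector(t(Y)))
  m <- fit_fpca(d)
  expect_identical(m$smoother, "empirical")
  h <- mean(diff(grid))
  pca <- eigen(stats::cov(Y), symmetric = TRUE)
  expect_equal(m$lambda[1:2], pca$values[1:2] * h, tolerance = 1e-6)
  for (k in 1:2) {
    v <- pca$vectors[, k] / sqrt(h)
    if (sum(v) < 0) v <- -v
    expect_equal(m$phi[, k], v, tolerance = 1e-6)
  }
})

test_that("sparse designs recover the generating eigenfunctions", {
  # a single realization carries irreducible eigenvector rotation of order
  # sqrt(lambda1 * lambda2 / n) / (lambda1 - lambda2), so the check is on
  # the median worst-case error over 7 seeded replicates at n = 1000
  errs <- vapply(c(17, 23, 31, 47, 59, 71, 83), function(seed) {
    d <- fpca_sim(1000, lambda = c(0.5, 0.12), sigma = 0.05, seed = seed,
                  n_obs = 2:4)
    m <- fit_fpca(d, bw_cov = 0.3)
    expect_gte(m$K, 2L)
    phi1 <- rep(1, length(m$grid))
    phi2 <- sqrt(12) * (m$grid - 0.5)
    max(min(max(abs(m$phi[, 1] - phi1)), max(abs(m$phi[, 1] + phi1))),
        min(max(abs(m$phi[, 2] - phi2)), max(abs(m$phi[, 2] + phi2))))
  }, numeric(1))
  expect_lt(median(errs), 0.15)
})

test_that("the 95% rule selects the generating number of components", {
  # lambda (0.8, 0.16, 0.04): cumulative FVE (0.80, 0.96, 1.00) -> K = 2
  phi3 <- function(t) sqrt(5) * (6 * (t - 0.5)^2 - 0.5) /
    sqrt(sum((sqrt(5) * (6 * (seq(0, 1, length.out = 101) - 0.5)^2 - 0.5))^2) / 101)
  set.seed(19)
  rows <- lapply(1:800, function(i) {
    mt <- sample(2:3, 1)
    t <- sort(runif(mt))
    y <- 1 + rnorm(1, sd = sqrt(0.8)) +
      rnorm(1, sd = sqrt(0.16)) * sqrt(12) * (t - 0.5) +
      rnorm(1, sd = sqrt(0.04)) * phi3(t) + rnorm(mt, sd = 0.02)
    data.frame(subject_id = sprintf("s%04d", i), age = t, value = y)
  })
  m <- fit_fpca(do.call(rbind, rows))
  expect_equal(m$K, 2L)
})

test_that("group separation in first scores matches the generator", {
  delta <- 1.2                       # configured shift along phi1
  lam <- c(1, 0.25)
  d <- fpca_sim(1000, lambda = lam, sigma = 0.1, seed = 23,
                group_shift = delta)
  m <- fit_fpca(d)
  sg <- unique(d[, c("subject_id", "group")])
  sc <- merge(m$scores, sg, by = "subject_id")
  dd <- cohens_d(sc$xi_1[sc$group == "B"], sc$xi_1[sc$group == "A"])
  expect_lt(abs(dd$estimate - delta / sqrt(lam[1])) / (delta / sqrt(lam[1])), 0.2)
})

test_that("refitting identical inputs gives identical models", {
  d <- fpca_sim(150, seed = 29)
  m1 <- fit_fpca(d)
  m2 <- fit_fpca(d)
  expect_identical(m1, m2)
  expect_equal(nrow(tidy(m1)), m1$K)
  expect_equal(glance(m1)$n_subjects, 150L)
})
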