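test_that("standardized mean differences reproduce the published table", {
  # continuous rows of the reference baseline table, average-variance form
  chk <- reference_smd_check()
  key <- c("moca", "mmse", "age", "faq", "ravlt_immediate", "ldeltotal",
           "trabscor", "adas13")
  sub <- chk[chk$variable %in% key, ]
  expect_equal(nrow(sub), 8L)
  expect_true(all(sub$rel_error < 0.01))
  # and at least 8 of all continuous rows agree to 1%
  expect_gte(sum(chk$rel_error < 0.01), 8L)

  expect_equal(smd_continuous(25.87, 2.61, 22.06, 4.56)$estimate, 1.025,
               tolerance = 0.01)
  expect_equal(smd_continuous(71.47, 7.30, 72.21, 6.45)$estimate, 0.107,
               tolerance = 0.05)
  expect_equal(smd_continuous(3, 1, 3, 2)$estimate, 0)
})

test_that("binary SMD matches the published sex row and hand arithmetic", {
  expect_equal(smd_binary(46 / 128, 48 / 83)$estimate, 0.450, tolerance = 0.005)
  expect_equal(smd_binary(0.2, 0.8)$estimate, 0.6 / sqrt(0.16), tolerance = 1e-12)
  expect_equal(smd_binary(0.3, 0.3)$estimate, 0)
  expect_error(smd_binary(0, 1), class = "perialps_infinite_effect")
})

test_that("Cohen's d conventions and degenerate samples", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(cohens_d(x, x)$estimate, 0)
  expect_error(cohens_d(c(0, 0, 0), c(1, 1, 1)),
               class = "perialps_infinite_effect")
  set.seed(21)
  d <- cohens_d(rnorm(1000), rnorm(1000, mean = -0.5))$estimate
  expect_gt(d, 0.4); expect_lt(d, 0.6)
  # pooled-df and average-variance agree for equal group sizes/variances
  set.seed(22)
  a <- rnorm(400); b <- rnorm(400, 0.3)
  expect_equal(cohens_d(a, b, "pooled_df")$estimate,
               cohens_d(a, b, "average_variance")$estimate, tolerance = 1e-3)
  expect_identical(cohens_d(a, b)$convention, "pooled_df")
})

test_that("covariate adjustment: orthogonality, nulling, deconfounding", {
  set.seed(31)
  n <- 200
  g <- factor(rep(c("HC", "CI"), each = n), levels = c("HC", "CI"))
  cov_bal <- rep(rnorm(n), 2)              # identical in both groups
  y <- 0.5 * (g == "CI") + 0.2 * cov_bal + rnorm(2 * n, sd = 0.1)
  d1 <- adjusted_group_difference(
    data.frame(group = g, y = y, cov = cov_bal), "y", "cov")
  raw <- mean(y[g == "CI"]) - mean(y[g == "HC"])
  expect_equal(d1$effect, raw, tolerance = 1e-9)

  y2 <- 2 * cov_bal
  d2 <- suppressWarnings(adjusted_group_difference(   # exact fit is intended
    data.frame(group = g, y = y2, cov = cov_bal), "y", "cov"))
  expect_equal(d2$effect, 0, tolerance = 1e-9)

  # confounded design: group shifts the covariate, outcome depends only on it
  delta <- 1.5
  cov_conf <- rnorm(2 * n) + delta * (g == "CI")
  y3 <- cov_conf + rnorm(2 * n, sd = 0.2)
  raw3 <- mean(y3[g == "CI"]) - mean(y3[g == "HC"])
  d3 <- adjusted_group_difference(
    data.frame(group = g, y = y3, cov = cov_conf), "y", "cov")
  se3 <- 0.2 * sqrt(2 / n)
  expect_gt(raw3, delta - 0.3)
  expect_lt(abs(d3$effect), 2 * se3 * 1.5)

  # collinear designs are reported, missing rows counted
  expect_error(
    adjusted_group_difference(
      data.frame(group = g, y = y, c1 = cov_bal, c2 = 2 * cov_bal),
      "y", c("c1", "c2")),
    class = "perialps_rank_deficiency"
  )
  dd <- data.frame(group = g, y = y, cov = cov_bal)
  dd$cov[1:10] <- NA
  expect_equal(adjusted_group_difference(dd, "y", "cov")$n_dropped, 10L)
})

test_that("correlations: closed-form cases and the midrank t approximation", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(correlate(x, 3 * x + 1)$estimate, 1, tolerance = 1e-12)
  expect_equal(correlate(x, -x^3, "spearman")$estimate, -1)
  r <- correlate(x, c(2, 1, 4, 3, 5), "spearman")
  expect_equal(r$estimate, 0.8, tolerance = 1e-12)
  # brute-force rank formula 1 - 6 sum(d^2) / (n (n^2 - 1))
  expect_equal(r$estimate, 1 - 6 * sum((x - rank(c(2, 1, 4, 3, 5)))^2) / (5 * 24),
               tolerance = 1e-12)
  expect_error(correlate(x, rep(1, 5)), class = "perialps_undefined_correlation")
})

test_that("group tests: t, chi-squared against the hand-computed oracle, KS", {
  d_id <- data.frame(group = rep(c("A", "B"), each = 10), v = rep(1:10, 2))
  tt <- group_tests(d_id, "v")
  expect_equal(tt$statistic, 0, tolerance = 1e-12)
  expect_equal(tt$p_value, 1, tolerance = 1e-12)
  expect_identical(tt$method, "student_t")

  # balanced 2x2 table has chi-squared exactly 0
  d_bal <- data.frame(group = rep(c("A", "B"), each = 100),
                      s = rep(rep(c("m", "f"), each = 50), 2))
  expect_equal(group_tests(d_bal, "s")$statistic, 0, tolerance = 1e-12)

  # the published sex table: oracle sum((O - E)^2 / E) without correction
  counts <- reference_sex_counts()
  d_sex <- data.frame(
    group = rep(counts$group, counts$n),
    sex = rep(counts$sex, counts$n)
  )
  res <- group_tests(d_sex, "sex")
  O <- xtabs(n ~ group + sex, counts)
  E <- outer(rowSums(O), colSums(O)) / sum(O)
  expect_equal(res$statistic, sum((O - E)^2 / E), tolerance = 1e-9)
  expect_identical(res$method, "chi_square")
  expect_lt(res$p_value, 0.05)

  ks <- group_tests(data.frame(group = rep(c("A", "B"), 50), v = rnorm(100)),
                    "v", ks_normality = TRUE)
  expect_true("ks" %in% ks$method)
})

test_that("BH adjustment matches the brute-force step-up definition", {
  step_up <- function(p) {
    n <- length(p); o <- order(p, decreasing = TRUE)
    ro <- order(o)
    pmin(1, cummin(n / (n:1) * p[o]))[ro]
  }
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.37), 0.37)
  expect_equal(bh_fdr(rep(1, 6)), rep(1, 6))
  set.seed(41)
  for (i in 1:20) {
    p <- runif(sample(3:40, 1))
    adj <- bh_fdr(p)
    expect_equal(adj, step_up(p), tolerance = 1e-12)
    expect_true(all(adj >= p - 1e-12))
    perm <- sample(length(p))
    expect_equal(bh_fdr(p[perm]), adj[perm], tolerance = 1e-12)
  }
  expect_error(bh_fdr(c(0.5, 1.2)), class = "perialps_invalid_input")
})

test_that("Student t maintains nominal type-I error under the null", {
  set.seed(51)
  m <- matrix(rnorm(5000 * 60), 5000, 60)
  rej <- vapply(seq_len(5000), function(i) {
    t.test(m[i, 1:30], m[i, 31:60], var.equal = TRUE)$p.value < 0.05
  }, logical(1))
  expect_gte(mean(rej), 0.04)
  expect_lte(mean(rej), 0.06)
})
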