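test_that("DTI WLS recovers model-exact tensors and their scalars", {
  gt <- study_gtab(c(2, 12, 24, 24))
  D <- diag(c(1.7, 0.3, 0.3))
  s <- simulate_voxel_signal(list(compartment(1, D)), gt, S0 = 100)
  fit <- fit_dti_wls(s, gt)
  expect_lt(max(abs(fit$D - D)), 1e-9)
  expect_equal(fit$S0, 100, tolerance = 1e-9)
  # hand-evaluated FA of eigenvalues (1.7, 0.3, 0.3)
  fa_hand <- sqrt(0.5 * ((1.7 - 0.3)^2 + 0 + (1.7 - 0.3)^2) /
                    (1.7^2 + 0.3^2 + 0.3^2))
  expect_equal(fit$fa, fa_hand, tolerance = 1e-9)
  expect_equal(fit$md, mean(diag(D)), tolerance = 1e-12)

  iso <- fit_dti_wls(simulate_voxel_signal(list(compartment(1, 0.8)), gt), gt)
  expect_equal(iso$fa, 0, tolerance = 1e-9)
})

test_that("DTI round-trip holds for 100 random PSD tensors", {
  gt <- study_gtab(c(1, 6, 24, 24))
  set.seed(42)
  worst <- 0
  for (i in 1:100) {
    D <- random_psd_tensor(0.2, 2.5)
    s <- simulate_voxel_signal(list(compartment(1, D)), gt, S0 = 50)
    fit <- fit_dti_wls(s, gt)
    worst <- max(worst, max(abs(fit$D - D)) / max(abs(D)))
  }
  expect_lt(worst, 1e-8)
})

test_that("DTI fitting is rotation equivariant", {
  gt <- study_gtab(c(1, 6, 24, 24))
  set.seed(3)
  D <- diag(c(1.8, 0.5, 0.3))
  s <- simulate_voxel_signal(list(compartment(1, D)), gt, S0 = 20)
  dirs <- cbind(gt$bx, gt$by, gt$bz)
  for (i in 1:5) {
    R <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
    rdirs <- dirs %*% t(R)
    rdirs[gt$bval == 0, ] <- 0
    gt_rot <- gradient_table(gt$bval, rdirs)
    fit <- fit_dti_wls(s, gt_rot)
    expect_lt(max(abs(fit$D - R %*% D %*% t(R))), 1e-6)
  }
})

test_that("DTI preconditions are enforced", {
  gt <- study_gtab(c(1, 6, 24, 24))
  s <- simulate_voxel_signal(list(compartment(1, 1.0)), gt)
  expect_error(fit_dti_wls(s[1:5], gt[1:5, ]), class = "perialps_invalid_input")
  expect_error(fit_dti_wls(replace(s, 3, NaN), gt), class = "perialps_invalid_input")
  # collapse all directions onto one axis: rank-deficient design
  bad <- gradient_table(c(0, rep(1000, 8)),
                        rbind(c(0, 0, 0), matrix(rep(c(1, 0, 0), 8), ncol = 3, byrow = TRUE)))
  sbad <- simulate_voxel_signal(list(compartment(1, 1.0)), bad)
  expect_error(fit_dti_wls(sbad, bad), class = "perialps_singular_design")
})

test_that("DKI WLS recovers model-exact (D, W) on the study table", {
  gt <- study_gtab(c(2, 12, 48, 60))
  set.seed(8)
  D <- diag(c(1.5, 0.9, 0.5)); D[1, 2] <- D[2, 1] <- 0.1
  W <- runif(15, -0.05, 0.4)
  s <- dki_model_signal(D, W, gt, S0 = 80)
  fit <- fit_dki_wls(s, gt)
  expect_lt(max(abs(fit$D - D)), 1e-6)
  expect_lt(max(abs(fit$W - W)), 1e-6)
  expect_equal(fit$S0, 80, tolerance = 1e-6)
})

test_that("Gaussian signals yield a zero kurtosis tensor and DTI-consistent D", {
  gt <- study_gtab(c(2, 12, 48, 60))
  D <- random_psd_tensor(0.3, 2.0)
  s <- simulate_voxel_signal(list(compartment(1, D)), gt, S0 = 30)
  dki <- fit_dki_wls(s, gt)
  dti <- fit_dti_wls(s, gt)
  expect_lt(max(abs(dki$W)), 1e-8)
  expect_lt(max(abs(dki$D - dti$D)), 1e-8)
})

test_that("fitted kurtosis approximates the analytic mixture cumulant at low b", {
  gt <- validation_gtab()
  s <- simulate_voxel_signal(iso_mixture(), gt, S0 = 100)
  fit <- fit_dki_wls(s, gt)
  expect_lt(abs(fit$kxxxx - 0.75), 0.1)
  expect_lt(abs(fit$dxx - 2.0) / 2.0, 0.05)
})

test_that("directional kurtosis follows the apparent-kurtosis convention", {
  gt <- study_gtab(c(2, 12, 48, 60))
  # isotropic D: prefactor (MD / D(n))^2 is 1, so K(ex) = W_xxxx
  W <- setNames(rep(0, 15), names(fit_dki_wls(
    dki_model_signal(diag(rep(1, 3)), rep(0, 15), gt), gt)$W))
  W["xxxx"] <- 0.37
  fit_iso <- fit_dki_wls(dki_model_signal(diag(rep(1.2, 3)), W, gt), gt)
  expect_equal(fit_iso$kxxxx, 0.37, tolerance = 1e-8)
  # W = 0 gives zero kurtosis in every direction
  fit0 <- fit_dki_wls(dki_model_signal(diag(c(1.5, 1, 0.7)), rep(0, 15), gt), gt)
  set.seed(2)
  for (i in 1:5) {
    n <- rnorm(3); n <- n / sqrt(sum(n^2))
    expect_equal(directional_kurtosis(fit0, n), 0, tolerance = 1e-8)
  }
  # hand arithmetic: D = diag(2, 1, 1), W_xxxx = 0.6, MD = 4/3
  W2 <- rep(0, 15); W2[1] <- 0.6
  fit2 <- fit_dki_wls(dki_model_signal(diag(c(2, 1, 1)), W2, gt), gt)
  expect_equal(fit2$kxxxx, ((4 / 3) / 2)^2 * 0.6, tolerance = 1e-8)
  expect_equal(directional_kurtosis(fit2, c(1, 0, 0), "raw"), 0.6,
               tolerance = 1e-8)
  # optional floor clamps negative kurtoses only
  W3 <- rep(0, 15); W3[1] <- -0.3
  fit3 <- fit_dki_wls(dki_model_signal(diag(rep(1, 3)), W3, gt), gt,
                      floor_kurtosis = TRUE)
  expect_equal(fit3$kxxxx, 0)
})

test_that("DKI identifiability preconditions are enforced", {
  single <- make_gradient_table(c(0, 1000), c(2, 30), seed = 1)
  s <- simulate_voxel_signal(iso_mixture(), single)
  expect_error(fit_dki_wls(s, single), class = "perialps_identifiability_error")
})

test_that("noisy FA is nearly unbiased at SNR 30", {
  gt <- study_gtab(c(2, 12, 24, 24))
  D <- diag(c(1.7, 0.3, 0.3))
  s <- simulate_voxel_signal(list(compartment(1, D)), gt, S0 = 100)
  fa_true <- fit_dti_wls(s, gt)$fa
  fas <- vapply(1:500, function(i) {
    fit_dti_wls(add_rician_noise(s, 100 / 30, seed = 1000 + i), gt)$fa
  }, numeric(1))
  expect_lt(abs(median(fas) - fa_true), 0.03)
})
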