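test_that("alps_index arithmetic and degenerate inputs", {
  expect_equal(alps_index(1.2, 1.4, 0.8, 1.0), 1.3 / 0.9, tolerance = 1e-12)
  expect_equal(alps_index(0.7, 0.7, 0.7, 0.7), 1.0)
  expect_error(alps_index(1, 1, -2, 1), class = "perialps_degenerate_denominator")
  expect_error(alps_index(NA, 1, 1, 1), class = "perialps_invalid_input")
})

test_that("sphere ROI rasterization counts lattice voxels by center distance", {
  m <- sphere_mask(c(21, 21, 21), c(10, 10, 10), 2.5, 1)
  # brute-force count of integer offsets with squared norm <= 6.25
  off <- expand.grid(-3:3, -3:3, -3:3)
  expect_equal(sum(m), sum(rowSums(off^2) <= 6.25))
  expect_equal(sum(m), 81L)
})

test_that("extract_roi_mean averages finite voxels and flags empty ROIs", {
  map <- array(1.2, c(10, 10, 10))
  roi <- sphere_mask(c(10, 10, 10), c(5, 5, 5), 2.5)
  expect_equal(extract_roi_mean(map, roi), 1.2)
  map[roi] <- NA; map[which(roi)[1]] <- 3
  expect_equal(extract_roi_mean(map, roi), 3)
  map[roi] <- NA
  expect_error(extract_roi_mean(map, roi), class = "perialps_empty_roi")
})

test_that("isotropic phantom yields index exactly 1 and mirrored symmetry", {
  cfg <- small_phantom_config(snr = Inf, g = 0, f_fw = 0, tissue_axial = 0.8,
                              tissue_radial = 0.8)
  ph <- build_alps_phantom(cfg)
  maps <- fit_dwi_volume(ph$signal, ph$gtab, mask = roi_union(ph), model = "dti")
  res <- compute_alps(maps, phantom_roi_set(ph))
  expect_equal(res$dti_alps_mean, 1.0, tolerance = 1e-9)
  expect_equal(ph$truth$dti_alps, 1.0, tolerance = 1e-12)
})

test_that("mirrored noise-free phantoms give identical hemispheres", {
  ph <- build_alps_phantom(small_phantom_config(snr = Inf, g = 0.6))
  maps <- fit_dwi_volume(ph$signal, ph$gtab, mask = roi_union(ph), model = "dki")
  res <- compute_alps(maps, phantom_roi_set(ph))
  expect_lt(abs(res$dti_alps_left - res$dti_alps_right), 1e-9)
  expect_lt(abs(res$dki_alps_left - res$dki_alps_right), 1e-9)
  expect_equal(res$dti_alps_mean, (res$dti_alps_left + res$dti_alps_right) / 2,
               tolerance = 1e-12)
  td <- tidy(res)
  expect_equal(td$dti_alps_mean, res$dti_alps_mean)
})

test_that("the index is invariant under global diffusivity rescaling", {
  ph <- build_alps_phantom(small_phantom_config(snr = Inf, g = 0.4))
  maps <- fit_dwi_volume(ph$signal, ph$gtab, mask = roi_union(ph), model = "dti")
  res1 <- compute_alps(maps, phantom_roi_set(ph))
  for (nm in c("dxx", "dyy", "dzz")) maps[[nm]] <- maps[[nm]] * 3.7
  res2 <- compute_alps(maps, phantom_roi_set(ph))
  expect_equal(res1$dti_alps_mean, res2$dti_alps_mean, tolerance = 1e-12)
})

test_that("fitted index tracks the analytic oracle on low-b acquisitions", {
  # D(n) is a b -> 0 quantity: on the low-b validation shells the
  # kurtosis-corrected tensor reproduces the analytic mixture index to 1%
  for (g in c(0, 0.5, 1)) {
    cfg <- alps_phantom_config(grid_size = c(24L, 24L, 24L), roi_radius_mm = 2,
                               shell_bvals = c(0, 100, 200, 400),
                               dirs_per_shell = c(1, 6, 24, 30),
                               snr = Inf, g = g)
    ph <- build_alps_phantom(cfg)
    maps <- fit_dwi_volume(ph$signal, ph$gtab, mask = roi_union(ph), model = "dki")
    res <- compute_alps(maps, phantom_roi_set(ph))
    expect_equal(res$dti_alps_mean, ph$truth$dti_alps, tolerance = 0.01)
  }
})

test_that("fitted index increases with the glymphatic parameter", {
  vals <- vapply(c(0, 1), function(g) {
    ph <- build_alps_phantom(small_phantom_config(snr = Inf, g = g))
    maps <- fit_dwi_volume(ph$signal, ph$gtab, mask = roi_union(ph), model = "dti")
    compute_alps(maps, phantom_roi_set(ph))$dti_alps_mean
  }, numeric(1))
  expect_gt(vals[2], vals[1])
})

test_that("mean index over noisy realizations stays near the noise-free value", {
  cfg <- small_phantom_config(snr = Inf, g = 0.5, seed = 21)
  ph <- build_alps_phantom(cfg)
  rois <- phantom_roi_set(ph)
  mask <- roi_union(ph)
  maps0 <- fit_dwi_volume(ph$signal, ph$gtab, mask = mask, model = "dti")
  ref <- compute_alps(maps0, rois)$dti_alps_mean
  sigma <- cfg$S0 / 30
  idx <- vapply(1:200, function(i) {
    noisy <- add_rician_noise(ph$signal, sigma, seed = 5000 + i)
    maps <- fit_dwi_volume(noisy, ph$gtab, mask = mask, model = "dti")
    compute_alps(maps, rois)$dti_alps_mean
  }, numeric(1))
  se <- sd(idx) / sqrt(length(idx))
  expect_lt(abs(mean(idx) - ref), 3 * se + 1e-12)
})

test_that("DKI-ALPS inversion flag flips the orientation of the ratio", {
  ph <- build_alps_phantom(small_phantom_config(snr = Inf, g = 0.5))
  maps <- fit_dwi_volume(ph$signal, ph$gtab, mask = roi_union(ph), model = "dki")
  a <- compute_alps(maps, phantom_roi_set(ph))
  b <- compute_alps(maps, phantom_roi_set(ph), invert_kurtosis = TRUE)
  expect_equal(b$dki_alps_left, 1 / a$dki_alps_left, tolerance = 1e-9)
  expect_equal(a$dti_alps_mean, b$dti_alps_mean)  # DTI side untouched
})
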