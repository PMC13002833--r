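# Shared fixtures: gradient tables, reference mixtures, small phantoms.

# Study-style acquisition (b = 0, 500, 1000, 2000 s/mm^2).
study_gtab <- function(dirs = c(2, 12, 48, 60), seed = 11L) {
  make_gradient_table(c(0, 500, 1000, 2000), dirs, seed = seed)
}

# Low-b validation acquisition: inside the cumulant expansion's validity
# range, where fitted D(n)/K(n) approximate the analytic b -> 0 values.
validation_gtab <- function(dirs = c(2, 12, 24, 30), seed = 11L) {
  make_gradient_table(c(0, 100, 200, 400), dirs, seed = seed)
}

# The canonical two-compartment isotropic mixture: D = 2.0, K = 0.75.
iso_mixture <- function() {
  list(compartment(0.5, 1.0), compartment(0.5, 3.0))
}

# Random symmetric PSD tensor with eigenvalues in [lo, hi] (1e-3 mm^2/s).
random_psd_tensor <- function(lo = 0.2, hi = 2.5) {
  q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  q %*% diag(runif(3, lo, hi)) %*% t(q)
}

# Small phantom configuration used where full 40^3 resolution is not needed.
small_phantom_config <- function(...) {
  defaults <- list(grid_size = c(24L, 24L, 24L), roi_radius_mm = 2,
                   shell_bvals = c(0, 500, 1000),
                   dirs_per_shell = c(1, 12, 24))
  do.call(alps_phantom_config, utils::modifyList(defaults, list(...)))
}

roi_union <- function(phantom) Reduce(`|`, phantom$roi_masks)

# Sparse longitudinal generator on [0, 1] with known components:
# phi1 constant, phi2 centered linear (orthonormal on [0, 1]).
fpca_sim <- function(n, lambda = c(1, 0.25), sigma = 0.1, seed = 1,
                     n_obs = 1:3, mu_fun = function(t) 2 + 0.5 * t,
                     group_shift = 0) {
  phi1 <- function(t) rep(1, length(t))
  phi2 <- function(t) sqrt(12) * (t - 0.5)
  set.seed(seed)
  rows <- lapply(seq_len(n), function(i) {
    m <- sample(n_obs, 1)
    t <- sort(runif(m))
    xi1 <- rnorm(1, sd = sqrt(lambda[1])) +
      if (i <= n / 2) 0 else group_shift
    xi2 <- rnorm(1, sd = sqrt(lambda[2]))
    y <- mu_fun(t) + xi1 * phi1(t) + xi2 * phi2(t) + rnorm(m, sd = sigma)
    data.frame(subject_id = sprintf("s%05d", i), age = t, value = y,
               group = if (i <= n / 2) "A" else "B")
  })
  do.call(rbind, rows)
}
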