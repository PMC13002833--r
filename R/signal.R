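# Gaussian-compartment signal simulation and the analytic mixture oracle.
#
# All diffusivities are carried in units of 1e-3 mm^2/s; b-values in s/mm^2.
# The signal equation therefore uses the dimensionless exponent
# b * D * 1e-3.

#' Define a Gaussian diffusion compartment
#'
#' @param fraction Signal fraction in \[0, 1\].
#' @param tensor Either a symmetric PSD 3x3 matrix (units 1e-3 mm^2/s), a
#'   single diffusivity (isotropic compartment), or a length-3 vector of
#'   eigenvalues aligned with the coordinate axes.
#' @return A list of class `compartment` with elements `fraction` and `tensor`.
#' @export
compartment <- function(fraction, tensor) {
  if (!is.numeric(fraction) || length(fraction) != 1L ||
      fraction < 0 || fraction > 1) {
    perialps_abort("`fraction` must be a single value in [0, 1].",
                   "perialps_invalid_compartment")
  }
  if (is.numeric(tensor) && !is.matrix(tensor)) {
    tensor <- if (length(tensor) == 1L) diag(rep(tensor, 3)) else diag(as.numeric(tensor))
  }
  check_psd3(tensor, what = "compartment tensor")
  structure(list(fraction = fraction, tensor = tensor), class = "compartment")
}

#' Axially symmetric (cigar/pancake) tensor aligned with a coordinate axis
#'
#' @param axial Diffusivity along `axis` (1e-3 mm^2/s).
#' @param radial Diffusivity perpendicular to `axis`.
#' @param axis One of "x", "y", "z".
#' @return A 3x3 diagonal tensor.
#' @export
axial_tensor <- function(axial, radial, axis = c("z", "x", "y")) {
  axis <- match.arg(axis)
  d <- rep(radial, 3)
  d[match(axis, c("x", "y", "z"))] <- axial
  diag(d)
}

check_mixture <- function(mixture) {
  if (!is.list(mixture) || length(mixture) == 0L) {
    perialps_abort("`mixture` must be a non-empty list of compartments.",
                   "perialps_invalid_compartment")
  }
  fr <- vapply(mixture, function(cp) cp$fraction, numeric(1))
  if (abs(sum(fr) - 1) > 1e-9) {
    perialps_abort("Compartment fractions must sum to 1 (tol 1e-9).",
                   "perialps_invalid_compartment")
  }
  for (cp in mixture) check_psd3(cp$tensor, what = "compartment tensor")
  invisible(TRUE)
}

#' Simulate the noise-free multi-shell signal of a compartment mixture
#'
#' Evaluates S(b, n) = S0 * sum_i f_i * exp(-b * n' D_i n) for every row of
#' the gradient table.
#'
#' @param mixture List of [compartment()] objects whose fractions sum to 1.
#' @param gtab A [gradient_table()].
#' @param S0 Non-diffusion-weighted intensity (> 0).
#' @return Numeric vector with one intensity per gradient-table row.
#' @export
simulate_voxel_signal <- function(mixture, gtab, S0 = 1) {
  check_mixture(mixture)
  if (!is.numeric(S0) || S0 <= 0) {
    perialps_abort("`S0` must be positive.", "perialps_invalid_config")
  }
  dirs <- gtab_dirs(gtab)
  b3 <- gtab$bval * 1e-3
  sig <- numeric(nrow(gtab))
  for (cp in mixture) {
    # quadratic form n' D n for all rows at once
    q <- rowSums((dirs %*% cp$tensor) * dirs)
    sig <- sig + cp$fraction * exp(-b3 * q)
  }
  S0 * sig
}

#' Analytic directional diffusivity and kurtosis of a Gaussian mixture
#'
#' For a mixture of Gaussian compartments the exact small-b cumulants along a
#' direction n are D(n) = sum_i f_i D_i(n) and
#' K(n) = 3 * (sum_i f_i D_i(n)^2 - D(n)^2) / D(n)^2,
#' i.e. the excess kurtosis induced by the variance of the per-compartment
#' diffusivities. This is the fitting-free oracle used to validate tensor
#' estimation.
#'
#' @param mixture List of [compartment()] objects.
#' @param direction Length-3 direction vector (normalized internally).
#' @return Named list with elements `D` (1e-3 mm^2/s) and `K` (unitless).
#' @export
analytic_directional_stats <- function(mixture, direction) {
  check_mixture(mixture)
  n <- unit_vector(direction)
  di <- vapply(mixture, function(cp) drop(t(n) %*% cp$tensor %*% n), numeric(1))
  fr <- vapply(mixture, function(cp) cp$fraction, numeric(1))
  D <- sum(fr * di)
  if (D <= 0) {
    perialps_abort("D(n) = 0: directional kurtosis undefined.",
                   "perialps_undefined_kurtosis")
  }
  K <- 3 * (sum(fr * di^2) - D^2) / D^2
  list(D = D, K = K)
}

#' Add Rician (magnitude-MRI) noise to a signal vector
#'
#' Each sample S is replaced by sqrt((S + e1)^2 + e2^2) with e1, e2
#' independent zero-mean Gaussians of standard deviation `sigma`.
#'
#' @param signal Numeric vector (or array) of noise-free intensities.
#' @param sigma Noise standard deviation (same units as the signal).
#' @param seed Optional integer seed; the caller's RNG state is restored.
#' @return Noisy vector/array with the shape of `signal`.
#' @export
add_rician_noise <- function(signal, sigma, seed = NULL) {
  if (sigma < 0) {
    perialps_abort("`sigma` must be non-negative.", "perialps_invalid_config")
  }
  if (sigma == 0) return(signal)
  with_seed(seed, {
    e1 <- rnorm(length(signal), sd = sigma)
    e2 <- rnorm(length(signal), sd = sigma)
    out <- sqrt((signal + e1)^2 + e2^2)
    if (!is.null(dim(signal))) dim(out) <- dim(signal)
    out
  })
}
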