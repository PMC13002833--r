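# Digital multi-shell diffusion phantom in the ALPS geometry.
#
# Two mirrored hemispheres each contain a projection-fiber block (principal
# axis z, inferior-superior) and an association-fiber block (principal axis
# y, anterior-posterior). A perivascular compartment elongated along x
# (right-left, the direction of the medullary veins) carries the glymphatic
# signal: its fraction grows linearly with the conductance parameter g and
# its axial diffusivity rises from tissue level toward free water. An
# isotropic free-water pool completes each mixture. Every block's analytic
# directional diffusivities/kurtoses and the analytic ALPS index are stored
# as ground truth.

#' Default configuration for the ALPS phantom
#'
#' @param grid_size Integer length-3 grid (voxels), default 40^3.
#' @param voxel_mm Isotropic voxel size in mm.
#' @param g Glymphatic conductance in \[0, 1\]; scales the perivascular
#'   compartment fraction (`f_pv = g * f_pv_max`) and its axial diffusivity
#'   (`d_pv_base + g * (d_free - d_pv_base)`).
#' @param f_fw Free-water fraction in \[0, 1\].
#' @param f_pv_max Perivascular fraction at g = 1.
#' @param tissue_axial,tissue_radial Tissue-tensor eigenvalues (1e-3 mm^2/s).
#' @param d_pv_base Perivascular axial diffusivity at g = 0.
#' @param d_free Free-water diffusivity (1e-3 mm^2/s).
#' @param snr Signal-to-noise ratio S0 / sigma at b = 0; `Inf` = noise-free.
#' @param S0 b = 0 intensity inside tissue.
#' @param shell_bvals,dirs_per_shell Acquisition scheme passed to
#'   [make_gradient_table()].
#' @param roi_radius_mm Spherical ROI radius (2.5 mm = 5 mm diameter).
#' @param md_het_sd SD of the per-voxel multiplicative diffusivity
#'   heterogeneity inside white matter (0 = homogeneous blocks).
#' @param seed Integer seed for directions, noise and heterogeneity.
#' @return A named list of phantom parameters.
#' @export
alps_phantom_config <- function(grid_size = c(40L, 40L, 40L), voxel_mm = 1,
                                g = 0.5, f_fw = 0.1, f_pv_max = 0.2,
                                tissue_axial = 1.4, tissue_radial = 0.4,
                                d_pv_base = 1.0, d_free = 3.0,
                                snr = 30, S0 = 100,
                                shell_bvals = c(0, 500, 1000, 2000),
                                dirs_per_shell = c(1, 6, 48, 60),
                                roi_radius_mm = 2.5,
                                md_het_sd = 0, seed = 1L) {
  as.list(environment())
}

# The four block mixtures (left/right are identical: axis-aligned tensors
# are mirror symmetric).
phantom_block_mixture <- function(cfg, fiber = c("projection", "association")) {
  fiber <- match.arg(fiber)
  f_pv <- cfg$g * cfg$f_pv_max
  f_t <- 1 - cfg$f_fw - f_pv
  if (f_t < 0) {
    perialps_abort("f_fw + g * f_pv_max exceeds 1.", "perialps_invalid_config")
  }
  axis <- if (fiber == "projection") "z" else "y"
  mix <- list(compartment(f_t, axial_tensor(cfg$tissue_axial, cfg$tissue_radial, axis)))
  if (f_pv > 0) {
    d_pv <- cfg$d_pv_base + cfg$g * (cfg$d_free - cfg$d_pv_base)
    mix <- c(mix, list(compartment(f_pv, axial_tensor(d_pv, cfg$tissue_radial, "x"))))
  }
  if (cfg$f_fw > 0) mix <- c(mix, list(compartment(cfg$f_fw, cfg$d_free)))
  mix
}

# Voxel-index ranges of the four blocks, scaled to the grid.
phantom_block_ranges <- function(grid_size) {
  sc <- function(lo, hi, n) max(1L, round(lo * n)):min(n, round(hi * n))
  list(
    x_left = sc(0.10, 0.45, grid_size[1]),
    x_right = sc(0.55, 0.90, grid_size[1]),
    y_proj = sc(0.15, 0.44, grid_size[2]),
    y_assoc = sc(0.56, 0.85, grid_size[2]),
    z = sc(0.35, 0.65, grid_size[3])
  )
}

#' Rasterize a spherical ROI on a voxel grid
#'
#' Membership by voxel-center distance: voxel (i, j, k) with center
#' ((i-1) * voxel_mm, ...) is included when its center lies within
#' `radius_mm` of `center_mm`.
#'
#' @param grid_size Integer length-3.
#' @param center_mm Sphere center in mm (grid frame, voxel 1 at 0 mm).
#' @param radius_mm Sphere radius in mm (> 0).
#' @param voxel_mm Isotropic voxel size.
#' @return Logical 3D array.
#' @export
sphere_mask <- function(grid_size, center_mm, radius_mm, voxel_mm = 1) {
  if (radius_mm <= 0) {
    perialps_abort("ROI radius must be positive.", "perialps_invalid_config")
  }
  cx <- (seq_len(grid_size[1]) - 1) * voxel_mm
  cy <- (seq_len(grid_size[2]) - 1) * voxel_mm
  cz <- (seq_len(grid_size[3]) - 1) * voxel_mm
  dx2 <- (cx - center_mm[1])^2
  dy2 <- (cy - center_mm[2])^2
  dz2 <- (cz - center_mm[3])^2
  arr <- outer(outer(dx2, dy2, `+`), dz2, `+`)
  arr <= radius_mm^2
}

#' Build the ALPS phantom volume with analytic ground truth
#'
#' @param config List from [alps_phantom_config()].
#' @return An object of class `alps_phantom`: `signal` (4D array), `gtab`,
#'   `region_labels` (0 background, 1 projection, 2 association), `roi_masks`
#'   (named list of four logical arrays), `wm_mask`, `truth` (analytic
#'   per-block directional diffusivities/kurtoses, the mixtures, and the
#'   analytic DTI-/DKI-ALPS indices) and the `config` itself.
#' @export
build_alps_phantom <- function(config = alps_phantom_config()) {
  cfg <- config
  if (cfg$g < 0 || cfg$g > 1 || cfg$f_fw < 0 || cfg$f_fw > 1) {
    perialps_abort("g and f_fw must lie in [0, 1].", "perialps_invalid_config")
  }
  gs <- as.integer(cfg$grid_size)
  br <- phantom_block_ranges(gs)
  block_extent_mm <- cfg$voxel_mm *
    min(length(br$x_left), length(br$x_right),
        length(br$y_proj), length(br$y_assoc), length(br$z))
  if (2 * cfg$roi_radius_mm >= block_extent_mm) {
    perialps_abort("ROI radius exceeds the phantom block size.",
                   "perialps_invalid_config")
  }

  gtab <- make_gradient_table(cfg$shell_bvals, cfg$dirs_per_shell,
                              seed = cfg$seed)
  labels <- array(0L, gs)
  labels[br$x_left, br$y_proj, br$z] <- 1L
  labels[br$x_right, br$y_proj, br$z] <- 1L
  labels[br$x_left, br$y_assoc, br$z] <- 2L
  labels[br$x_right, br$y_assoc, br$z] <- 2L
  wm_mask <- labels > 0L

  mixes <- list(projection = phantom_block_mixture(cfg, "projection"),
                association = phantom_block_mixture(cfg, "association"))

  nvol <- nrow(gtab)
  signal <- array(0, c(gs, nvol))

  # per-voxel multiplicative diffusivity heterogeneity (seeded)
  het <- NULL
  if (cfg$md_het_sd > 0) {
    het <- with_seed(cfg$seed + 1L, {
      h <- array(1, gs)
      h[wm_mask] <- pmax(0.1, 1 + rnorm(sum(wm_mask), sd = cfg$md_het_sd))
      h
    })
  }

  smat <- matrix(signal, prod(gs), nvol)
  dirs <- gtab_dirs(gtab)
  b3 <- gtab$bval * 1e-3
  for (lab in c(1L, 2L)) {
    mix <- mixes[[lab]]
    vox <- which(labels == lab)
    expo <- vapply(mix, function(cp) -b3 * rowSums((dirs %*% cp$tensor) * dirs),
                   numeric(nvol))                       # nvol x ncomp
    fr <- vapply(mix, `[[`, numeric(1), "fraction")
    if (is.null(het)) {
      base <- cfg$S0 * drop(exp(expo) %*% fr)
      smat[vox, ] <- matrix(base, length(vox), nvol, byrow = TRUE)
    } else {
      s <- het[vox]
      acc <- matrix(0, length(vox), nvol)
      for (ci in seq_along(mix)) {
        acc <- acc + fr[ci] * exp(outer(s, expo[, ci]))
      }
      smat[vox, ] <- cfg$S0 * acc
    }
  }
  signal <- array(smat, c(gs, nvol))

  if (is.finite(cfg$snr)) {
    sigma <- cfg$S0 / cfg$snr
    signal <- add_rician_noise(signal, sigma, seed = cfg$seed + 2L)
  }

  # ROI masks centred in each block, one per hemisphere x fiber
  ctr <- function(xr, yr) (c(mean(range(xr)), mean(range(yr)), mean(range(br$z))) - 1) * cfg$voxel_mm
  centers <- list(
    left_projection = ctr(br$x_left, br$y_proj),
    right_projection = ctr(br$x_right, br$y_proj),
    left_association = ctr(br$x_left, br$y_assoc),
    right_association = ctr(br$x_right, br$y_assoc)
  )
  roi_masks <- lapply(centers, function(cc)
    sphere_mask(gs, cc, cfg$roi_radius_mm, cfg$voxel_mm))
  for (nm in names(roi_masks)) {
    fiber_lab <- if (grepl("projection", nm)) 1L else 2L
    if (any(labels[roi_masks[[nm]]] != fiber_lab)) {
      perialps_abort("ROI extends beyond its fiber block.", "perialps_invalid_config")
    }
  }

  ax <- list(x = c(1, 0, 0), y = c(0, 1, 0), z = c(0, 0, 1))
  dir_stats <- lapply(mixes, function(mix)
    lapply(ax, function(n) analytic_directional_stats(mix, n)))
  truth <- list(
    g = cfg$g, f_fw = cfg$f_fw,
    mixtures = mixes,
    D = lapply(dir_stats, function(s) vapply(s, `[[`, numeric(1), "D")),
    K = lapply(dir_stats, function(s) vapply(s, `[[`, numeric(1), "K")),
    dti_alps = alps_index(dir_stats$projection$x$D, dir_stats$association$x$D,
                          dir_stats$projection$y$D, dir_stats$association$z$D),
    dki_alps = tryCatch(
      alps_index(dir_stats$projection$x$K, dir_stats$association$x$K,
                 dir_stats$projection$y$K, dir_stats$association$z$K),
      perialps_error = function(e) NA_real_  # zero kurtosis: ratio undefined
    )
  )

  structure(list(signal = signal, gtab = gtab, region_labels = labels,
                 roi_masks = roi_masks, roi_centers_mm = centers,
                 wm_mask = wm_mask, truth = truth, config = cfg),
            class = "alps_phantom")
}

#' ROI set of a phantom, in the form [compute_alps()] expects
#'
#' @param phantom An `alps_phantom`.
#' @return A named list of four logical ROI masks.
#' @export
phantom_roi_set <- function(phantom) {
  roi_set(masks = phantom$roi_masks)
}
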