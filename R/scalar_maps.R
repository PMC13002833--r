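# Voxel-wise model fitting over 3D grids and scalar-map assembly.

#' Fit DTI or DKI voxel-wise over a 4D volume and assemble scalar maps
#'
#' The OLS pass is vectorized across voxels; the per-voxel weighted pass
#' solves the normal equations with voxel-specific weights. Voxels outside
#' the mask carry NA in every output map.
#'
#' @param signal4d 4D numeric array (x, y, z, volume).
#' @param gtab A [gradient_table()] with one row per volume.
#' @param mask Logical/0-1 3D array of voxels to fit; default fits voxels
#'   whose b = 0 mean intensity is positive.
#' @param model `"dti"` or `"dki"`.
#' @param shells Optional b-value subset passed to the fitters.
#' @param convention Kurtosis convention for DKI maps (see
#'   [directional_kurtosis()]).
#' @return An object of class `dwi_scalar_maps`: a list of 3D arrays
#'   `fa`, `md`, `dxx`, `dyy`, `dzz` (plus `kxxxx`, `kyyyy`, `kzzzz` for
#'   DKI), together with `model` and `mask`.
#' @export
fit_dwi_volume <- function(signal4d, gtab, mask = NULL,
                           model = c("dti", "dki"), shells = NULL,
                           convention = c("apparent", "raw")) {
  model <- match.arg(model)
  convention <- match.arg(convention)
  dims <- dim(signal4d)
  if (length(dims) != 4L || dims[4] != nrow(gtab)) {
    perialps_abort("`signal4d` must be 4D with one volume per gradient-table row.",
                   "perialps_invalid_input")
  }
  smat <- matrix(signal4d, prod(dims[1:3]), dims[4])
  if (is.null(mask)) {
    b0 <- gtab$bval == 0
    mask <- array(rowMeans(smat[, b0, drop = FALSE]) > 0, dims[1:3])
  }
  if (!all(dim(mask) == dims[1:3])) {
    perialps_abort("`mask` shape does not match the volume grid.",
                   "perialps_invalid_input")
  }
  vox <- which(as.logical(mask))
  if (!length(vox)) {
    perialps_abort("Mask is empty.", "perialps_invalid_input")
  }
  if (!is.null(shells)) {
    keep <- gtab$bval %in% shells
    gtab <- gtab[keep, , drop = FALSE]
    smat <- smat[, keep, drop = FALSE]
  }

  X <- if (model == "dti") dti_design(gtab) else dki_design(gtab)
  p <- ncol(X)
  qx <- qr(X)
  if (qx$rank < p) {
    perialps_abort("Rank-deficient design for the requested model.",
                   "perialps_singular_design")
  }

  Y <- t(smat[vox, , drop = FALSE])            # nvol x nvox
  b0rows <- gtab$bval == 0
  ref <- colMeans(Y[b0rows, , drop = FALSE])
  Y <- pmax(Y, rep(1e-6 * pmax(ref, .Machine$double.eps), each = nrow(Y)))
  logY <- log(Y)

  B0 <- qr.coef(qx, logY)                      # OLS, all voxels at once
  Wt <- exp(2 * (X %*% B0))                    # per-voxel weights

  # normal-equation pieces for every voxel via one contraction each
  O <- matrix(0, nrow(X), p * p)
  for (q in seq_len(nrow(X))) O[q, ] <- as.vector(tcrossprod(X[q, ]))
  A <- crossprod(O, Wt)                        # p^2 x nvox
  R <- crossprod(X, Wt * logY)                 # p  x nvox

  nvox <- length(vox)
  out_names <- c("fa", "md", "dxx", "dyy", "dzz",
                 if (model == "dki") c("kxxxx", "kyyyy", "kzzzz"))
  vals <- matrix(NA_real_, nvox, length(out_names))
  colnames(vals) <- out_names
  for (v in seq_len(nvox)) {
    beta <- tryCatch(
      solve(matrix(A[, v], p, p), R[, v]),
      error = function(e) rep(NA_real_, p)
    )
    if (anyNA(beta)) next
    D <- tensor_from_coef(beta[2:7])
    sc <- fa_md_from_tensor(D)
    vals[v, "fa"] <- sc$fa
    vals[v, "md"] <- sc$md
    vals[v, "dxx"] <- D[1, 1]
    vals[v, "dyy"] <- D[2, 2]
    vals[v, "dzz"] <- D[3, 3]
    if (model == "dki") {
      V <- beta[8:22]
      dax <- c(D[1, 1], D[2, 2], D[3, 3])
      k <- if (convention == "apparent") {
        # V = MD^2 W, so K(axis) = V_axis / D_axis^2
        V[1:3] / dax^2
      } else {
        if (sc$md > 0) V[1:3] / sc$md^2 else rep(NA_real_, 3)
      }
      k[dax <= 0] <- NA_real_
      vals[v, c("kxxxx", "kyyyy", "kzzzz")] <- k
    }
  }

  maps <- lapply(out_names, function(nm) {
    m <- array(NA_real_, dims[1:3])
    m[vox] <- vals[, nm]
    m
  })
  names(maps) <- out_names
  structure(c(maps, list(model = model, mask = array(as.logical(mask), dims[1:3]),
                         convention = convention)),
            class = "dwi_scalar_maps")
}

#' Assemble per-voxel fit objects into scalar volumes
#'
#' @param fits List of `dti_fit`/`dki_fit` objects, one per in-mask voxel in
#'   `which(mask)` order.
#' @param mask Logical 3D array; `sum(mask)` must equal `length(fits)`.
#' @return A `dwi_scalar_maps` object (NA outside the mask).
#' @export
scalar_volumes <- function(fits, mask) {
  vox <- which(as.logical(mask))
  if (length(vox) != length(fits)) {
    perialps_abort("Number of fits does not match the mask voxel count.",
                   "perialps_invalid_input")
  }
  is_dki <- length(fits) > 0 && inherits(fits[[1]], "dki_fit")
  out_names <- c("fa", "md", "dxx", "dyy", "dzz",
                 if (is_dki) c("kxxxx", "kyyyy", "kzzzz"))
  maps <- lapply(out_names, function(nm) {
    m <- array(NA_real_, dim(mask))
    m[vox] <- vapply(fits, function(f) f[[nm]], numeric(1))
    m
  })
  names(maps) <- out_names
  structure(c(maps, list(model = if (is_dki) "dki" else "dti",
                         mask = array(as.logical(mask), dim(mask)),
                         convention = if (is_dki) fits[[1]]$convention else NULL)),
            class = "dwi_scalar_maps")
}
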