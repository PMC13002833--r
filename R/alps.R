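# DTI-ALPS and DKI-ALPS index computation from scalar maps and four
# spherical ROIs (left/right x projection/association).

.roi_names <- c("left_projection", "right_projection",
                "left_association", "right_association")

#' Define the four ALPS regions of interest
#'
#' Either explicit binary masks or sphere specifications (center + radius)
#' can be supplied, keyed `left_projection`, `right_projection`,
#' `left_association`, `right_association`.
#'
#' @param centers_mm Optional named list of length-3 mm coordinates.
#' @param radius_mm Sphere radius in mm (default 2.5, i.e. 5 mm diameter).
#' @param masks Optional named list of logical 3D arrays (overrides centers).
#' @param voxel_mm Isotropic voxel size used to rasterize spheres.
#' @return An object of class `roi_set`.
#' @export
roi_set <- function(centers_mm = NULL, radius_mm = 2.5, masks = NULL,
                    voxel_mm = 1) {
  if (is.null(masks) && is.null(centers_mm)) {
    perialps_abort("Provide either `centers_mm` or `masks`.",
                   "perialps_invalid_config")
  }
  src <- if (!is.null(masks)) masks else centers_mm
  if (!all(.roi_names %in% names(src))) {
    perialps_abort(paste("ROI set must contain:", paste(.roi_names, collapse = ", ")),
                   "perialps_invalid_config")
  }
  if (!is.null(masks)) {
    for (nm in .roi_names) {
      if (!sum(masks[[nm]])) {
        perialps_abort(sprintf("ROI mask '%s' is empty.", nm), "perialps_empty_roi")
      }
    }
    pj <- masks$left_projection | masks$right_projection
    as_ <- masks$left_association | masks$right_association
    if (any(pj & as_)) {
      perialps_abort("Projection and association ROIs overlap.",
                     "perialps_invalid_config")
    }
  }
  if (radius_mm <= 0) {
    perialps_abort("ROI radius must be positive.", "perialps_invalid_config")
  }
  structure(list(centers_mm = centers_mm, radius_mm = radius_mm,
                 masks = masks, voxel_mm = voxel_mm),
            class = "roi_set")
}

roi_mask_for <- function(rois, name, grid_size) {
  if (!is.null(rois$masks)) return(as.logical(rois$masks[[name]]) |> array(grid_size))
  sphere_mask(grid_size, rois$centers_mm[[name]], rois$radius_mm, rois$voxel_mm)
}

#' Mean of a scalar map over an ROI
#'
#' Sentinel (NA) voxels inside the ROI are excluded; sphere membership is by
#' voxel-center distance.
#'
#' @param map Numeric 3D array (NA outside the fitted mask).
#' @param roi Logical 3D array, or a list with `center_mm` and `radius_mm`.
#' @param voxel_mm Isotropic voxel size (sphere ROIs only).
#' @return Scalar mean.
#' @export
extract_roi_mean <- function(map, roi, voxel_mm = 1) {
  mask <- if (is.list(roi)) {
    sphere_mask(dim(map), roi$center_mm, roi$radius_mm, voxel_mm)
  } else {
    as.logical(roi)
  }
  if (!isTRUE(all(dim(map) == dim(array(mask, dim(map)))))) {
    mask <- array(mask, dim(map))
  }
  vals <- map[mask]
  vals <- vals[is.finite(vals)]
  if (!length(vals)) {
    perialps_abort("ROI contains no finite map voxels.", "perialps_empty_roi")
  }
  mean(vals)
}

#' The ALPS ratio
#'
#' mean of the two x-axis values (perivascular direction in both fiber
#' systems) over the mean of the cross-fiber values (y in the projection
#' area, z in the association area). The same ratio applied to diffusion
#' tensor axis diffusivities gives DTI-ALPS and applied to directional
#' kurtoses gives DKI-ALPS.
#'
#' @param x_proj,x_assoc x-axis values in the projection/association ROI.
#' @param y_proj y-axis value in the projection ROI.
#' @param z_assoc z-axis value in the association ROI.
#' @return Unitless index.
#' @export
alps_index <- function(x_proj, x_assoc, y_proj, z_assoc) {
  vals <- c(x_proj, x_assoc, y_proj, z_assoc)
  if (any(!is.finite(vals))) {
    perialps_abort("ALPS inputs must be finite.", "perialps_invalid_input")
  }
  den <- mean(c(y_proj, z_assoc))
  if (den <= 0) {
    perialps_abort("ALPS denominator mean(y_proj, z_assoc) must be positive.",
                   "perialps_degenerate_denominator")
  }
  mean(c(x_proj, x_assoc)) / den
}

#' Compute per-hemisphere and bilateral ALPS indices from scalar maps
#'
#' @param maps A `dwi_scalar_maps` object (or a plain list of arrays with
#'   `dxx`, `dyy`, `dzz` and optionally `kxxxx`, `kyyyy`, `kzzzz`).
#' @param rois A [roi_set()].
#' @param voxel_mm Isotropic voxel size for sphere ROIs.
#' @param invert_kurtosis If `TRUE`, the DKI-ALPS ratio is computed with the
#'   reciprocal orientation (cross-fiber kurtoses over x-axis kurtoses); the
#'   default substitutes the directional kurtoses literally into the ALPS
#'   ratio.
#' @return An object of class `alps_result` with the ROI means behind each
#'   index and `dti_alps_left/right/mean` (plus the `dki_*` analogues when
#'   kurtosis maps are present). Use [tidy.alps_result()] for a tibble.
#' @export
compute_alps <- function(maps, rois, voxel_mm = 1, invert_kurtosis = FALSE) {
  gs <- dim(maps$dxx)
  roi_mean <- function(map_name, roi_name) {
    m <- roi_mask_for(rois, roi_name, gs)
    tryCatch(
      extract_roi_mean(maps[[map_name]], m),
      perialps_empty_roi = function(e) {
        perialps_abort(sprintf("ROI '%s': %s", roi_name, conditionMessage(e)),
                       "perialps_empty_roi")
      }
    )
  }
  hemi_index <- function(prefix, side) {
    x_proj <- roi_mean(paste0(prefix, "xx", if (prefix == "k") "xx"),
                       paste0(side, "_projection"))
    x_assoc <- roi_mean(paste0(prefix, "xx", if (prefix == "k") "xx"),
                        paste0(side, "_association"))
    y_proj <- roi_mean(paste0(prefix, "yy", if (prefix == "k") "yy"),
                       paste0(side, "_projection"))
    z_assoc <- roi_mean(paste0(prefix, "zz", if (prefix == "k") "zz"),
                        paste0(side, "_association"))
    idx <- if (prefix == "k" && invert_kurtosis) {
      alps_index(y_proj, z_assoc, x_proj, x_assoc)
    } else {
      alps_index(x_proj, x_assoc, y_proj, z_assoc)
    }
    list(index = idx,
         rois = c(x_proj = x_proj, x_assoc = x_assoc,
                  y_proj = y_proj, z_assoc = z_assoc))
  }

  res <- list(voxel_mm = voxel_mm, invert_kurtosis = invert_kurtosis)
  left <- hemi_index("d", "left")
  right <- hemi_index("d", "right")
  res$dti_rois <- list(left = left$rois, right = right$rois)
  res$dti_alps_left <- left$index
  res$dti_alps_right <- right$index
  res$dti_alps_mean <- (left$index + right$index) / 2

  if (!is.null(maps$kxxxx)) {
    kl <- hemi_index("k", "left")
    kr <- hemi_index("k", "right")
    res$dki_rois <- list(left = kl$rois, right = kr$rois)
    res$dki_alps_left <- kl$index
    res$dki_alps_right <- kr$index
    res$dki_alps_mean <- (kl$index + kr$index) / 2
  }
  structure(res, class = "alps_result")
}

#' Tidy an ALPS result into a one-row tibble
#'
#' @param x An `alps_result`.
#' @param ... Unused.
#' @return One-row tibble of the left/right/bilateral indices.
#' @exportS3Method generics::tidy
tidy.alps_result <- function(x, ...) {
  cols <- c("dti_alps_left", "dti_alps_right", "dti_alps_mean",
            "dki_alps_left", "dki_alps_right", "dki_alps_mean")
  present <- cols[cols %in% names(x)]
  tibble::as_tibble(setNames(lapply(present, function(nm) x[[nm]]), present))
}

#' @export
print.alps_result <- function(x, ...) {
  cat("ALPS indices\n")
  cat(sprintf("  DTI-ALPS  left %.4f  right %.4f  mean %.4f\n",
              x$dti_alps_left, x$dti_alps_right, x$dti_alps_mean))
  if (!is.null(x$dki_alps_mean)) {
    cat(sprintf("  DKI-ALPS  left %.4f  right %.4f  mean %.4f%s\n",
                x$dki_alps_left, x$dki_alps_right, x$dki_alps_mean,
                if (x$invert_kurtosis) "  (inverted orientation)" else ""))
  }
  invisible(x)
}
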