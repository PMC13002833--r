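# Diffusion (DTI) and kurtosis (DKI) tensor fitting by two-pass weighted
# least squares on the log-linearized signal models.
#
# DTI:  ln S(b, n) = ln S0 - b * n' D n
# DKI:  ln S(b, n) = ln S0 - b * D(n) + (1/6) b^2 * D(n)^2 * K(n)
# with D(n)^2 K(n) = MD^2 * W(n); the DKI model is linear in the 22
# parameters (ln S0, 6 tensor elements, 15 elements of MD^2 * W).
# Diffusivities are in 1e-3 mm^2/s throughout.

# Unique-element bookkeeping for the symmetric rank-4 kurtosis tensor.
.w_names <- c("xxxx", "yyyy", "zzzz",
              "xxxy", "xxxz", "xyyy", "yyyz", "xzzz", "yzzz",
              "xxyy", "xxzz", "yyzz",
              "xxyz", "xyyz", "xyzz")
.w_mult <- c(1, 1, 1, 4, 4, 4, 4, 4, 4, 6, 6, 6, 12, 12, 12)
# exponents of (nx, ny, nz) per unique element
.w_pow <- rbind(
  c(4, 0, 0), c(0, 4, 0), c(0, 0, 4),
  c(3, 1, 0), c(3, 0, 1), c(1, 3, 0), c(0, 3, 1), c(1, 0, 3), c(0, 1, 3),
  c(2, 2, 0), c(2, 0, 2), c(0, 2, 2),
  c(2, 1, 1), c(1, 2, 1), c(1, 1, 2)
)

# n' W n n n contraction weights for a direction matrix (rows = directions)
w_monomials <- function(dirs) {
  out <- matrix(0, nrow(dirs), 15L)
  for (k in seq_len(15L)) {
    out[, k] <- .w_mult[k] *
      dirs[, 1]^.w_pow[k, 1] * dirs[, 2]^.w_pow[k, 2] * dirs[, 3]^.w_pow[k, 3]
  }
  colnames(out) <- .w_names
  out
}

d_monomials <- function(dirs) {
  cbind(xx = dirs[, 1]^2, yy = dirs[, 2]^2, zz = dirs[, 3]^2,
        xy = 2 * dirs[, 1] * dirs[, 2],
        xz = 2 * dirs[, 1] * dirs[, 3],
        yz = 2 * dirs[, 2] * dirs[, 3])
}

dti_design <- function(gtab) {
  b3 <- gtab$bval * 1e-3
  cbind(lnS0 = 1, -b3 * d_monomials(gtab_dirs(gtab)))
}

dki_design <- function(gtab) {
  b3 <- gtab$bval * 1e-3
  dirs <- gtab_dirs(gtab)
  cbind(lnS0 = 1, -b3 * d_monomials(dirs), (b3^2 / 6) * w_monomials(dirs))
}

clamp_signal <- function(signal, gtab) {
  if (any(!is.finite(signal))) {
    perialps_abort("Signal contains non-finite values.", "perialps_invalid_input")
  }
  s0 <- signal[gtab$bval == 0]
  ref <- if (length(s0)) mean(s0) else max(signal)
  pmax(signal, 1e-6 * ref)
}

# Two-pass WLS solve: OLS on log-signal, then weights = squared predicted
# signal from the OLS pass.
wls_solve <- function(X, logs) {
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    perialps_abort("Rank-deficient design: not enough independent directions/shells.",
                   "perialps_singular_design")
  }
  b_ols <- qr.coef(qx, logs)
  w <- exp(2 * drop(X %*% b_ols))
  xw <- X * w
  drop(solve(crossprod(xw, X), crossprod(xw, logs)))
}

tensor_from_coef <- function(d6) {
  matrix(c(d6[1], d6[4], d6[5],
           d6[4], d6[2], d6[6],
           d6[5], d6[6], d6[3]), 3, 3)
}

fa_md_from_tensor <- function(D) {
  ev <- eigen(D, symmetric = TRUE, only.values = TRUE)$values
  ev <- pmax(ev, 0)  # clip for scalar derivation only; raw tensor retained
  md <- mean(ev)
  ss <- sum(ev^2)
  fa <- if (ss > 0) sqrt(1.5 * sum((ev - md)^2) / ss) else 0
  list(fa = min(fa, 1), md = md, evals = ev)
}

#' Fit a diffusion tensor by two-pass weighted least squares
#'
#' An ordinary-least-squares pass on the log signal provides predicted
#' signals whose squares serve as the weights of the definitive weighted
#' pass (the standard heteroscedasticity correction for log-linearized
#' diffusion models). Intensities are floored at 1e-6 * S0 before taking
#' logs.
#'
#' @param signal Numeric vector, one intensity per gradient-table row.
#' @param gtab A [gradient_table()] with at least 7 volumes, one of them
#'   b = 0, spanning at least 6 non-collinear directions.
#' @param shells Optional numeric vector of b-values to restrict the fit to
#'   (e.g. `c(0, 500, 1000)` to keep the Gaussian model in its validity
#'   range on multi-shell data).
#' @return An object of class `dti_fit`: S0, the raw tensor `D`
#'   (1e-3 mm^2/s), clipped eigenvalues, `fa`, `md` and the axis
#'   diffusivities `dxx`, `dyy`, `dzz`.
#' @export
fit_dti_wls <- function(signal, gtab, shells = NULL) {
  if (!is.null(shells)) {
    keep <- gtab$bval %in% shells
    signal <- signal[keep]
    gtab <- gtab[keep, , drop = FALSE]
  }
  if (nrow(gtab) < 7L || !any(gtab$bval == 0)) {
    perialps_abort("DTI needs >= 7 volumes including a b = 0 volume.",
                   "perialps_invalid_input")
  }
  s <- clamp_signal(signal, gtab)
  beta <- wls_solve(dti_design(gtab), log(s))
  D <- tensor_from_coef(beta[2:7])
  sc <- fa_md_from_tensor(D)
  structure(list(
    S0 = exp(beta[[1]]), D = D, evals = sc$evals,
    fa = sc$fa, md = sc$md,
    dxx = D[1, 1], dyy = D[2, 2], dzz = D[3, 3]
  ), class = "dti_fit")
}

#' Fit a diffusion-kurtosis model by two-pass weighted least squares
#'
#' Fits the 22-parameter log-linearized DKI model. The 15 quartic
#' coefficients estimate MD^2 * W; the returned `W` is scaled back by the
#' fitted MD so that directional kurtoses follow the apparent-kurtosis
#' convention K(n) = (MD / D(n))^2 * W(n).
#'
#' @inheritParams fit_dti_wls
#' @param convention `"apparent"` (default) reports K_xxxx etc. as
#'   directional apparent kurtoses; `"raw"` reports the raw tensor elements
#'   W_xxxx etc. instead.
#' @param floor_kurtosis If `TRUE`, reported axis kurtoses are floored at 0
#'   (a post-hoc floor, not a constrained fit; the unconstrained fit is the
#'   default).
#' @return An object of class `dki_fit` with S0, `D`, `W` (named 15-vector),
#'   `fa`, `md`, axis diffusivities and axis kurtoses `kxxxx`, `kyyyy`,
#'   `kzzzz`.
#' @export
fit_dki_wls <- function(signal, gtab, shells = NULL,
                        convention = c("apparent", "raw"),
                        floor_kurtosis = FALSE) {
  convention <- match.arg(convention)
  if (!is.null(shells)) {
    keep <- gtab$bval %in% shells
    signal <- signal[keep]
    gtab <- gtab[keep, , drop = FALSE]
  }
  nshell <- length(unique(gtab$bval[gtab$bval > 0]))
  if (nshell < 2L) {
    perialps_abort("DKI needs at least two nonzero b-shells.",
                   "perialps_identifiability_error")
  }
  if (nrow(gtab) < 22L) {
    perialps_abort("DKI needs at least 22 volumes.", "perialps_invalid_input")
  }
  s <- clamp_signal(signal, gtab)
  beta <- wls_solve(dki_design(gtab), log(s))
  D <- tensor_from_coef(beta[2:7])
  V <- beta[8:22]                      # MD^2 * W elements
  sc <- fa_md_from_tensor(D)
  md <- sc$md
  W <- if (md > 0) V / md^2 else V * NA_real_
  names(W) <- .w_names
  fit <- structure(list(
    S0 = exp(beta[[1]]), D = D, W = W, V = setNames(V, .w_names),
    evals = sc$evals, fa = sc$fa, md = md,
    dxx = D[1, 1], dyy = D[2, 2], dzz = D[3, 3],
    convention = convention
  ), class = "dki_fit")
  fit$kxxxx <- directional_kurtosis(fit, c(1, 0, 0), convention)
  fit$kyyyy <- directional_kurtosis(fit, c(0, 1, 0), convention)
  fit$kzzzz <- directional_kurtosis(fit, c(0, 0, 1), convention)
  if (floor_kurtosis) {
    fit$kxxxx <- max(fit$kxxxx, 0)
    fit$kyyyy <- max(fit$kyyyy, 0)
    fit$kzzzz <- max(fit$kzzzz, 0)
  }
  fit
}

#' Directional kurtosis of a fitted DKI model
#'
#' Apparent convention: K(n) = (MD / D(n))^2 * W(n) with
#' W(n) = sum over ijkl of n_i n_j n_k n_l W_ijkl. Raw convention returns
#' W(n) itself.
#'
#' @param fit A `dki_fit`.
#' @param direction Length-3 direction (normalized internally).
#' @param convention `"apparent"` or `"raw"`.
#' @return Unitless kurtosis value.
#' @export
directional_kurtosis <- function(fit, direction,
                                 convention = c("apparent", "raw")) {
  convention <- match.arg(convention)
  n <- unit_vector(direction)
  wn <- drop(w_monomials(matrix(n, 1, 3)) %*% fit$W)
  if (convention == "raw") return(wn)
  dn <- drop(t(n) %*% fit$D %*% n)
  if (dn <= 0) {
    perialps_abort("D(n) <= 0: directional kurtosis undefined.",
                   "perialps_undefined_kurtosis")
  }
  (fit$md / dn)^2 * wn
}

#' Simulate a signal exactly from the DKI model (for round-trip validation)
#'
#' @param D 3x3 diffusion tensor (1e-3 mm^2/s).
#' @param W Named or ordered 15-vector of unique kurtosis-tensor elements.
#' @param gtab A [gradient_table()].
#' @param S0 b = 0 intensity.
#' @return Signal vector following the truncated-cumulant DKI model exactly.
#' @export
dki_model_signal <- function(D, W, gtab, S0 = 1) {
  md <- mean(diag(D))
  beta <- c(log(S0), D[1, 1], D[2, 2], D[3, 3], D[1, 2], D[1, 3], D[2, 3],
            md^2 * W)
  drop(exp(dki_design(gtab) %*% beta))
}
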