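# Sparse functional principal component analysis (PACE-style) for irregular
# longitudinal index measurements.
#
# Pipeline: local-linear mean smoothing of pooled observations, local-linear
# smoothing of raw off-diagonal covariances, measurement-error variance from
# the smoothed diagonal, quadrature eigendecomposition with a 95%
# fraction-of-variance-explained truncation, and conditional-expectation
# (best linear predictor) subject scores.

# Gaussian-kernel local linear smoother evaluated on `grid`.
loclin1d <- function(x, y, grid, bw, w = NULL) {
  if (bw <= 0) perialps_abort("Bandwidth must be positive.", "perialps_invalid_config")
  if (is.null(w)) w <- rep(1, length(x))
  vapply(grid, function(g) {
    u <- (x - g) / bw
    k <- w * exp(-0.5 * u^2)
    sw <- sum(k); swx <- sum(k * u); swx2 <- sum(k * u^2)
    swy <- sum(k * y); swxy <- sum(k * u * y)
    det <- sw * swx2 - swx^2
    if (det <= .Machine$double.eps * sw^2) {
      # degenerate local design: fall back to the local constant estimate
      if (sw <= 0) return(NA_real_)
      return(swy / sw)
    }
    (swx2 * swy - swx * swxy) / det
  }, numeric(1))
}

# Local linear smoother on a symmetric surface: fit a local plane at each
# (s, t) grid pair from scattered raw points (xs, xt, z). The bandwidth is
# locally inflated where the effective number of kernel-weighted points
# falls below `ess_min` (domain corners of sparse designs), trading
# resolution for variance where raw pairs are scarce.
loclin2d_sym <- function(xs, xt, z, grid, bw, ess_min = 150) {
  G <- length(grid)
  out <- matrix(NA_real_, G, G)
  for (i in seq_len(G)) {
    du_all <- xs - grid[i]
    for (j in i:G) {
      dv_all <- xt - grid[j]
      est <- NA_real_
      for (mult in c(1, 1.5, 2, 3, 5)) {
        bwl <- bw * mult
        u <- du_all / bwl
        v <- dv_all / bwl
        k <- exp(-0.5 * (u^2 + v^2))
        s0 <- sum(k)
        ess <- s0^2 / sum(k^2)
        if (ess < ess_min && mult < 5) next
        su <- sum(k * u); sv <- sum(k * v)
        suu <- sum(k * u^2); svv <- sum(k * v^2); suv <- sum(k * u * v)
        sz <- sum(k * z); suz <- sum(k * u * z); svz <- sum(k * v * z)
        A <- matrix(c(s0, su, sv, su, suu, suv, sv, suv, svv), 3, 3)
        est <- tryCatch(solve(A, c(sz, suz, svz))[1],
                        error = function(e) if (s0 > 0) sz / s0 else NA_real_)
        break
      }
      out[i, j] <- est
      out[j, i] <- est
    }
  }
  out
}

check_series <- function(data, id_col, time_col, value_col) {
  for (cl in c(id_col, time_col, value_col)) {
    if (!cl %in% names(data)) {
      perialps_abort(sprintf("Column '%s' not found.", cl), "perialps_invalid_input")
    }
  }
  ok <- is.finite(data[[time_col]]) & is.finite(data[[value_col]])
  data[ok, , drop = FALSE]
}

#' Estimate the population mean function by local linear smoothing
#'
#' @param data Long-format data frame of longitudinal observations.
#' @param grid Evaluation grid (numeric vector).
#' @param bandwidth Kernel bandwidth (time units); default 10% of the grid
#'   range.
#' @param id_col,time_col,value_col Column names.
#' @return Numeric vector `mu` on the grid.
#' @export
estimate_mean_function <- function(data, grid, bandwidth = NULL,
                                   id_col = "subject_id", time_col = "age",
                                   value_col = "value") {
  data <- check_series(data, id_col, time_col, value_col)
  t_all <- data[[time_col]]; y_all <- data[[value_col]]
  if (length(t_all) < 10L) {
    perialps_abort("Mean estimation needs at least 10 pooled observations.",
                   "perialps_invalid_input")
  }
  if (length(unique(t_all)) < 2L) {
    perialps_abort("All observations share one time point.",
                   "perialps_degenerate_design")
  }
  if (is.null(bandwidth)) bandwidth <- 0.10 * diff(range(grid))
  loclin1d(t_all, y_all, grid, bandwidth)
}

#' Estimate the covariance surface and measurement-error variance
#'
#' Raw covariances (y_ij - mu(t_ij)) * (y_il - mu(t_il)) for j != l are
#' smoothed by a 2D local linear smoother (subjects with one visit cannot
#' contribute off-diagonal pairs). The diagonal of the raw second moments
#' (j = l), which includes the noise variance, is smoothed separately; the
#' average gap to the surface diagonal over the central half of the grid
#' estimates sigma^2 (floored at 0).
#'
#' @inheritParams estimate_mean_function
#' @param mu Mean function on `grid`.
#' @param bandwidth Surface bandwidth; default 15% of the grid range.
#' @return List with `surface` (G x G), `sigma2`, `n_pairs`.
#' @export
estimate_covariance_surface <- function(data, mu, grid, bandwidth = NULL,
                                        id_col = "subject_id",
                                        time_col = "age",
                                        value_col = "value") {
  data <- check_series(data, id_col, time_col, value_col)
  if (is.null(bandwidth)) bandwidth <- 0.15 * diff(range(grid))
  mu_at <- function(t) approx(grid, mu, xout = t, rule = 2)$y
  resid <- data[[value_col]] - mu_at(data[[time_col]])
  ids <- data[[id_col]]
  tt <- data[[time_col]]

  xs <- xt <- z <- numeric(0)
  for (sid in unique(ids)) {
    w <- which(ids == sid)
    if (length(w) < 2L) next
    pr <- utils::combn(w, 2L)
    a <- pr[1, ]; b <- pr[2, ]
    xs <- c(xs, tt[a], tt[b])
    xt <- c(xt, tt[b], tt[a])
    z <- c(z, rep(resid[a] * resid[b], 2L))
  }
  if (!length(z)) {
    perialps_abort("No subject has repeated visits: covariance unidentifiable.",
                   "perialps_unidentifiable_covariance")
  }
  surface <- loclin2d_sym(xs, xt, z, grid, bandwidth)
  surface <- (surface + t(surface)) / 2

  diag_n <- loclin1d(tt, resid^2, grid, bandwidth)
  G <- length(grid)
  central <- seq(ceiling(G * 0.25), floor(G * 0.75))
  sigma2 <- max(0, mean(diag_n[central] - diag(surface)[central], na.rm = TRUE))
  list(surface = surface, sigma2 = sigma2, n_pairs = length(z) / 2L)
}

#' Quadrature eigendecomposition of a covariance surface
#'
#' Uses uniform Riemann quadrature weights (grid spacing h), so the
#' dense-balanced limit coincides with multivariate PCA of the data matrix.
#' Negative eigenvalues are truncated to zero and excluded from the
#' fraction-of-variance-explained denominator; eigenfunctions are
#' L2-normalized with sign fixed so their integral is non-negative.
#'
#' @param surface Symmetric G x G covariance matrix on `grid`.
#' @param grid Equally spaced time grid.
#' @param fve_threshold Truncation rule: smallest K with cumulative FVE at or
#'   above this value (default 0.95).
#' @return List with `lambda` (all non-negative eigenvalues), `phi` (G x K
#'   matrix of retained eigenfunctions), `fve` (cumulative), `K`.
#' @export
eigendecompose <- function(surface, grid, fve_threshold = 0.95) {
  if (any(!is.finite(surface))) {
    perialps_abort("Covariance surface has non-finite entries.",
                   "perialps_invalid_input")
  }
  if (max(abs(surface - t(surface))) > 1e-8) {
    perialps_abort("Covariance surface must be symmetric.", "perialps_invalid_input")
  }
  h <- mean(diff(grid))
  eg <- eigen((surface + t(surface)) / 2, symmetric = TRUE)
  lambda <- eg$values * h
  keep <- lambda > 0
  lambda <- lambda[keep]
  vectors <- eg$vectors[, keep, drop = FALSE]
  if (!length(lambda)) {
    perialps_abort("Covariance surface has no positive eigenvalues.",
                   "perialps_invalid_input")
  }
  phi <- vectors / sqrt(h)                 # unit L2 norm under h-quadrature
  sgn <- ifelse(colSums(phi) * h >= 0, 1, -1)
  phi <- sweep(phi, 2, sgn, `*`)
  fve <- cumsum(lambda) / sum(lambda)
  # small epsilon so exact-threshold cases are not lost to rounding
  K <- which(fve >= fve_threshold - 1e-12)[1]
  list(lambda = lambda, phi = phi[, seq_len(K), drop = FALSE],
       phi_all = phi, fve = fve, K = K)
}

#' Conditional-expectation (BLUP) scores for one subject
#'
#' xi_i = Lambda Phi_i' (Phi_i Lambda Phi_i' + sigma2 I)^-1 (y_i - mu_i),
#' with model functions linearly interpolated at the subject's observation
#' times.
#'
#' @param times,values Subject observation times and values.
#' @param model An `fpca_model` (see [fit_fpca()]).
#' @return Numeric vector of K scores.
#' @export
fpc_scores <- function(times, values, model) {
  mu_i <- approx(model$grid, model$mu, xout = times, rule = 2)$y
  Phi <- vapply(seq_len(model$K),
                function(k) approx(model$grid, model$phi[, k], xout = times,
                                   rule = 2)$y,
                numeric(length(times)))
  Phi <- matrix(Phi, nrow = length(times))
  Lam <- diag(model$lambda[seq_len(model$K)], model$K)
  Sig <- Phi %*% Lam %*% t(Phi) + model$sigma2 * diag(length(times))
  rhs <- tryCatch(solve(Sig, values - mu_i), error = function(e) NULL)
  if (is.null(rhs)) {
    if (model$sigma2 == 0 && anyDuplicated(times)) {
      perialps_abort("Singular within-subject covariance (sigma2 = 0 with duplicated times).",
                     "perialps_singular_system")
    }
    # noiseless dense designs make Sig rank-K: use the Moore-Penrose inverse,
    # under which the BLUP reduces to the quadrature projection
    sv <- svd(Sig)
    pos <- sv$d > max(sv$d) * 1e-12
    rhs <- sv$v[, pos, drop = FALSE] %*%
      ((t(sv$u[, pos, drop = FALSE]) %*% (values - mu_i)) / sv$d[pos])
  }
  drop(Lam %*% t(Phi) %*% rhs)
}

#' Fit a sparse functional PCA model to longitudinal measurements
#'
#' Chains [estimate_mean_function()], [estimate_covariance_surface()],
#' [eigendecompose()] and [fpc_scores()]. With a fully dense balanced design
#' (every subject observed exactly on the same time points) and
#' `smoother = "auto"`, the cross-sectional sample mean and covariance are
#' used instead of kernel smoothing, which makes the decomposition coincide
#' with multivariate PCA.
#'
#' @param data Long-format data frame (one row per observation).
#' @param id_col,time_col,value_col Column names.
#' @param n_grid Number of equally spaced grid points (default 51).
#' @param bw_mean,bw_cov Bandwidths; defaults 10% / 15% of the time range.
#' @param fve_threshold FVE truncation level (default 0.95).
#' @param smoother `"auto"`, `"local"` or `"empirical"`.
#' @return Object of class `fpca_model`: `grid`, `mu`, `phi`, `lambda`,
#'   `sigma2`, `fve`, `K`, and a `scores` tibble (one row per subject).
#' @export
fit_fpca <- function(data, id_col = "subject_id", time_col = "age",
                     value_col = "value", n_grid = 51L,
                     bw_mean = NULL, bw_cov = NULL, fve_threshold = 0.95,
                     smoother = c("auto", "local", "empirical")) {
  smoother <- match.arg(smoother)
  data <- check_series(as.data.frame(data), id_col, time_col, value_col)
  tt <- data[[time_col]]
  ids <- data[[id_col]]

  times_by_subject <- split(tt, ids)
  utimes <- sort(unique(tt))
  balanced <- length(utimes) <= 256 &&
    all(vapply(times_by_subject,
               function(ti) length(ti) == length(utimes) &&
                 all(sort(ti) == utimes), logical(1)))
  use_empirical <- smoother == "empirical" || (smoother == "auto" && balanced)

  if (use_empirical) {
    if (!balanced) {
      perialps_abort("`smoother = \"empirical\"` needs a balanced dense design.",
                     "perialps_invalid_input")
    }
    grid <- utimes
    ord <- order(ids, tt)
    ymat <- matrix(data[[value_col]][ord], ncol = length(utimes), byrow = TRUE)
    mu <- colMeans(ymat)
    surface <- stats::cov(ymat)
    sigma2 <- 0
  } else {
    grid <- seq(min(tt), max(tt), length.out = n_grid)
    mu <- estimate_mean_function(data, grid, bw_mean, id_col, time_col, value_col)
    cs <- estimate_covariance_surface(data, mu, grid, bw_cov,
                                      id_col, time_col, value_col)
    surface <- cs$surface
    sigma2 <- cs$sigma2
  }

  eg <- eigendecompose(surface, grid, fve_threshold)
  model <- structure(list(
    grid = grid, mu = mu, phi = eg$phi, lambda = eg$lambda,
    sigma2 = sigma2, fve = eg$fve, K = eg$K,
    smoother = if (use_empirical) "empirical" else "local",
    value_col = value_col
  ), class = "fpca_model")

  sc <- lapply(split(seq_len(nrow(data)), ids), function(ix) {
    xi <- fpc_scores(tt[ix], data[[value_col]][ix], model)
    c(n_obs = length(ix), xi)
  })
  scores <- tibble::tibble(
    !!id_col := names(sc),
    n_obs = vapply(sc, `[[`, numeric(1), 1L)
  )
  for (k in seq_len(model$K)) {
    scores[[paste0("xi_", k)]] <- vapply(sc, `[[`, numeric(1), k + 1L)
  }
  model$scores <- scores
  model
}

#' @export
print.fpca_model <- function(x, ...) {
  cat(sprintf("Sparse FPCA model (%s estimates)\n", x$smoother))
  cat(sprintf("  grid: %d points on [%.2f, %.2f]\n",
              length(x$grid), min(x$grid), max(x$grid)))
  cat(sprintf("  K = %d components (FVE %.1f%%), sigma2 = %.4g\n",
              x$K, 100 * x$fve[x$K], x$sigma2))
  invisible(x)
}

#' Tidy FPCA eigencomponents
#'
#' @param x An `fpca_model`.
#' @param ... Unused.
#' @return Tibble with one row per retained component: eigenvalue, FVE.
#' @exportS3Method generics::tidy
tidy.fpca_model <- function(x, ...) {
  tibble::tibble(
    component = seq_len(x$K),
    lambda = x$lambda[seq_len(x$K)],
    fve = x$fve[seq_len(x$K)] - c(0, x$fve)[seq_len(x$K)],
    cumulative_fve = x$fve[seq_len(x$K)]
  )
}

#' One-line FPCA model summary
#'
#' @param x An `fpca_model`.
#' @param ... Unused.
#' @return One-row tibble: K, total FVE of retained components, sigma2,
#'   number of subjects.
#' @exportS3Method generics::glance
glance.fpca_model <- function(x, ...) {
  tibble::tibble(K = x$K, cumulative_fve = x$fve[x$K], sigma2 = x$sigma2,
                 n_subjects = nrow(x$scores), n_grid = length(x$grid))
}

#' Plot an FPCA model: mean function and retained eigenfunctions
#'
#' @param object An `fpca_model`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.fpca_model <- function(object, ...) {
  df <- tibble::tibble(
    t = rep(object$grid, object$K + 1L),
    value = c(object$mu, as.vector(object$phi[, seq_len(object$K)])),
    curve = rep(c("mean", paste0("phi_", seq_len(object$K))),
                each = length(object$grid))
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$t, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~curve, scales = "free_y") +
    ggplot2::labs(x = "time", y = NULL,
                  title = "FPCA mean function and eigenfunctions")
}
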