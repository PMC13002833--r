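# Multi-shell gradient tables (FSL-style bval/bvec convention).
#
# A gradient table is a tibble with one row per acquired volume:
#   bval  diffusion weighting (s/mm^2)
#   bx, by, bz  unit gradient direction (zero vector for b = 0 volumes)
#   shell  integer shell index (0 for the b = 0 shell)

#' Construct a gradient table from b-values and directions
#'
#' @param bvals Numeric vector of b-values (s/mm^2), one per volume.
#' @param bvecs Numeric matrix with one row per volume and columns (x, y, z).
#'   Rows for `bvals > 0` must be unit vectors; rows for `bvals == 0` must be
#'   the zero vector.
#' @return A tibble of class `gradient_table` with columns `bval`, `bx`, `by`,
#'   `bz` and `shell`.
#' @export
gradient_table <- function(bvals, bvecs) {
  bvecs <- unname(as.matrix(bvecs))
  bvals <- unname(bvals)
  if (ncol(bvecs) != 3L) {
    perialps_abort("`bvecs` must have three columns (x, y, z).", "perialps_invalid_config")
  }
  if (length(bvals) != nrow(bvecs)) {
    perialps_abort("`bvals` and `bvecs` describe different numbers of volumes.",
                   "perialps_invalid_config")
  }
  if (any(!is.finite(bvals)) || any(bvals < 0)) {
    perialps_abort("b-values must be finite and non-negative.", "perialps_invalid_config")
  }
  norms <- sqrt(rowSums(bvecs^2))
  nz <- bvals > 0
  if (any(abs(norms[nz] - 1) > 1e-6)) {
    perialps_abort("Every direction with b > 0 must have unit norm (tol 1e-6).",
                   "perialps_invalid_config")
  }
  if (any(norms[!nz] > 1e-6)) {
    perialps_abort("Directions for b = 0 volumes must be the zero vector.",
                   "perialps_invalid_config")
  }
  shells <- sort(unique(bvals))
  # shell 0 is reserved for b = 0 when present; nonzero shells count from 1
  shell_id <- match(bvals, shells)
  if (0 %in% shells) shell_id <- shell_id - 1L
  tab <- tibble::tibble(
    bval = as.numeric(bvals),
    bx = bvecs[, 1], by = bvecs[, 2], bz = bvecs[, 3],
    shell = as.integer(shell_id)
  )
  class(tab) <- c("gradient_table", class(tibble::tibble()))
  tab
}

#' Build a multi-shell gradient table with near-uniform directions
#'
#' Directions on each nonzero shell are laid out on a Fibonacci sphere
#' (deterministic, approximately uniform) and then given a shell-specific
#' random rotation drawn from the seeded RNG, so repeated shells do not share
#' identical directions while the whole table is reproducible from `seed`.
#'
#' @param shell_bvals Numeric vector of shell b-values (s/mm^2); a 0 shell is
#'   allowed.
#' @param dirs_per_shell Integer vector, same length, of volumes per shell.
#' @param seed Integer seed controlling the per-shell rotations.
#' @return A `gradient_table` with `sum(dirs_per_shell)` rows.
#' @export
make_gradient_table <- function(shell_bvals = c(0, 500, 1000, 2000),
                                dirs_per_shell = c(1, 6, 48, 60),
                                seed = 1L) {
  if (length(shell_bvals) != length(dirs_per_shell)) {
    perialps_abort("`shell_bvals` and `dirs_per_shell` must have the same length.",
                   "perialps_invalid_config")
  }
  if (any(shell_bvals < 0)) {
    perialps_abort("Negative b-values are not allowed.", "perialps_invalid_config")
  }
  if (any(dirs_per_shell < 1)) {
    perialps_abort("Each shell needs at least one volume.", "perialps_invalid_config")
  }
  with_seed(seed, {
    rows <- lapply(seq_along(shell_bvals), function(i) {
      b <- shell_bvals[i]
      n <- dirs_per_shell[i]
      if (b == 0) {
        cbind(bval = rep(0, n), matrix(0, n, 3))
      } else {
        dirs <- fibonacci_sphere(n) %*% t(random_rotation())
        dirs <- dirs / sqrt(rowSums(dirs^2))
        cbind(bval = rep(b, n), dirs)
      }
    })
    m <- do.call(rbind, rows)
    gradient_table(m[, 1], m[, 2:4, drop = FALSE])
  })
}

# Deterministic Fibonacci-sphere point set (golden-angle spiral).
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  ga <- pi * (3 - sqrt(5))
  phi <- ga * (seq_len(n) - 1)
  cbind(r * cos(phi), r * sin(phi), z)
}

# Uniform random rotation matrix (QR of a Gaussian matrix, determinant +1).
random_rotation <- function() {
  qr_ <- qr(matrix(rnorm(9), 3, 3))
  q <- qr.Q(qr_)
  d <- diag(sign(diag(qr.R(qr_))))
  q <- q %*% d
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

#' Read an FSL-style bval/bvec pair
#'
#' Accepts both the FSL layout (3 rows by N columns) and its transpose for the
#' bvec file; the orientation is auto-detected from the shape and a message is
#' emitted when the transposed dialect is encountered.
#'
#' @param bval_path,bvec_path Paths to whitespace-separated text files.
#' @return A `gradient_table`.
#' @export
read_bval_bvec <- function(bval_path, bvec_path) {
  bvals <- scan(bval_path, what = numeric(), quiet = TRUE)
  raw <- as.matrix(read.table(bvec_path))
  if (nrow(raw) == 3L && ncol(raw) != 3L) {
    bvecs <- t(raw)
  } else if (ncol(raw) == 3L && nrow(raw) != 3L) {
    message("bvec file is N x 3 (transposed relative to FSL); normalizing.")
    bvecs <- raw
  } else if (all(dim(raw) == 3L)) {
    bvecs <- t(raw) # ambiguous 3x3: assume FSL rows-are-components
  } else {
    perialps_abort(sprintf("bvec file '%s' is neither 3xN nor Nx3.", bvec_path),
                   "perialps_format_error")
  }
  if (length(bvals) != nrow(bvecs)) {
    perialps_abort(
      sprintf("bval file '%s' has %d entries but bvec file '%s' has %d directions.",
              bval_path, length(bvals), bvec_path, nrow(bvecs)),
      "perialps_format_error"
    )
  }
  gradient_table(bvals, bvecs)
}

#' Write a gradient table as FSL-style bval/bvec files
#'
#' @param gtab A `gradient_table`.
#' @param bval_path,bvec_path Output paths.
#' @return Invisibly, the two paths.
#' @export
write_bval_bvec <- function(gtab, bval_path, bvec_path) {
  cat(paste(format(gtab$bval, trim = TRUE, scientific = FALSE), collapse = " "),
      "\n", sep = "", file = bval_path)
  m <- rbind(gtab$bx, gtab$by, gtab$bz)
  lines <- apply(m, 1, function(r) paste(sprintf("%.10f", r), collapse = " "))
  writeLines(lines, bvec_path)
  invisible(c(bval_path, bvec_path))
}

gtab_dirs <- function(gtab) cbind(gtab$bx, gtab$by, gtab$bz)
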