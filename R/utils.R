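# Internal helpers shared across modules.

#' @importFrom rlang abort .data :=
#' @importFrom stats rnorm runif quantile sd var coef lm pt p.adjust
#'   t.test chisq.test ks.test cor cor.test approx setNames aggregate
#' @importFrom utils write.csv read.csv
NULL

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

perialps_abort <- function(message, class) {
  rlang::abort(message, class = c(class, "perialps_error"))
}

# Evaluate `code` under a temporarily seeded RNG, restoring the caller's
# RNG state afterwards. seed = NULL leaves the RNG alone.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    perialps_abort("`seed` must be a single finite number.", "perialps_invalid_config")
  }
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  force(code)
}

is_symmetric3 <- function(m, tol = 1e-8) {
  is.matrix(m) && all(dim(m) == c(3L, 3L)) && max(abs(m - t(m))) <= tol
}

# Smallest eigenvalue check for PSD-ness of a symmetric 3x3 tensor.
check_psd3 <- function(m, tol = 1e-10, what = "tensor") {
  if (!is_symmetric3(m)) {
    perialps_abort(sprintf("%s must be a symmetric 3x3 matrix.", what),
                   "perialps_invalid_compartment")
  }
  ev <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -tol) {
    perialps_abort(
      sprintf("%s is not positive semi-definite (min eigenvalue %.3g).", what, min(ev)),
      "perialps_invalid_compartment"
    )
  }
  invisible(TRUE)
}

unit_vector <- function(v) {
  nv <- sqrt(sum(v^2))
  if (nv == 0) perialps_abort("Direction must be non-zero.", "perialps_invalid_input")
  v / nv
}
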