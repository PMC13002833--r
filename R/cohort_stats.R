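# Cohort statistics layer: effect sizes, group tests, covariate-adjusted
# contrasts, correlations and false-discovery-rate control.

new_effect_size <- function(estimate, convention, m1, s1, n1 = NA, m2, s2, n2 = NA) {
  structure(list(estimate = estimate, convention = convention,
                 m1 = m1, s1 = s1, n1 = n1, m2 = m2, s2 = s2, n2 = n2),
            class = "effect_size")
}

#' @export
print.effect_size <- function(x, ...) {
  cat(sprintf("Standardized effect %.4f (%s convention)\n",
              x$estimate, x$convention))
  invisible(x)
}

#' Standardized mean difference from summary statistics
#'
#' |m1 - m2| / sqrt((s1^2 + s2^2) / 2) — the average-variance convention
#' used in baseline-characteristics tables.
#'
#' @param m1,s1 Mean and SD of group 1.
#' @param m2,s2 Mean and SD of group 2.
#' @return An `effect_size` object (unsigned estimate).
#' @export
smd_continuous <- function(m1, s1, m2, s2) {
  if (s1 < 0 || s2 < 0) {
    perialps_abort("SDs must be non-negative.", "perialps_invalid_input")
  }
  den <- sqrt((s1^2 + s2^2) / 2)
  if (den == 0) {
    if (m1 != m2) {
      perialps_abort("Zero variance with unequal means: infinite effect.",
                     "perialps_infinite_effect")
    }
    return(new_effect_size(0, "average_variance", m1, s1, m2 = m2, s2 = s2))
  }
  new_effect_size(abs(m1 - m2) / den, "average_variance", m1, s1, m2 = m2, s2 = s2)
}

#' Standardized mean difference for binary proportions
#'
#' |p1 - p2| / sqrt((p1 (1 - p1) + p2 (1 - p2)) / 2).
#'
#' @param p1,p2 Group proportions in (0, 1) (or equal).
#' @return An `effect_size` object.
#' @export
smd_binary <- function(p1, p2) {
  if (p1 < 0 || p1 > 1 || p2 < 0 || p2 > 1) {
    perialps_abort("Proportions must lie in [0, 1].", "perialps_invalid_input")
  }
  den <- sqrt((p1 * (1 - p1) + p2 * (1 - p2)) / 2)
  if (den == 0) {
    if (p1 != p2) {
      perialps_abort("Degenerate proportions with unequal values: infinite effect.",
                     "perialps_infinite_effect")
    }
    return(new_effect_size(0, "average_variance", p1, NA, m2 = p2, s2 = NA))
  }
  new_effect_size(abs(p1 - p2) / den, "average_variance",
                  p1, sqrt(p1 * (1 - p1)), m2 = p2, s2 = sqrt(p2 * (1 - p2)))
}

#' Cohen's d between two samples
#'
#' @param sample1,sample2 Numeric vectors (n >= 2 each).
#' @param convention `"pooled_df"` (df-weighted pooled SD, the classical
#'   Cohen's d) or `"average_variance"` (same denominator as
#'   [smd_continuous()]).
#' @return An `effect_size` (signed: mean1 - mean2 in the numerator).
#' @export
cohens_d <- function(sample1, sample2,
                     convention = c("pooled_df", "average_variance")) {
  convention <- match.arg(convention)
  sample1 <- sample1[is.finite(sample1)]
  sample2 <- sample2[is.finite(sample2)]
  n1 <- length(sample1); n2 <- length(sample2)
  if (n1 < 2L || n2 < 2L) {
    perialps_abort("Cohen's d needs at least 2 observations per group.",
                   "perialps_insufficient_sample")
  }
  m1 <- mean(sample1); m2 <- mean(sample2)
  s1 <- sd(sample1); s2 <- sd(sample2)
  den <- if (convention == "pooled_df") {
    sqrt(((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / (n1 + n2 - 2))
  } else {
    sqrt((s1^2 + s2^2) / 2)
  }
  if (den == 0) {
    if (m1 != m2) {
      perialps_abort("Zero pooled variance with unequal means: infinite effect.",
                     "perialps_infinite_effect")
    }
    return(new_effect_size(0, convention, m1, s1, n1, m2, s2, n2))
  }
  new_effect_size((m1 - m2) / den, convention, m1, s1, n1, m2, s2, n2)
}

#' Covariate-adjusted group difference via ordinary least squares
#'
#' Fits `outcome ~ group + covariates`; the adjusted effect is the group
#' coefficient, its standardized version divides by the residual SD, and
#' the p-value is the coefficient's t-test. Rows with missing values in any
#' used column are dropped (listwise deletion) and counted.
#'
#' @param data Data frame with a two-level `group` column.
#' @param outcome Name of the numeric outcome column.
#' @param covariates Character vector of covariate column names (may be
#'   empty).
#' @param group_col Name of the grouping column (first level = reference).
#' @return One-row tibble: outcome, adjusted effect (non-reference minus
#'   reference), standardized `d`, `p_value`, `n_used`, `n_dropped`,
#'   `covariates`.
#' @export
adjusted_group_difference <- function(data, outcome, covariates = character(),
                                      group_col = "group") {
  cols <- c(outcome, group_col, covariates)
  missing_cols <- setdiff(cols, names(data))
  if (length(missing_cols)) {
    perialps_abort(paste("Missing columns:", paste(missing_cols, collapse = ", ")),
                   "perialps_invalid_input")
  }
  d <- as.data.frame(data)[cols]
  cc <- stats::complete.cases(d)
  d <- d[cc, , drop = FALSE]
  d[[group_col]] <- droplevels(factor(d[[group_col]]))
  if (nlevels(d[[group_col]]) != 2L) {
    perialps_abort("Grouping column must have exactly two levels.",
                   "perialps_invalid_input")
  }
  fml <- stats::reformulate(c(group_col, covariates), response = outcome)
  fit <- lm(fml, data = d)
  if (any(is.na(coef(fit)))) {
    bad <- names(coef(fit))[is.na(coef(fit))]
    perialps_abort(paste("Rank-deficient design; collinear terms:",
                         paste(bad, collapse = ", ")),
                   "perialps_rank_deficiency")
  }
  sm <- summary(fit)
  term <- grep(paste0("^", group_col), rownames(sm$coefficients), value = TRUE)[1]
  est <- sm$coefficients[term, "Estimate"]
  tibble::tibble(
    outcome = outcome,
    effect = est,
    d = est / sm$sigma,
    p_value = sm$coefficients[term, "Pr(>|t|)"],
    n_used = nrow(d),
    n_dropped = sum(!cc),
    covariates = paste(covariates, collapse = "+")
  )
}

#' Pearson or Spearman correlation with t-approximation p-value
#'
#' Pearson delegates to [stats::cor.test()]; Spearman computes rho on
#' midranks and applies the same t approximation
#' t = rho sqrt((n - 2) / (1 - rho^2)) (ties handled by midranks, so no
#' exact-p machinery is involved).
#'
#' @param x,y Numeric vectors (pairwise complete observations are used).
#' @param method `"pearson"` or `"spearman"`.
#' @return One-row tibble: method, estimate, statistic, p_value, n.
#' @export
correlate <- function(x, y, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) {
    perialps_abort("Correlation needs at least 3 complete pairs.",
                   "perialps_insufficient_sample")
  }
  if (sd(x) == 0 || sd(y) == 0) {
    perialps_abort("Zero variance: correlation undefined.",
                   "perialps_undefined_correlation")
  }
  if (method == "pearson") {
    ct <- cor.test(x, y, method = "pearson")
    est <- unname(ct$estimate); stat <- unname(ct$statistic); p <- ct$p.value
  } else {
    est <- cor(rank(x), rank(y))
    if (abs(est) >= 1) {
      stat <- sign(est) * Inf
      p <- 0
    } else {
      stat <- est * sqrt((n - 2) / (1 - est^2))
      p <- 2 * pt(-abs(stat), df = n - 2)
    }
  }
  tibble::tibble(method = method, estimate = est, statistic = stat,
                 p_value = p, n = n)
}

#' Two-group comparison tests for a set of variables
#'
#' Continuous variables: two-sample t-test (Student by default, Welch via
#' `welch = TRUE`). Categorical variables (factor/character): chi-squared
#' test on the contingency table without continuity correction. With
#' `ks_normality = TRUE` each continuous variable additionally gets a
#' one-sample Kolmogorov-Smirnov test against a normal distribution with
#' the sample mean/SD (note the p-value does not account for the estimated
#' parameters).
#'
#' @param data Data frame.
#' @param variables Character vector of column names to test.
#' @param group_col Two-level grouping column.
#' @param welch Use the Welch (unequal-variance) t-test.
#' @param ks_normality Add KS distribution checks for continuous variables.
#' @return Tibble with one row per test: variable, method, statistic, df,
#'   p_value.
#' @export
group_tests <- function(data, variables, group_col = "group",
                        welch = FALSE, ks_normality = FALSE) {
  d <- as.data.frame(data)
  g <- droplevels(factor(d[[group_col]]))
  if (nlevels(g) != 2L) {
    perialps_abort("Grouping column must have exactly two levels.",
                   "perialps_invalid_input")
  }
  rows <- list()
  for (v in variables) {
    x <- d[[v]]
    if (is.numeric(x)) {
      ok <- is.finite(x)
      x1 <- x[ok & g == levels(g)[1]]
      x2 <- x[ok & g == levels(g)[2]]
      if (length(x1) < 2L || length(x2) < 2L) {
        perialps_abort(sprintf("Variable '%s': a group has fewer than 2 values.", v),
                       "perialps_insufficient_sample")
      }
      tt <- t.test(x1, x2, var.equal = !welch)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        variable = v, method = if (welch) "welch_t" else "student_t",
        statistic = unname(tt$statistic), df = unname(tt$parameter),
        p_value = tt$p.value
      )
      if (ks_normality) {
        xs <- x[ok]
        ks <- suppressWarnings(ks.test(xs, "pnorm", mean(xs), sd(xs)))
        rows[[length(rows) + 1L]] <- tibble::tibble(
          variable = v, method = "ks", statistic = unname(ks$statistic),
          df = NA_real_, p_value = ks$p.value
        )
      }
    } else {
      tab <- table(g, x)
      cs <- suppressWarnings(chisq.test(tab, correct = FALSE))
      rows[[length(rows) + 1L]] <- tibble::tibble(
        variable = v, method = "chi_square", statistic = unname(cs$statistic),
        df = unname(cs$parameter), p_value = cs$p.value
      )
    }
  }
  dplyr::bind_rows(rows)
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up adjusted p-values (delegated to [stats::p.adjust()] with
#' `method = "BH"`), with input validation.
#'
#' @param p_values Numeric vector of p-values in \[0, 1\].
#' @return Adjusted vector, original order preserved.
#' @export
bh_fdr <- function(p_values) {
  if (any(!is.finite(p_values)) || any(p_values < 0) || any(p_values > 1)) {
    perialps_abort("p-values must be finite and in [0, 1].",
                   "perialps_invalid_input")
  }
  p.adjust(p_values, method = "BH")
}
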