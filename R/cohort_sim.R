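# Sparse two-group longitudinal cohort simulator.
#
# Each subject carries a latent "glymphatic" factor u ~ N(0, 1) that loads
# (positively) on the ALPS indices and (negatively) on PSMD and free water,
# inducing the cross-index correlation structure seen in aging cohorts.
# Index trajectories follow y_ij = mu_g(t_ij) + xi_i1 phi_1(t_ij)
# + xi_i2 phi_2(t_ij) + eps_ij with group-specific quadratic mean functions
# of age, orthonormal eigenfunctions on the age domain, and Gaussian
# measurement noise. Amyloid burden and cognitive scores are linear in the
# latent factor plus noise.

.cohort_indices <- c("dti_alps", "dki_alps", "psmd", "fw_wm")

#' Default configuration of the longitudinal cohort simulator
#'
#' Defaults emulate an aging two-group cohort (healthy controls, HC, versus
#' cognitively impaired, CI): 128 HC and 83 CI subjects, 1-3 irregular
#' visits each, baseline DTI-ALPS about 1.37 (HC) versus 1.28 (CI) and
#' DKI-ALPS about 1.63 versus 1.37, with HCs declining faster with age;
#' PSMD (units 1e-3 mm^2/s) and free-water fraction are higher and rising
#' in CI.
#'
#' @param n_hc,n_ci Group sizes.
#' @param visit_probs P(1, 2, 3 visits); must sum to 1.
#' @param age_mean,age_sd Baseline-age distribution per group (years).
#' @param visit_gap_range Uniform range of between-visit gaps (years).
#' @param age_domain Age interval on which the eigenfunctions are
#'   orthonormal.
#' @param mean_coef Per index and group: quadratic coefficients
#'   (level, slope, curvature) in (age - 70) years. The level is anchored
#'   so that it equals the expected baseline (first-visit) value of the
#'   group: the generator subtracts the offset induced by the group's
#'   baseline-age spread, `slope * (mu_age - 70) +
#'   curvature * (sd_age^2 + (mu_age - 70)^2)`.
#' @param score_sd Per index: SDs of the first and second eigenfunction
#'   scores (index units, since the eigenfunctions are L2-normalized on the
#'   age domain their pointwise magnitude is about 0.16).
#' @param latent_loading Per index: correlation of the first score with the
#'   shared latent factor (sign encodes direction).
#' @param noise_sd Per index: measurement-noise SD (must be positive).
#' @param abeta Parameters of the amyloid model:
#'   `suvr = mean_g - slope * u + N(0, sd)`.
#' @param cognition Parameters of the cognitive scores (MoCA-like and
#'   ADAS13-like), linear in u plus noise.
#' @param sex_p_male Probability of male sex per group.
#' @param education Mean/SD of education years per group.
#' @return Named list of simulator parameters.
#' @export
cohort_config <- function(
    n_hc = 128L, n_ci = 83L,
    visit_probs = c(0.5, 0.3, 0.2),
    age_mean = c(hc = 71.47, ci = 72.21),
    age_sd = c(hc = 7.30, ci = 6.45),
    visit_gap_range = c(0.9, 2.1),
    age_domain = c(55, 95),
    mean_coef = list(
      dti_alps = list(hc = c(1.37, -0.012, -4e-4), ci = c(1.28, -0.006, -2e-4)),
      dki_alps = list(hc = c(1.63, -0.020, -5e-4), ci = c(1.37, -0.009, -2e-4)),
      psmd = list(hc = c(0.25, 0.0012, 3e-5), ci = c(0.26, 0.0022, 6e-5)),
      fw_wm = list(hc = c(0.28, 0.0012, 3e-5), ci = c(0.29, 0.0022, 5e-5))
    ),
    score_sd = list(dti_alps = c(1.26, 0.40), dki_alps = c(1.90, 0.60),
                    psmd = c(0.19, 0.06), fw_wm = c(0.22, 0.07)),
    latent_loading = c(dti_alps = 0.70, dki_alps = 0.75,
                       psmd = -0.55, fw_wm = -0.60),
    noise_sd = c(dti_alps = 0.10, dki_alps = 0.15,
                 psmd = 0.015, fw_wm = 0.015),
    abeta = list(mean = c(hc = 1.09, ci = 1.25), slope = 0.10, sd = 0.12),
    cognition = list(
      moca = list(mean = c(hc = 25.87, ci = 22.06), slope = 1.2, sd = 2.5),
      adas13 = list(mean = c(hc = 8.24, ci = 16.37), slope = -1.8, sd = 4.0)
    ),
    sex_p_male = c(hc = 46 / 128, ci = 48 / 83),
    education = list(hc = c(16.55, 2.42), ci = c(15.71, 2.56))) {
  as.list(environment())
}

# Orthonormal eigenfunctions on the age domain: phi_1 constant,
# phi_2 centered linear.
cohort_eigenfunctions <- function(age_domain) {
  T_ <- diff(age_domain)
  mid <- mean(age_domain)
  list(
    phi1 = function(t) rep(1 / sqrt(T_), length(t)),
    phi2 = function(t) (t - mid) * sqrt(12 / T_^3)
  )
}

#' Simulate a sparse two-group longitudinal cohort
#'
#' @param config List from [cohort_config()].
#' @param seed Integer seed.
#' @return A tibble with one row per visit: `subject_id`, `group`
#'   (factor HC/CI), `sex`, `education_years`, `visit`, `age`, the four
#'   dMRI indices (`dti_alps`, `dki_alps`, `psmd` in 1e-3 mm^2/s, `fw_wm`),
#'   `abeta_suvr`, `moca`, `adas13`.
#' @export
simulate_longitudinal_cohort <- function(config = cohort_config(), seed = 1L) {
  cfg <- config
  if (cfg$n_hc < 1L || cfg$n_ci < 1L) {
    perialps_abort("Group sizes must be at least 1.", "perialps_invalid_config")
  }
  if (abs(sum(cfg$visit_probs) - 1) > 1e-9) {
    perialps_abort("Visit-count probabilities must sum to 1.",
                   "perialps_invalid_config")
  }
  if (any(unlist(cfg$noise_sd) <= 0)) {
    perialps_abort("Measurement-noise SDs must be positive.",
                   "perialps_invalid_config")
  }
  ef <- cohort_eigenfunctions(cfg$age_domain)

  with_seed(seed, {
    n <- cfg$n_hc + cfg$n_ci
    group <- rep(c("hc", "ci"), c(cfg$n_hc, cfg$n_ci))
    sid <- sprintf("S%04d", seq_len(n))

    n_visits <- sample(seq_along(cfg$visit_probs), n, replace = TRUE,
                       prob = cfg$visit_probs)
    base_age <- rnorm(n, cfg$age_mean[group], cfg$age_sd[group])
    base_age <- pmin(pmax(base_age, cfg$age_domain[1]),
                     cfg$age_domain[2] - 2 * cfg$visit_gap_range[2])

    u <- rnorm(n)                          # shared latent glymphatic factor
    xi1 <- xi2 <- list()
    for (idx in .cohort_indices) {
      s <- cfg$score_sd[[idx]]
      rho <- cfg$latent_loading[[idx]]
      xi1[[idx]] <- s[1] * (rho * u + sqrt(1 - rho^2) * rnorm(n))
      xi2[[idx]] <- s[2] * rnorm(n)
    }

    sex <- ifelse(runif(n) < cfg$sex_p_male[group], "male", "female")
    edu <- vapply(seq_len(n), function(i) {
      p <- cfg$education[[group[i]]]
      rnorm(1, p[1], p[2])
    }, numeric(1))
    abeta <- cfg$abeta$mean[group] - cfg$abeta$slope * u +
      rnorm(n, sd = cfg$abeta$sd)
    moca <- cfg$cognition$moca$mean[group] + cfg$cognition$moca$slope * u +
      rnorm(n, sd = cfg$cognition$moca$sd)
    adas13 <- cfg$cognition$adas13$mean[group] +
      cfg$cognition$adas13$slope * u + rnorm(n, sd = cfg$cognition$adas13$sd)

    rows <- vector("list", n)
    for (i in seq_len(n)) {
      gaps <- runif(n_visits[i] - 1L, cfg$visit_gap_range[1],
                    cfg$visit_gap_range[2])
      ages <- base_age[i] + cumsum(c(0, gaps))
      vals <- list()
      for (idx in .cohort_indices) {
        cc <- cfg$mean_coef[[idx]][[group[i]]]
        # anchor the level so it is the expected baseline value of the group
        mu_d <- cfg$age_mean[[group[i]]] - 70
        lvl <- cc[1] - cc[2] * mu_d -
          cc[3] * (cfg$age_sd[[group[i]]]^2 + mu_d^2)
        a <- ages - 70
        mu_g <- lvl + cc[2] * a + cc[3] * a^2
        vals[[idx]] <- mu_g + xi1[[idx]][i] * ef$phi1(ages) +
          xi2[[idx]][i] * ef$phi2(ages) +
          rnorm(length(ages), sd = cfg$noise_sd[[idx]])
      }
      rows[[i]] <- tibble::tibble(
        subject_id = sid[i], group = group[i], sex = sex[i],
        education_years = edu[i], visit = seq_len(n_visits[i]), age = ages,
        dti_alps = vals$dti_alps, dki_alps = vals$dki_alps,
        psmd = vals$psmd, fw_wm = vals$fw_wm,
        abeta_suvr = abeta[i], moca = moca[i], adas13 = adas13[i]
      )
    }
    out <- dplyr::bind_rows(rows)
    out$group <- factor(toupper(out$group), levels = c("HC", "CI"))
    out
  })
}
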