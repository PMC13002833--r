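Package: perialps
Title: Perivascular Diffusion (ALPS), White-Matter Injury and Trajectory
    Analysis for Multi-Shell Diffusion MRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies glymphatic-system proxies and white-matter injury
    markers from multi-shell diffusion MRI and models their longitudinal
    trajectories. Implements diffusion-tensor (DTI) and diffusion-kurtosis
    (DKI) weighted-least-squares fitting, the DTI-ALPS and DKI-ALPS
    perivascular-diffusion indices, peak width of skeletonized mean
    diffusivity (PSMD), bi-tensor free-water mapping, sparse functional
    principal component analysis (PACE-style) for irregular longitudinal
    index measurements, and an effect-size oriented cohort-statistics layer
    (standardized mean differences, covariate-adjusted group contrasts,
    correlations, false-discovery-rate control). Ships a multi-shell
    diffusion phantom generator with analytic ground truth in the ALPS
    geometry and a sparse two-group longitudinal cohort simulator so the
    whole pipeline is testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    digest,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    RNifti,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
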