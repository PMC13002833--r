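# End-to-end orchestration: phantom pair -> tensor fits -> ALPS/PSMD/FW ->
# synthetic cohort -> FPCA trajectories -> cohort statistics, with file
# output and a hashed manifest.

#' Pipeline configuration
#'
#' @param phantom_g Glymphatic conductances of the phantom pair.
#' @param phantom Base phantom configuration ([alps_phantom_config()]);
#'   its `g` is overridden per phantom. The default pair is noise-free so
#'   the imaging stage is exactly reproducible.
#' @param cohort Cohort simulator configuration ([cohort_config()]).
#' @param fw_max_voxels Voxel cap for the free-water stage (seeded
#'   subsample of the white-matter mask).
#' @param stages Character vector of stages to run, a subset of
#'   `c("phantom", "cohort", "fpca", "stats")`.
#' @param seed Master seed; per-stage seeds are derived from it.
#' @param out_dir Optional output directory; when given, tables, maps and a
#'   hashed manifest are written there.
#' @return Named list of class `pipeline_config`.
#' @export
pipeline_config <- function(phantom_g = c(0.3, 0.9),
                            phantom = alps_phantom_config(snr = Inf),
                            cohort = cohort_config(),
                            fw_max_voxels = 300L,
                            stages = c("phantom", "cohort", "fpca", "stats"),
                            seed = 1L, out_dir = NULL) {
  cfg <- as.list(environment())
  unknown <- setdiff(names(cfg), c("phantom_g", "phantom", "cohort",
                                   "fw_max_voxels", "stages", "seed", "out_dir"))
  if (length(unknown)) {
    perialps_abort(paste("Unknown configuration keys:", paste(unknown, collapse = ", ")),
                   "perialps_invalid_config")
  }
  structure(cfg, class = "pipeline_config")
}

#' Read a 4D diffusion volume with its gradient table
#'
#' The bvec orientation convention is gradient frame = image frame; no
#' reorientation is applied. Transposed (N x 3) bvec files are auto-detected.
#'
#' @param dwi_path NIfTI path (.nii or .nii.gz).
#' @param bval_path,bvec_path FSL-style gradient text files.
#' @return List with `signal` (4D array) and `gtab`.
#' @export
read_dwi <- function(dwi_path, bval_path, bvec_path) {
  for (p in c(dwi_path, bval_path, bvec_path)) {
    if (!file.exists(p)) {
      perialps_abort(sprintf("Input file not found: %s", p), "perialps_format_error")
    }
  }
  img <- RNifti::readNifti(dwi_path)
  signal <- array(as.numeric(img), dim(img))
  gtab <- read_bval_bvec(bval_path, bvec_path)
  if (length(dim(signal)) != 4L || dim(signal)[4] != nrow(gtab)) {
    perialps_abort(
      sprintf("Volume count mismatch: DWI has %s volumes, gradient table %d rows (%s).",
              if (length(dim(signal)) == 4L) dim(signal)[4] else "no",
              nrow(gtab), bval_path),
      "perialps_format_error"
    )
  }
  list(signal = signal, gtab = gtab)
}

#' Write a phantom to disk (NIfTI + bval/bvec + JSON truth sidecar)
#'
#' @param phantom An `alps_phantom`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the written file paths.
#' @export
write_phantom <- function(phantom, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    dwi = file.path(dir, "dwi.nii.gz"),
    labels = file.path(dir, "labels.nii.gz"),
    wm = file.path(dir, "wm_mask.nii.gz"),
    bval = file.path(dir, "dwi.bval"),
    bvec = file.path(dir, "dwi.bvec"),
    truth = file.path(dir, "truth.json")
  )
  RNifti::writeNifti(phantom$signal, paths["dwi"])
  RNifti::writeNifti(phantom$region_labels, paths["labels"])
  RNifti::writeNifti(phantom$wm_mask + 0L, paths["wm"])
  for (nm in names(phantom$roi_masks)) {
    p <- file.path(dir, paste0("roi_", nm, ".nii.gz"))
    RNifti::writeNifti(phantom$roi_masks[[nm]] + 0L, p)
    paths[paste0("roi_", nm)] <- p
  }
  write_bval_bvec(phantom$gtab, paths["bval"], paths["bvec"])
  truth <- phantom$truth
  truth$mixtures <- lapply(truth$mixtures, function(mix)
    lapply(mix, function(cp) list(fraction = cp$fraction,
                                  tensor = as.vector(cp$tensor))))
  jsonlite::write_json(truth, paths["truth"], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

phantom_session <- function(g, base_cfg, fw_max_voxels, seed) {
  cfg <- base_cfg
  cfg$g <- g
  cfg$seed <- seed
  ph <- build_alps_phantom(cfg)
  maps <- fit_dwi_volume(ph$signal, ph$gtab, mask = ph$wm_mask, model = "dki")
  alps <- compute_alps(maps, phantom_roi_set(ph), voxel_mm = cfg$voxel_mm)
  skel <- make_skeleton_mask(maps$fa)
  psmd_val <- psmd(maps$md, skel)
  fwres <- fit_fw_volume(ph$signal, ph$gtab, ph$wm_mask,
                         d_iso = cfg$d_free, max_voxels = fw_max_voxels,
                         seed = seed)
  tibble::tibble(
    subject_id = sprintf("phantom_g%03.0f", 100 * g),
    g = g,
    dti_alps_left = alps$dti_alps_left, dti_alps_right = alps$dti_alps_right,
    dti_alps = alps$dti_alps_mean,
    dki_alps_left = alps$dki_alps_left, dki_alps_right = alps$dki_alps_right,
    dki_alps = alps$dki_alps_mean,
    psmd = psmd_val,
    fw_wm = fw_wm_mean(fwres$fw, ph$wm_mask),
    analytic_dti_alps = ph$truth$dti_alps
  )
}

cohort_statistics <- function(cohort, fpca_models) {
  indices <- c("dti_alps", "dki_alps", "psmd", "fw_wm")
  baseline <- cohort[cohort$visit == 1L, ]
  hc <- function(v, d = baseline) d[[v]][d$group == "HC"]
  ci <- function(v, d = baseline) d[[v]][d$group == "CI"]

  rows <- list()
  for (v in indices) {
    tt <- group_tests(baseline, v)
    d <- cohens_d(hc(v), ci(v))
    rows[[length(rows) + 1L]] <- tibble::tibble(
      analysis = "baseline_group", variable = v,
      estimate = mean(ci(v)) - mean(hc(v)),
      statistic = tt$statistic, p_value = tt$p_value,
      effect = d$estimate, convention = d$convention
    )
  }
  for (v in indices) {
    m1 <- adjusted_group_difference(baseline, v,
                                    c("age", "sex", "education_years"))
    rows[[length(rows) + 1L]] <- tibble::tibble(
      analysis = "glm_model1", variable = v, estimate = m1$effect,
      statistic = NA_real_, p_value = m1$p_value, effect = m1$d,
      convention = "residual_sd"
    )
  }
  for (v in c("dti_alps", "dki_alps")) {
    m2 <- adjusted_group_difference(baseline, v,
                                    c("age", "sex", "education_years",
                                      "psmd", "fw_wm"))
    rows[[length(rows) + 1L]] <- tibble::tibble(
      analysis = "glm_model2", variable = v, estimate = m2$effect,
      statistic = NA_real_, p_value = m2$p_value, effect = m2$d,
      convention = "residual_sd"
    )
  }
  pairs <- list(c("dti_alps", "dki_alps"), c("dti_alps", "psmd"),
                c("dki_alps", "psmd"), c("dti_alps", "fw_wm"),
                c("dki_alps", "fw_wm"), c("psmd", "fw_wm"),
                c("dti_alps", "abeta_suvr"), c("dki_alps", "abeta_suvr"))
  for (pr in pairs) {
    ct <- correlate(baseline[[pr[1]]], baseline[[pr[2]]], "pearson")
    rows[[length(rows) + 1L]] <- tibble::tibble(
      analysis = "correlation", variable = paste(pr, collapse = "~"),
      estimate = ct$estimate, statistic = ct$statistic,
      p_value = ct$p_value, effect = NA_real_, convention = "pearson"
    )
  }
  for (v in indices) {
    for (cg in c("moca", "adas13")) {
      ct <- correlate(baseline[[v]], baseline[[cg]], "spearman")
      rows[[length(rows) + 1L]] <- tibble::tibble(
        analysis = "cognition_correlation", variable = paste(v, cg, sep = "~"),
        estimate = ct$estimate, statistic = ct$statistic,
        p_value = ct$p_value, effect = NA_real_, convention = "spearman"
      )
    }
  }
  if (!is.null(fpca_models)) {
    subj_group <- unique(cohort[, c("subject_id", "group")])
    for (v in indices) {
      sc <- fpca_models[[v]]$scores
      sc <- dplyr::left_join(sc, subj_group, by = "subject_id")
      d <- cohens_d(sc$xi_1[sc$group == "HC"], sc$xi_1[sc$group == "CI"])
      tt <- t.test(sc$xi_1[sc$group == "HC"], sc$xi_1[sc$group == "CI"],
                   var.equal = TRUE)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        analysis = "fpc1_group", variable = v,
        estimate = -diff(tt$estimate), statistic = unname(tt$statistic),
        p_value = tt$p.value, effect = d$estimate, convention = d$convention
      )
    }
  }
  out <- dplyr::bind_rows(rows)
  out <- dplyr::group_by(out, .data$analysis)
  out <- dplyr::mutate(out, p_fdr = bh_fdr(.data$p_value))
  dplyr::ungroup(out)
}

#' Run the full synthetic pipeline
#'
#' Stages (all optional via `config$stages`): a noise-free phantom pair at
#' two glymphatic conductances fitted through DKI/ALPS/PSMD/FW; the sparse
#' longitudinal cohort; per-index FPCA trajectory models; and the cohort
#' statistics layer (baseline tests, adjusted models, correlations, FPC
#' score contrasts, FDR within each analysis family).
#'
#' @param config A [pipeline_config()].
#' @return Object of class `perialps_pipeline` with elements
#'   `session_records`, `cohort`, `fpca`, `stats`, `config` and (when
#'   `out_dir` is set) `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  cfg <- config
  res <- list(config = cfg)
  if ("phantom" %in% cfg$stages) {
    res$session_records <- dplyr::bind_rows(lapply(
      seq_along(cfg$phantom_g),
      function(i) phantom_session(cfg$phantom_g[i], cfg$phantom,
                                  cfg$fw_max_voxels,
                                  seed = cfg$seed + 10L * i)
    ))
  }
  if ("cohort" %in% cfg$stages) {
    res$cohort <- simulate_longitudinal_cohort(cfg$cohort, seed = cfg$seed)
  }
  if ("fpca" %in% cfg$stages) {
    if (is.null(res$cohort)) {
      perialps_abort("Stage 'fpca' requires stage 'cohort'.", "perialps_invalid_config")
    }
    res$fpca <- lapply(setNames(nm = c("dti_alps", "dki_alps", "psmd", "fw_wm")),
                       function(v) fit_fpca(res$cohort, value_col = v))
  }
  if ("stats" %in% cfg$stages) {
    if (is.null(res$cohort)) {
      perialps_abort("Stage 'stats' requires stage 'cohort'.", "perialps_invalid_config")
    }
    res$stats <- cohort_statistics(res$cohort, res$fpca)
  }
  if (!is.null(cfg$out_dir)) {
    res$manifest <- write_outputs(res, cfg$out_dir)
  }
  structure(res, class = "perialps_pipeline")
}

#' Write pipeline outputs and a hashed manifest
#'
#' Tables are written as CSV (header row, no row names), FPCA models as
#' JSON; the manifest lists every written file with its SHA-256 hash and is
#' itself written as `manifest.json`.
#'
#' @param result A `perialps_pipeline` (or compatible list).
#' @param out_dir Output directory (created if needed).
#' @return Tibble manifest (file, sha256).
#' @export
write_outputs <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  put_csv <- function(df, name) {
    p <- file.path(out_dir, name)
    write.csv(df, p, row.names = FALSE)
    files <<- c(files, p)
  }
  if (!is.null(result$session_records)) put_csv(result$session_records, "sessions.csv")
  if (!is.null(result$cohort)) put_csv(result$cohort, "cohort.csv")
  if (!is.null(result$stats)) put_csv(result$stats, "stats.csv")
  if (!is.null(result$fpca)) {
    for (v in names(result$fpca)) {
      m <- result$fpca[[v]]
      p <- file.path(out_dir, paste0("fpca_", v, ".json"))
      jsonlite::write_json(
        list(grid = m$grid, mu = m$mu, phi = m$phi, lambda = m$lambda,
             sigma2 = m$sigma2, fve = m$fve, K = m$K),
        p, auto_unbox = TRUE, digits = NA
      )
      files <- c(files, p)
      put_csv(m$scores, paste0("fpca_", v, "_scores.csv"))
    }
  }
  if (!is.null(result$config$seed)) {
    p <- file.path(out_dir, "run_config.json")
    jsonlite::write_json(
      list(seed = result$config$seed, stages = result$config$stages,
           phantom_g = result$config$phantom_g),
      p, auto_unbox = TRUE, digits = NA
    )
    files <- c(files, p)
  }
  manifest <- tibble::tibble(
    file = basename(files),
    sha256 = vapply(unname(files), function(f)
      digest::digest(f, algo = "sha256", file = TRUE), character(1),
      USE.NAMES = FALSE)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  manifest
}
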