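## End-to-end study orchestration ----------------------------------------

feature_table <- function(rows, ids, method) {
  m <- do.call(rbind, rows)
  data.frame(lesion_id = ids, method = method, m, check.names = FALSE,
             stringsAsFactors = FALSE)
}

feature_cols <- function(tab) {
  as.matrix(tab[, feature_registry()$qualified, drop = FALSE])
}

segment_volume <- function(vol, method, background, calibration) {
  if (method == "fixed60") fixed_threshold_segment(vol)
  else adaptive_threshold_segment(vol, background_estimate = background,
                                  calibration = calibration)
}

#' Run the full phantom study
#'
#' Executes the whole pipeline under one master seed: cohort generation,
#' acquisition emulation under every reconstruction setting of the
#' configured grid, two test-retest acquisition pairs, MTV segmentation
#' (both methods on the standard protocol, adaptive elsewhere), 58-feature
#' extraction, and the statistical battery (Friedman versus segmentation,
#' COV stability classes versus reconstruction, test-retest ICC,
#' Mann-Whitney heterogeneity discrimination, H_GS correlation, paired
#' t-test on Sphericity). All tables are written under `out_dir` together
#' with a JSON manifest sufficient to reproduce every output.
#'
#' @param config a [study_config()].
#' @param out_dir output directory (created if needed).
#' @param write_volumes also write every simulated volume as NIfTI
#'   (default FALSE: volumes are cheap to regenerate from the manifest).
#' @param quiet suppress per-stage progress messages.
#' @return list of class `run_manifest` (also written as
#'   `manifest.json`): configuration, per-stage outputs, seeds consumed,
#'   and the in-memory `report`.
#' @export
run_study <- function(config = study_config(), out_dir = tempfile("phantom_run_"),
                      write_volumes = FALSE, quiet = FALSE) {
  stopifnot(inherits(config, "study_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(...)
  stage <- function(name, lesion_id, expr) {
    tryCatch(expr, error = function(e) stop(
      "stage '", name, "' failed",
      if (!is.na(lesion_id)) paste0(" at lesion ", lesion_id), ": ",
      conditionMessage(e), call. = FALSE))
  }
  calibration <- default_calibration()
  seed <- config$seed

  say("stage build: ", config$n_lesions, " lesions")
  study <- stage("build", NA, build_study(
    seed = seed, n_lesions = config$n_lesions,
    resolution = config$resolution))
  gt <- study$ground_truth
  utils::write.csv(gt, file.path(out_dir, "ground_truth.csv"),
                   row.names = FALSE)

  grid <- reconstruction_grid()
  if (config$grid == "minimal") grid <- grid[grid$family == "matrix", ]
  grid$setting_id <- paste0(grid$family, ".", grid$label)

  settings_for <- function(row, lesion_idx, counter) {
    acquisition_settings(
      matrix_size = row$matrix_size, fwhm_filter = row$fwhm_filter,
      psf = row$psf, tof = row$tof, iterations = row$iterations,
      subsets = row$subsets, noise_scale = config$noise_scale,
      seed = child_seed(seed, c(counter, lesion_idx)))
  }
  standard <- grid[grid$label == if (config$grid == "minimal") "m256" else "OSEM+PSF+TOF", ][1, ]

  say("stage simulate: ", nrow(grid), " settings x ", nrow(gt), " lesions")
  feats_by_setting <- list()
  feats_default <- list()
  for (si in seq_len(nrow(grid))) {
    rows <- vector("list", nrow(gt))
    for (li in seq_len(nrow(gt))) {
      vol <- stage("simulate", li, suppressWarnings(
        simulate_acquisition(study$lesions[[li]],
                             settings_for(grid[si, ], li, 3000L + si))))
      if (write_volumes)
        write_volume(vol, file.path(out_dir, sprintf(
          "vol_%s_lesion%02d.nii.gz", grid$setting_id[si], li)))
      seg <- stage("segment", li, segment_volume(
        vol, "adaptive", study$lesions[[li]]$background, calibration))
      rows[[li]] <- stage("features", li, extract_all(vol, seg))
    }
    feats_by_setting[[grid$setting_id[si]]] <- feature_table(
      rows, gt$lesion_id, grid$setting_id[si])
  }

  say("stage segment/features: standard protocol, both methods")
  per_method <- list()
  for (m in config$methods) {
    rows <- vector("list", nrow(gt))
    for (li in seq_len(nrow(gt))) {
      vol <- suppressWarnings(simulate_acquisition(
        study$lesions[[li]], settings_for(standard, li, 3000L + match(
          standard$setting_id, grid$setting_id))))
      seg <- stage("segment", li, segment_volume(
        vol, m, study$lesions[[li]]$background, calibration))
      rows[[li]] <- stage("features", li, extract_all(vol, seg))
    }
    per_method[[m]] <- feature_table(rows, gt$lesion_id, m)
    utils::write.csv(per_method[[m]],
                     file.path(out_dir, paste0("features_", m, ".csv")),
                     row.names = FALSE)
  }

  say("stage test-retest: 2 pairs")
  tr_feats <- list()
  for (pair in 1:2) {
    for (half in c("test", "retest")) {
      rows <- vector("list", nrow(gt))
      for (li in seq_len(nrow(gt))) {
        s <- settings_for(standard, li, 5000L + pair)
        s$seed <- child_seed(s$seed, if (half == "test") 1L else 2L)
        vol <- suppressWarnings(simulate_acquisition(study$lesions[[li]], s))
        seg <- stage("segment", li, segment_volume(
          vol, "adaptive", study$lesions[[li]]$background, calibration))
        rows[[li]] <- stage("features", li, extract_all(vol, seg))
      }
      tr_feats[[paste0(half, pair)]] <- feature_table(
        rows, gt$lesion_id, paste0(half, pair))
    }
  }

  say("stage evaluate")
  fried <- if (length(config$methods) >= 2) friedman_stability(
    lapply(per_method, feature_cols)) else NULL
  fams <- stats::setNames(grid$family, grid$setting_id)
  covst <- cov_stability(lapply(feats_by_setting, feature_cols), fams)
  icc <- icc_reproducibility(
    feature_cols(tr_feats$test1), feature_cols(tr_feats$retest1),
    feature_cols(tr_feats$test2), feature_cols(tr_feats$retest2),
    form = config$icc_form)
  ref <- per_method[[if ("adaptive" %in% config$methods) "adaptive" else 1L]]
  hom <- gt$h_gs == 0
  mw <- if (any(hom) && any(!hom)) heterogeneity_discrimination(
    feature_cols(ref)[hom, , drop = FALSE],
    feature_cols(ref)[!hom, , drop = FALSE]) else NULL
  hgs <- if (sum(!hom) >= 5) hgs_correlation(
    feature_cols(ref)[!hom, , drop = FALSE], gt$h_gs[!hom],
    method = config$cor_method) else NULL
  non_necrotic <- !(gt$layout %in% c("a", "b", "c", "f", "g"))
  sph <- if (sum(non_necrotic) >= 3) sphericity_agreement(
    feature_cols(ref)[non_necrotic, "M_Sphericity"],
    gt$s_gs[non_necrotic]) else NULL
  report <- build_report(friedman = fried, cov = covst, icc = icc,
                         mw = mw, hgs = hgs)
  utils::write.csv(report$table, file.path(out_dir, "report.csv"),
                   row.names = FALSE)
  summary_json <- list(
    summary = as.list(report$summary), funnel = as.list(report$funnel),
    sphericity_agreement = sph)
  jsonlite::write_json(summary_json, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")

  cfg_path <- file.path(out_dir, "config.yaml")
  write_study_config(config, cfg_path)
  manifest <- list(
    package_version = as.character(utils::packageVersion("phantomrad")),
    config = unclass(config),
    config_hash = unname(tools::md5sum(cfg_path)),
    seed = seed,
    outputs = list(
      ground_truth = "ground_truth.csv",
      features = paste0("features_", config$methods, ".csv"),
      report = "report.csv", summary = "summary.json"),
    settings_grid = grid$setting_id,
    test_retest_pairs = 2L)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  out <- c(manifest, list(report = report, out_dir = out_dir))
  class(out) <- "run_manifest"
  invisible(out)
}
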