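#' Default pipeline configuration
#'
#' A single nested list holding every tunable of the pipeline: analysis grid,
#' ring geometry, feature toggles, AIF constants, fit bounds, onset-detection
#' rule, selection thresholds, LOO mode, and the phantom/cohort specs used
#' when data are synthesized. Serializes round-trip stable to YAML; every
#' artifact directory records the config hash.
#'
#' @param ... named overrides merged into the defaults (nested lists merged
#'   recursively).
#' @return a \code{pipeline_config} list.
#' @export
default_config <- function(...) {
  cfg <- list(
    seed = 1L,
    grid = list(in_plane_mm = 1.5, slice_mm = 3.0, pad_px = 10L),
    ring = list(thickness_mm = 5.0, clip_to_prostate = TRUE,
                pz_tolerance_frac = 0.01),
    features = list(min_voxels = 10L, include_min = TRUE, include_max = TRUE),
    aif = unclass(aif_spec()),
    fit = list(lower = c(0, 1e-3, 0, 0), upper = c(3, 10, 0.3, 60),
               dt_fine = 0.5),
    onset = list(k = 3, consecutive = 2L, baseline_subtract = TRUE),
    selection = list(p_pass = 0.05, r_max = 0.85, max_k = 4L),
    loo = list(nested = FALSE, threshold = 0.5),
    phantom = list(grid_shape = c(48L, 48L, 16L), spacing_mm = c(1.5, 1.5, 3.0),
                   prostate_radius_mm = c(24, 20, 18), pz_fraction = 0.35,
                   n_gtv = 1L, gtv_radius_mm = 7,
                   noise_sd = list(adc = 150, dce = 0.05),
                   dce_dt_s = 5, dce_duration_s = 300, dce_onset_s = 20),
    cohort = list(n_patients = 25L, positive_fraction_target = 0.2))
  ov <- list(...)
  if (length(ov)) cfg <- utils::modifyList(cfg, ov)
  class(cfg) <- c("pipeline_config", "list")
  cfg
}

#' Read / write a pipeline configuration as YAML
#'
#' @param cfg a \code{pipeline_config}.
#' @param path YAML file path.
#' @return \code{read_config} returns a \code{pipeline_config}.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  cfg <- default_config()
  cfg <- utils::modifyList(cfg, yaml::read_yaml(path))
  class(cfg) <- c("pipeline_config", "list")
  cfg
}

#' Hash of a configuration (provenance stamp)
#'
#' @param cfg a \code{pipeline_config}.
#' @return md5 hex string of the canonical YAML serialization.
#' @export
config_hash <- function(cfg) {
  tf <- tempfile(fileext = ".yaml")
  on.exit(unlink(tf))
  yaml::write_yaml(unclass(cfg), tf)
  unname(tools::md5sum(tf))
}

#' Build the phantom / cohort specifications a config describes
#'
#' @param cfg a \code{pipeline_config}.
#' @param seed seed override (defaults to the config seed).
#' @return a \code{\link{phantom_spec}} or \code{\link{cohort_spec}}.
#' @export
config_phantom_spec <- function(cfg, seed = cfg$seed) {
  ph <- cfg$phantom
  phantom_spec(grid_shape = ph$grid_shape, spacing_mm = ph$spacing_mm,
               prostate_radius_mm = ph$prostate_radius_mm,
               pz_fraction = ph$pz_fraction, n_gtv = ph$n_gtv,
               gtv_radius_mm = ph$gtv_radius_mm, noise_sd = ph$noise_sd,
               dce_dt_s = ph$dce_dt_s, dce_duration_s = ph$dce_duration_s,
               dce_onset_s = ph$dce_onset_s, seed = seed)
}

#' @rdname config_phantom_spec
#' @export
config_cohort_spec <- function(cfg, seed = cfg$seed) {
  co <- cfg$cohort
  cohort_spec(n_patients = co$n_patients,
              label_model = default_label_model(
                positive_fraction_target = co$positive_fraction_target),
              scan_counts = co$scan_counts, seed = seed)
}

#' Extract all features for one scan of one patient
#'
#' Standardizes the volumes onto the analysis grid, crops to the prostate,
#' derives the five ROIs, and extracts the first-order ADC statistics plus
#' the DCE pharmacokinetic features for each.
#'
#' @param adc 3-D \code{image_volume}.
#' @param dce 4-D \code{image_volume}.
#' @param masks list with \code{prostate}, \code{pz}, \code{gtv} masks on the
#'   acquisition grid of \code{adc}.
#' @param cfg a \code{pipeline_config}.
#' @param n_baseline pre-bolus frame count for the DCE curves.
#' @return named numeric feature vector.
#' @export
extract_scan_features <- function(adc, dce, masks, cfg = default_config(),
                                  n_baseline = 3L) {
  grid <- grid_spec(cfg$grid$in_plane_mm, cfg$grid$slice_mm, cfg$grid$pad_px)
  sp <- vol_spacing(adc)
  adc_r <- resample(adc, grid, kind = "image")
  dce_r <- resample(dce, grid, kind = "image")
  msk <- lapply(masks[c("prostate", "pz", "gtv")], function(m) {
    attr(m, "spacing_mm") <- sp
    vol_data(resample(m, grid, kind = "mask"))
  })
  box <- crop_box(msk$prostate, grid$pad_px)
  adc_c <- apply_crop(vol_data(adc_r), box)
  dce_c <- apply_crop(vol_data(dce_r), box)
  msk <- lapply(msk, apply_crop, box = box)
  rois <- derive_rois(msk$prostate, msk$pz, msk$gtv,
                      spacing_mm = vol_spacing(adc_r),
                      thickness_mm = cfg$ring$thickness_mm,
                      tol_frac = cfg$ring$pz_tolerance_frac)
  aif <- do.call(aif_spec, cfg$aif)
  c(extract_adc_features(adc_c, rois, min_voxels = cfg$features$min_voxels,
                         include_min = cfg$features$include_min,
                         include_max = cfg$features$include_max),
    extract_dce_features(image_volume(dce_c, vol_spacing(dce_r), t_s = dce$t_s),
                         rois, aif = aif, n_baseline = n_baseline,
                         min_voxels = cfg$features$min_voxels,
                         lower = cfg$fit$lower, upper = cfg$fit$upper,
                         dt_fine = cfg$fit$dt_fine))
}

#' Feature table for a synthetic cohort
#'
#' Materializes each present patient-scan, runs the full extraction, and
#' assembles the wide feature table (one row per patient per scan point).
#' Volumes are processed one at a time and discarded, so memory stays flat.
#'
#' @param cohort_data result of \code{\link{generate_cohort}}.
#' @param cfg a \code{pipeline_config}.
#' @param scans scan points to process (default: all in the cohort).
#' @param verbose print progress.
#' @return wide feature data.frame.
#' @export
cohort_feature_table <- function(cohort_data, cfg = default_config(),
                                 scans = cohort_data$cohort_spec$scan_points,
                                 verbose = FALSE) {
  rows <- list()
  for (pid in cohort_data$patients) {
    for (s in scans) {
      if (!cohort_data$scans[pid, s]) next
      ph <- materialize_scan(cohort_data, pid, s)
      fv <- extract_scan_features(ph$adc, ph$dce, ph$masks, cfg = cfg,
                                  n_baseline = ph$truth$n_baseline)
      rows[[length(rows) + 1L]] <-
        cbind(data.frame(patient_id = pid, scan_point = s,
                         stringsAsFactors = FALSE),
              as.data.frame(as.list(fv), check.names = FALSE))
      if (verbose) message(pid, " ", s, " done")
    }
  }
  do.call(rbind, rows)
}

#' Run the full pipeline into an artifact directory
#'
#' Synthesizes a cohort from the config, extracts all features, writes the
#' longitudinal report, fits the outcome model for every comparison with at
#' least one screened feature, and records config, hash, and log. Identical
#' config and seed give identical outputs.
#'
#' @param cfg a \code{pipeline_config}.
#' @param out_dir artifact directory (created).
#' @param scans scan points to process.
#' @param write_volumes also write the NIfTI volumes (large; off by default).
#' @return list with \code{features}, \code{labels}, \code{report},
#'   \code{models}, \code{dir}, invisibly.
#' @export
run_pipeline <- function(cfg = default_config(), out_dir, scans = scan_levels(),
                         write_volumes = FALSE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "log.txt")
  logf <- function(...) cat(sprintf(...), "\n", sep = "", file = log_path,
                            append = TRUE)
  cat(sprintf("pipeline started %s\n", format(Sys.time())), file = log_path)
  h <- config_hash(cfg)
  write_config(cfg, file.path(out_dir, "config.yaml"))
  logf("config hash: %s", h)

  cohort <- generate_cohort(config_cohort_spec(cfg), config_phantom_spec(cfg))
  if (write_volumes) write_cohort(cohort, file.path(out_dir, "volumes"))
  feats <- cohort_feature_table(cohort, cfg, scans = scans)
  utils::write.csv(feats, file.path(out_dir, "features.csv"), row.names = FALSE)
  utils::write.csv(cohort$labels, file.path(out_dir, "labels.csv"),
                   row.names = FALSE)
  jsonlite::write_json(c(list(config_hash = h), cohort$truth),
                       file.path(out_dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  logf("features: %d rows x %d columns", nrow(feats), ncol(feats) - 2L)

  report <- longitudinal_report(feats)
  utils::write.csv(report, file.path(out_dir, "longitudinal_report.csv"),
                   row.names = FALSE)

  comparisons <- build_comparisons(feats, cohort$labels)
  models <- list()
  for (cmp in comparisons) {
    res <- tryCatch(
      fit_and_evaluate_loo(cmp$X, cmp$y,
                           threshold = cfg$loo$threshold,
                           nested = cfg$loo$nested,
                           p_pass = cfg$selection$p_pass,
                           r_max = cfg$selection$r_max,
                           max_k = cfg$selection$max_k),
      error = function(e) e)
    if (inherits(res, "error")) {
      logf("comparison %s skipped: %s", cmp$name, conditionMessage(res))
      next
    }
    models[[cmp$name]] <- res
    jsonlite::write_json(
      list(comparison = cmp$name, n = res$n,
           selected_features = res$selected_features,
           coefficients = as.list(res$coefficients),
           auc = res$auc, f1 = res$f1,
           confusion = as.vector(res$confusion),
           heldout_probs = res$heldout_probs, config_hash = h),
      file.path(out_dir, paste0("model_", gsub("-", "m", cmp$name), ".json")),
      auto_unbox = TRUE, digits = NA)
    utils::write.csv(res$roc,
                     file.path(out_dir, paste0("roc_", gsub("-", "m", cmp$name),
                                               ".csv")),
                     row.names = FALSE)
    logf("comparison %s: n=%d AUC=%.3f F1=%s features=[%s]",
         cmp$name, res$n, res$auc,
         ifelse(is.na(res$f1), "NA", sprintf("%.3f", res$f1)),
         paste(res$selected_features, collapse = ", "))
  }
  logf("pipeline finished %s", format(Sys.time()))
  invisible(list(features = feats, labels = cohort$labels, report = report,
                 models = models, cohort = cohort, dir = out_dir,
                 config_hash = h))
}
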