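#' Reference longitudinal means anchoring the synthetic cohort
#'
#' Published cohort-level means (and between-patient SDs at baseline) of the
#' quantitative features in the three tissue classes at the four scan points:
#' ADC in 1e-6 mm^2/s, Ktrans and kep in 1/min, ve as a fraction. These
#' anchor the tissue-parameter distributions and the default longitudinal
#' trajectories of the phantom generator.
#'
#' @return nested list: \code{$means[[param]][[class]]} length-4 numeric
#'   (S1..S4), \code{$sds[[param]][[class]]} baseline SD.
#' @export
reference_cohort_anchors <- function() {
  list(
    means = list(
      adc = list(gtv = c(1177.84, 1362.45, 1474.76, 1388.68),
                 nat_pz = c(1616.37, 1435.44, 1493.89, 1445.18),
                 nat_tz = c(1381.76, 1303.92, 1357.37, 1361.00)),
      Ktrans = list(gtv = c(0.12, 0.12, 0.11, 0.09),
                    nat_pz = c(0.08, 0.13, 0.09, 0.10),
                    nat_tz = c(0.12, 0.14, 0.09, 0.12)),
      ve = list(gtv = c(0.2554, 0.5880, 0.4637, 0.6658),
                nat_pz = c(0.2282, 0.5513, 0.6634, 0.6515),
                nat_tz = c(0.3355, 0.5266, 0.4662, 0.5930))),
    sds = list(
      adc = list(gtv = 217.12, nat_pz = 304.02, nat_tz = 170.34),
      Ktrans = list(gtv = 0.05, nat_pz = 0.05, nat_tz = 0.06),
      ve = list(gtv = 0.0821, nat_pz = 0.1112, nat_tz = 0.1273)))
}

#' Default per-tissue-class parameter distributions
#'
#' Baseline means and between-patient SDs for ADC and the Tofts parameters in
#' each tissue class (tumor, normal PZ, normal TZ, plus a periprostatic
#' background class), anchored to the reference cohort values.
#'
#' @return nested list by class with elements \code{adc_mean, adc_sd,
#'   Ktrans_mean, Ktrans_sd, ve_mean, ve_sd, vp_mean, vp_sd}.
#' @export
default_tissue_params <- function() {
  a <- reference_cohort_anchors()
  mk <- function(cl) list(
    adc_mean = a$means$adc[[cl]][1], adc_sd = a$sds$adc[[cl]],
    Ktrans_mean = a$means$Ktrans[[cl]][1], Ktrans_sd = a$sds$Ktrans[[cl]],
    ve_mean = a$means$ve[[cl]][1], ve_sd = a$sds$ve[[cl]],
    vp_mean = 0.02, vp_sd = 0.01)
  list(gtv = mk("gtv"), nat_pz = mk("nat_pz"), nat_tz = mk("nat_tz"),
       background = list(adc_mean = 700, adc_sd = 100,
                         Ktrans_mean = 0.02, Ktrans_sd = 0.01,
                         ve_mean = 0.15, ve_sd = 0.05,
                         vp_mean = 0.01, vp_sd = 0.005))
}

#' Digital-phantom specification
#'
#' A schematic prostate: an ellipsoid on a regular grid, a posterior shell
#' assigned to the peripheral zone, and 1-3 spherical lesions placed inside
#' the gland (predominantly in the PZ). Voxel values are drawn around
#' class-level means with additive Gaussian noise; the DCE series is
#' synthesized in concentration units (mM) by the Extended Tofts forward
#' model with the Parker population AIF.
#'
#' @param grid_shape voxels per axis (default 48 x 48 x 16).
#' @param spacing_mm per-axis voxel size in mm (default 1.5 x 1.5 x 3).
#' @param prostate_radius_mm ellipsoid semi-axes in mm.
#' @param pz_fraction posterior fraction of prostate voxels assigned to PZ.
#' @param n_gtv lesion count in 1..3.
#' @param gtv_radius_mm per-lesion sphere radius in mm (recycled).
#' @param tissue_params class-level distributions, see
#'   \code{\link{default_tissue_params}}.
#' @param noise_sd list with \code{adc} (1e-6 mm^2/s) and \code{dce} (mM)
#'   additive voxel noise SDs.
#' @param dce_dt_s DCE frame interval (s).
#' @param dce_duration_s total DCE duration (s, >= 150 so AUC120 exists).
#' @param dce_onset_s bolus arrival time (s).
#' @param seed RNG seed.
#' @return an object of class \code{phantom_spec}.
#' @export
phantom_spec <- function(grid_shape = c(48L, 48L, 16L),
                         spacing_mm = c(1.5, 1.5, 3.0),
                         prostate_radius_mm = c(24, 20, 18),
                         pz_fraction = 0.35,
                         n_gtv = 1L,
                         gtv_radius_mm = 7,
                         tissue_params = default_tissue_params(),
                         noise_sd = list(adc = 150, dce = 0.05),
                         dce_dt_s = 5,
                         dce_duration_s = 300,
                         dce_onset_s = 20,
                         seed = 1L) {
  stopifnot(all(spacing_mm > 0), all(prostate_radius_mm > 0),
            all(gtv_radius_mm > 0), pz_fraction > 0, pz_fraction < 1,
            n_gtv %in% 1:3, dce_dt_s > 0)
  if (dce_duration_s < 150)
    stop("dce_duration_s must be >= 150 so AUC120 is computable")
  structure(list(grid_shape = as.integer(grid_shape),
                 spacing_mm = as.numeric(spacing_mm),
                 prostate_radius_mm = as.numeric(prostate_radius_mm),
                 pz_fraction = pz_fraction, n_gtv = as.integer(n_gtv),
                 gtv_radius_mm = rep_len(as.numeric(gtv_radius_mm), n_gtv),
                 tissue_params = tissue_params, noise_sd = noise_sd,
                 dce_dt_s = dce_dt_s, dce_duration_s = dce_duration_s,
                 dce_onset_s = dce_onset_s, seed = as.integer(seed)),
            class = "phantom_spec")
}

# voxel-centre physical coordinates (mm) along each axis
axis_coords <- function(n, sp) (seq_len(n) - 0.5) * sp

# 3-D arrays of squared normalized ellipsoid coordinates about the grid centre
ellipsoid_mask <- function(grid_shape, spacing_mm, semi_axes, centre_mm = NULL) {
  if (is.null(centre_mm)) centre_mm <- grid_shape * spacing_mm / 2
  cx <- axis_coords(grid_shape[1], spacing_mm[1]) - centre_mm[1]
  cy <- axis_coords(grid_shape[2], spacing_mm[2]) - centre_mm[2]
  cz <- axis_coords(grid_shape[3], spacing_mm[3]) - centre_mm[3]
  q <- outer(outer((cx / semi_axes[1])^2, (cy / semi_axes[2])^2, `+`),
             (cz / semi_axes[3])^2, `+`)
  q <= 1
}

# deterministic lesion placement: sample a centre among voxels where the
# sphere fits entirely inside the prostate ellipsoid, preferring the target zone
place_gtv <- function(spec, prostate, pz, radius, zone, lesion_id) {
  d <- spec$grid_shape; sp <- spec$spacing_mm
  centre_mm <- d * sp / 2
  shrunk <- pmax(spec$prostate_radius_mm - radius, 0.1)
  feasible <- ellipsoid_mask(d, sp, shrunk, centre_mm)
  cand <- if (zone == "pz") feasible & pz else feasible & prostate & !pz
  if (!any(cand)) cand <- feasible & prostate   # fall back to anywhere inside
  if (!any(cand))
    stop(sprintf("lesion %d: no feasible centre for a %.1f mm GTV inside the prostate",
                 lesion_id, radius))
  idx <- which(cand)
  pick <- idx[sample.int(length(idx), 1L)]
  ai <- arrayInd(pick, d)
  ctr <- (as.numeric(ai) - 0.5) * sp
  ellipsoid_mask(d, sp, rep(radius, 3), ctr)
}

#' Generate one digital phantom scan
#'
#' Builds the prostate/PZ/GTV masks, an ADC map, and a 4-D DCE concentration
#' series. Geometry (lesion placement) and noise can be seeded separately so
#' a patient keeps the same anatomy across scan points while noise differs.
#' Identical seeds give bit-identical output.
#'
#' @param spec a \code{\link{phantom_spec}}.
#' @param geometry_seed seed for lesion placement (default \code{spec$seed}).
#' @param noise_seed seed for voxel noise (default \code{spec$seed}).
#' @return list with \code{adc} (\code{image_volume}), \code{dce} (4-D
#'   \code{image_volume}), \code{masks} (prostate, pz, gtv, gtvs),
#'   \code{class_map}, and \code{truth} (the generating parameters).
#' @export
generate_phantom <- function(spec, geometry_seed = spec$seed,
                             noise_seed = spec$seed) {
  d <- spec$grid_shape; sp <- spec$spacing_mm
  prostate <- ellipsoid_mask(d, sp, spec$prostate_radius_mm)
  # posterior shell: highest-y fraction of prostate voxels
  ycoord <- array(rep(rep(axis_coords(d[2], sp[2]), each = d[1]), d[3]), d)
  ythr <- stats::quantile(ycoord[prostate], probs = 1 - spec$pz_fraction,
                          names = FALSE, type = 7)
  pz <- prostate & (ycoord > ythr)

  set.seed(geometry_seed)
  zones <- c("pz", if (spec$n_gtv > 1) sample(c("pz", "tz"), spec$n_gtv - 1L,
                                              replace = TRUE,
                                              prob = c(0.85, 0.15)))
  gtvs <- vector("list", spec$n_gtv)
  for (i in seq_len(spec$n_gtv))
    gtvs[[i]] <- place_gtv(spec, prostate, pz, spec$gtv_radius_mm[i],
                           zones[i], i)
  gtv <- merge_multifocal(gtvs)

  # class map: tumor claims its voxels, then PZ, then TZ, 0 = background
  cls <- array(0L, d)
  cls[prostate & !pz] <- 3L
  cls[pz] <- 2L
  cls[gtv] <- 1L
  cls_names <- c("gtv", "nat_pz", "nat_tz")

  set.seed(noise_seed)
  tp <- spec$tissue_params
  adc <- array(0, d)
  bg <- cls == 0L
  adc[bg] <- tp$background$adc_mean
  for (ci in 1:3) adc[cls == ci] <- tp[[cls_names[ci]]]$adc_mean
  if (spec$noise_sd$adc > 0)
    adc <- adc + stats::rnorm(length(adc), 0, spec$noise_sd$adc)
  adc <- pmax(array(adc, d), 0)

  t_s <- seq(0, spec$dce_duration_s, by = spec$dce_dt_s)
  n_baseline <- max(2L, sum(t_s < spec$dce_onset_s))
  curves <- lapply(c(cls_names, "background"), function(cl) {
    p <- tp[[cl]]
    tofts_forward(Ktrans = p$Ktrans_mean, kep = p$Ktrans_mean / p$ve_mean,
                  vp = p$vp_mean, t_onset = spec$dce_onset_s, t_s = t_s)
  })
  names(curves) <- c(cls_names, "background")
  nt <- length(t_s)
  # rows = classes (background, gtv, nat_pz, nat_tz), one gather per cohort
  cmat <- rbind(curves$background, curves$gtv, curves$nat_pz, curves$nat_tz)
  dce <- cmat[as.vector(cls) + 1L, , drop = FALSE]
  if (spec$noise_sd$dce > 0)
    dce <- dce + stats::rnorm(length(dce), 0, spec$noise_sd$dce)
  dce <- array(pmax(dce, 0), c(d, nt))

  list(adc = image_volume(adc, sp),
       dce = image_volume(dce, sp, t_s = t_s),
       masks = list(prostate = prostate, pz = pz, gtv = gtv, gtvs = gtvs),
       class_map = cls,
       truth = list(tissue_params = tp, curves = curves, t_s = t_s,
                    n_baseline = n_baseline, dce_onset_s = spec$dce_onset_s,
                    zones = zones))
}

#' Cohort specification for the synthetic longitudinal study
#'
#' @param n_patients cohort size (>= 6 so every leave-one-out fold keeps both
#'   classes plausible).
#' @param scan_points scan labels (default S1..S4).
#' @param label_model list with \code{coefficients} (named, on baseline
#'   true features standardized by the reference anchors), optional
#'   \code{intercept}, and \code{positive_fraction_target} used to calibrate
#'   the intercept when it is \code{NULL}.
#' @param trajectories per-class, per-parameter longitudinal multipliers;
#'   defaults are the ratios of the reference cohort means to baseline.
#' @param scan_counts optional named vector of per-scan patient counts to
#'   emulate dropout (e.g. \code{c(S1=25, S2=25, S3=24, S4=20)}).
#' @param adc_ve_corr within-class correlation between a patient's ADC mean
#'   and ve draw (default 0.5): both reflect tissue cellularity, so cellular
#'   tumors sit low on both axes.
#' @param seed RNG seed.
#' @return an object of class \code{cohort_spec}.
#' @export
cohort_spec <- function(n_patients = 25L,
                        scan_points = scan_levels(),
                        label_model = default_label_model(),
                        trajectories = default_trajectories(),
                        scan_counts = NULL,
                        adc_ve_corr = 0.5,
                        seed = 1L) {
  stopifnot(n_patients >= 6L)
  if (!is.null(scan_counts)) {
    scan_counts <- unlist(scan_counts)
    stopifnot(all(names(scan_counts) %in% scan_points),
              all(scan_counts <= n_patients))
  }
  stopifnot(adc_ve_corr >= -1, adc_ve_corr <= 1)
  structure(list(n_patients = as.integer(n_patients),
                 scan_points = scan_points, label_model = label_model,
                 trajectories = trajectories, scan_counts = scan_counts,
                 adc_ve_corr = adc_ve_corr,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Default longitudinal trajectories
#'
#' Piecewise multipliers per scan point for each tissue class and parameter,
#' taken as the ratio of the reference cohort mean at each scan to its
#' baseline mean (tumor ADC rises after treatment, tumor kep falls as ve
#' rises).
#'
#' @return nested list \code{[[param]][[class]]} of length-4 multipliers.
#' @export
default_trajectories <- function() {
  a <- reference_cohort_anchors()$means
  lapply(a, function(per_param)
    lapply(per_param, function(v) v / v[1]))
}

#' Default label model linking baseline features to biopsy positivity
#'
#' Endpoint-biopsy positivity is drawn from a Bernoulli whose logit is a
#' linear combination of standardized baseline true features: a strong
#' negative weight on tumor ADC mean (low-ADC, i.e. cellular, tumors fail
#' more often) and a positive weight on tumor ve. The weights are steep so
#' the class membership is a nearly deterministic function of the generating
#' features -- the cohort is built to carry recoverable signal. The intercept
#' is calibrated so the expected prevalence matches
#' \code{positive_fraction_target}.
#'
#' @param coefficients named numeric vector on standardized baseline features.
#' @param intercept fixed intercept, or \code{NULL} to calibrate.
#' @param positive_fraction_target expected prevalence (default 0.2).
#' @return list describing the label model.
#' @export
default_label_model <- function(coefficients = c(GTV_ADC_Mean = -20,
                                                 GTV_DCE_ve = -8),
                                intercept = NULL,
                                positive_fraction_target = 0.2) {
  list(coefficients = coefficients, intercept = intercept,
       positive_fraction_target = positive_fraction_target)
}

# feature names the label model may reference, and their standardized values
# computed from the per-patient true baseline parameters
label_feature_matrix <- function(params_s1) {
  a <- reference_cohort_anchors()
  cls_pretty <- c(gtv = "GTV", nat_pz = "NAT-PZ", nat_tz = "NAT-TZ")
  cols <- list()
  for (cl in names(cls_pretty)) {
    get <- function(field) vapply(params_s1, function(p) p[[cl]][[field]], 0)
    cols[[paste0(cls_pretty[cl], "_ADC_Mean")]] <-
      (get("adc_mean") - a$means$adc[[cl]][1]) / a$sds$adc[[cl]]
    cols[[paste0(cls_pretty[cl], "_DCE_Ktrans")]] <-
      (get("Ktrans") - a$means$Ktrans[[cl]][1]) / a$sds$Ktrans[[cl]]
    cols[[paste0(cls_pretty[cl], "_DCE_ve")]] <-
      (get("ve") - a$means$ve[[cl]][1]) / a$sds$ve[[cl]]
    cols[[paste0(cls_pretty[cl], "_DCE_kep")]] <-
      scale(get("Ktrans") / get("ve"))[, 1]
  }
  do.call(cbind, cols)
}

rtrunc_norm <- function(n, mean, sd, lo = -Inf, hi = Inf) {
  x <- stats::rnorm(n, mean, sd)
  pmin(pmax(x, lo), hi)
}

# documented seed-splitting rule: one global seed expands to per-patient
# geometry streams and per-patient-per-scan noise streams
child_seed <- function(seed, patient, scan = 0L) {
  as.integer((seed + 1000003 * patient + 7919 * scan) %% 2147483647L)
}

#' Generate a synthetic longitudinal cohort
#'
#' Draws per-patient baseline tissue parameters from the class
#' distributions, applies the longitudinal trajectory multipliers at each
#' scan point, and draws endpoint-biopsy labels from the logistic label
#' model on the true baseline features. Volumes are not materialized here
#' (see \code{\link{materialize_scan}}), so large cohorts stay cheap.
#'
#' @param cohort a \code{\link{cohort_spec}}.
#' @param phantom a \code{\link{phantom_spec}} (geometry and noise template).
#' @return list with \code{patients}, \code{scans} (data.frame patient x
#'   scan presence), \code{params} (per patient, per scan, per class),
#'   \code{labels} (data.frame), and \code{truth}.
#' @export
generate_cohort <- function(cohort, phantom) {
  known <- c(outer(c("GTV", "NAT-PZ", "NAT-TZ"),
                   c("_ADC_Mean", "_DCE_Ktrans", "_DCE_ve", "_DCE_kep"),
                   paste0))
  unknown <- setdiff(names(cohort$label_model$coefficients), known)
  if (length(unknown))
    stop("label_model references unknown feature(s): ",
         paste(unknown, collapse = ", "),
         "; known names: ", paste(sort(known), collapse = ", "))
  set.seed(cohort$seed)
  n <- cohort$n_patients
  ids <- sprintf("P%02d", seq_len(n))
  tp <- phantom$tissue_params
  traj <- cohort$trajectories
  scans <- cohort$scan_points
  params <- vector("list", n); names(params) <- ids
  rho <- cohort$adc_ve_corr
  for (i in seq_len(n)) {
    base <- list()
    for (cl in c("gtv", "nat_pz", "nat_tz")) {
      p <- tp[[cl]]
      # ADC and ve share a cellularity axis: correlated Gaussian draws
      z1 <- stats::rnorm(1); z2 <- stats::rnorm(1)
      z_ve <- rho * z1 + sqrt(1 - rho^2) * z2
      base[[cl]] <- list(
        adc_mean = max(p$adc_mean + p$adc_sd * z1, 100),
        Ktrans = rtrunc_norm(1, p$Ktrans_mean, p$Ktrans_sd, lo = 0.005),
        ve = min(max(p$ve_mean + p$ve_sd * z_ve, 0.03), 0.95),
        vp = rtrunc_norm(1, p$vp_mean, p$vp_sd, lo = 0, hi = 0.15))
    }
    per_scan <- vector("list", length(scans)); names(per_scan) <- scans
    for (s in seq_along(scans)) {
      ps <- base
      for (cl in names(ps)) {
        ps[[cl]]$adc_mean <- base[[cl]]$adc_mean * traj$adc[[cl]][s]
        ps[[cl]]$Ktrans <- base[[cl]]$Ktrans * traj$Ktrans[[cl]][s]
        ps[[cl]]$ve <- min(base[[cl]]$ve * traj$ve[[cl]][s], 0.95)
      }
      per_scan[[scans[s]]] <- ps
    }
    params[[i]] <- per_scan
  }
  # labels from the true baseline features
  lm <- cohort$label_model
  Xl <- label_feature_matrix(lapply(params, function(p) p[[scans[1]]]))
  eta <- as.numeric(Xl[, names(lm$coefficients), drop = FALSE] %*%
                      lm$coefficients)
  b0 <- lm$intercept
  if (is.null(b0)) {
    target <- lm$positive_fraction_target
    b0 <- stats::uniroot(function(b) mean(stats::plogis(eta + b)) - target,
                         lower = -50, upper = 50)$root
  }
  pr <- stats::plogis(eta + b0)
  labels <- stats::rbinom(n, 1, pr)
  # scan presence (optional dropout, later scans lose patients at random)
  present <- matrix(TRUE, n, length(scans), dimnames = list(ids, scans))
  if (!is.null(cohort$scan_counts)) {
    for (s in names(cohort$scan_counts)) {
      keep <- sort(sample.int(n, cohort$scan_counts[[s]]))
      present[, s] <- seq_len(n) %in% keep
    }
  }
  list(patients = ids,
       scans = as.data.frame(present),
       params = params,
       labels = data.frame(patient_id = ids, label = labels,
                           stringsAsFactors = FALSE),
       truth = list(label_model = utils::modifyList(lm, list(intercept = b0)),
                    linear_predictor = eta + b0, prob = pr,
                    trajectories = traj, seed = cohort$seed),
       phantom_spec = phantom, cohort_spec = cohort)
}

#' Materialize the volumes of one patient scan
#'
#' Rebuilds the phantom for a given patient and scan point from the cohort's
#' stored true parameters: the anatomy is seeded per patient (stable across
#' scans), the noise per patient-scan.
#'
#' @param cohort_data result of \code{\link{generate_cohort}}.
#' @param patient patient id or index.
#' @param scan scan label (e.g. \code{"S2"}).
#' @return same structure as \code{\link{generate_phantom}}.
#' @export
materialize_scan <- function(cohort_data, patient, scan) {
  ids <- cohort_data$patients
  i <- if (is.character(patient)) match(patient, ids) else patient
  if (is.na(i)) stop("unknown patient: ", patient)
  s <- match(scan, cohort_data$cohort_spec$scan_points)
  if (is.na(s)) stop("unknown scan point: ", scan)
  spec <- cohort_data$phantom_spec
  ps <- cohort_data$params[[i]][[scan]]
  tp <- spec$tissue_params
  for (cl in names(ps)) {
    tp[[cl]]$adc_mean <- ps[[cl]]$adc_mean
    tp[[cl]]$Ktrans_mean <- ps[[cl]]$Ktrans
    tp[[cl]]$ve_mean <- ps[[cl]]$ve
    tp[[cl]]$vp_mean <- ps[[cl]]$vp
  }
  spec$tissue_params <- tp
  generate_phantom(spec,
                   geometry_seed = child_seed(cohort_data$cohort_spec$seed, i, 0L),
                   noise_seed = child_seed(cohort_data$cohort_spec$seed, i, s))
}

#' Write a cohort to disk as NIfTI volumes plus manifest
#'
#' One ADC and one DCE NIfTI per patient per scan, binary masks, a manifest
#' CSV with the biopsy labels, and the generating truth as JSON.
#'
#' @param cohort_data result of \code{\link{generate_cohort}}.
#' @param dir output directory (created).
#' @param patients,scans subsets to write (defaults: all present).
#' @return the manifest data.frame, invisibly.
#' @export
write_cohort <- function(cohort_data, dir,
                         patients = cohort_data$patients,
                         scans = cohort_data$cohort_spec$scan_points) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  for (pid in patients) {
    for (s in scans) {
      if (!cohort_data$scans[pid, s]) next
      ph <- materialize_scan(cohort_data, pid, s)
      stem <- file.path(dir, paste0(pid, "_", s))
      write_volume_nifti(ph$adc, paste0(stem, "_ADC.nii.gz"))
      write_volume_nifti(ph$dce, paste0(stem, "_DCE.nii.gz"))
      for (m in c("prostate", "pz", "gtv"))
        write_volume_nifti(ph$masks[[m]], paste0(stem, "_mask_", m, ".nii.gz"),
                           spacing_mm = cohort_data$phantom_spec$spacing_mm)
      rows[[length(rows) + 1L]] <- data.frame(patient_id = pid, scan_point = s,
                                              stem = basename(stem),
                                              stringsAsFactors = FALSE)
    }
  }
  manifest <- merge(do.call(rbind, rows), cohort_data$labels, by = "patient_id")
  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  jsonlite::write_json(cohort_data$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
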