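test_that("phantom masks obey the containment algebra and are seeded", {
  spec <- small_phantom(n_gtv = 2L, seed = 41)
  ph <- generate_phantom(spec)
  expect_true(all(ph$masks$prostate[ph$masks$pz]))
  expect_true(all(ph$masks$prostate[ph$masks$gtv]))
  pzfrac <- sum(ph$masks$pz) / sum(ph$masks$prostate)
  expect_lt(abs(pzfrac - spec$pz_fraction), 0.08)  # coarse-grid quantile ties

  ph2 <- generate_phantom(spec)
  expect_identical(ph$adc$data, ph2$adc$data)       # bit-identical under seed
  expect_identical(ph$dce$data, ph2$dce$data)
  expect_identical(ph$masks, ph2$masks)

  ph3 <- generate_phantom(spec, noise_seed = 99L)
  expect_false(identical(ph$adc$data, ph3$adc$data))
  expect_identical(ph$masks, ph3$masks)             # geometry seed unchanged
})

test_that("zero-noise phantom voxels equal the class means", {
  spec <- small_phantom(noise_sd = list(adc = 0, dce = 0), seed = 43)
  ph <- generate_phantom(spec)
  tp <- spec$tissue_params
  expect_true(all(ph$adc$data[ph$masks$gtv] == tp$gtv$adc_mean))
  nat_pz <- ph$masks$pz & !ph$masks$gtv
  expect_true(all(ph$adc$data[nat_pz] == tp$nat_pz$adc_mean))
})

test_that("an oversized lesion request fails with a clear error", {
  spec <- small_phantom(seed = 5)
  spec$gtv_radius_mm <- 40
  expect_error(generate_phantom(spec), "lesion 1")
})

test_that("cohort labels: symmetric null and monotone feature coupling", {
  spec <- small_phantom(seed = 47)
  # all-zero coefficients, intercept 0: prevalence ~ 0.5
  lm0 <- default_label_model(coefficients = c(GTV_ADC_Mean = 0), intercept = 0)
  co0 <- generate_cohort(cohort_spec(n_patients = 200, label_model = lm0,
                                     seed = 47), spec)
  phat <- mean(co0$labels$label)
  expect_lt(abs(phat - 0.5), 3 * sqrt(0.25 / 200))   # binomial tolerance

  # strong negative ADC weight: positives concentrate at low baseline ADC
  lm1 <- default_label_model(coefficients = c(GTV_ADC_Mean = -8),
                             positive_fraction_target = 0.3)
  co1 <- generate_cohort(cohort_spec(n_patients = 200, label_model = lm1,
                                     seed = 48), spec)
  adc <- sapply(co1$params, function(p) p$S1$gtv$adc_mean)
  y <- co1$labels$label
  low <- adc <= median(adc)
  expect_gt(mean(y[low]), mean(y[!low]) + 0.2)       # strong enrichment

  # unknown label feature is an error that lists the known names
  lm_bad <- default_label_model(coefficients = c(NOT_A_FEATURE = 1))
  expect_error(generate_cohort(cohort_spec(label_model = lm_bad), spec),
               "known names")
})

test_that("cohort emits the full patient-by-scan grid with stable naming", {
  spec <- small_phantom(seed = 51)
  co <- generate_cohort(cohort_spec(n_patients = 25, seed = 51), spec)
  expect_length(co$patients, 25)
  expect_equal(dim(co$scans), c(25L, 4L))
  expect_true(all(as.matrix(co$scans)))
  expect_equal(co$patients, sprintf("P%02d", 1:25))
  # 100 materializable volume sets
  expect_equal(sum(as.matrix(co$scans)), 100)
  # per-patient anatomy is stable across scans, noise differs
  a <- materialize_scan(co, "P03", "S1")
  b <- materialize_scan(co, "P03", "S2")
  expect_identical(a$masks$gtv, b$masks$gtv)
  expect_false(identical(a$adc$data, b$adc$data))
})

test_that("default trajectories follow the reference directions", {
  tr <- default_trajectories()
  expect_gt(tr$adc$gtv[2], 1)       # tumor ADC rises at 3 months
  expect_lt(tr$adc$nat_pz[2], 1)    # normal PZ ADC falls
  expect_gt(tr$ve$gtv[2], 1)        # tumor ve rises
  # implied tumor kep falls when Ktrans is flat and ve rises
  expect_lt(tr$Ktrans$gtv[2] / tr$ve$gtv[2], 1)
  expect_equal(unname(sapply(tr$adc, `[`, 1)), rep(1, 3))
})

test_that("cohort NIfTI round trip preserves volumes and manifest", {
  spec <- small_phantom(seed = 53)
  co <- generate_cohort(cohort_spec(n_patients = 6, seed = 53), spec)
  dir <- tempfile("cohort")
  man <- write_cohort(co, dir, patients = "P01", scans = c("S1", "S2"))
  expect_equal(nrow(man), 2)
  expect_true(file.exists(file.path(dir, "truth.json")))
  ph <- materialize_scan(co, "P01", "S1")
  back <- read_volume_nifti(file.path(dir, "P01_S1_ADC.nii.gz"))
  expect_equal(back$data, ph$adc$data, tolerance = 1e-6)
  expect_equal(back$spacing_mm, spec$spacing_mm, tolerance = 1e-6)
  unlink(dir, recursive = TRUE)
})

test_that("zero-noise end-to-end run returns Tofts parameters within 2%", {
  spec <- small_phantom(noise_sd = list(adc = 0, dce = 0), seed = 57)
  co <- generate_cohort(cohort_spec(n_patients = 6, seed = 57), spec)
  # analysis grid equal to the phantom grid: no interpolation mixing
  cfg <- default_config(grid = list(in_plane_mm = 2, slice_mm = 3))
  ph <- materialize_scan(co, "P02", "S1")
  fv <- extract_scan_features(ph$adc, ph$dce, ph$masks, cfg,
                              n_baseline = ph$truth$n_baseline)
  truth <- co$params$P02$S1
  expect_lt(abs(fv[["GTV_DCE_Ktrans"]] - truth$gtv$Ktrans) / truth$gtv$Ktrans,
            0.02)
  kep_true <- truth$gtv$Ktrans / truth$gtv$ve
  expect_lt(abs(fv[["GTV_DCE_kep"]] - kep_true) / kep_true, 0.02)
  expect_lt(abs(fv[["GTV_DCE_ve"]] - truth$gtv$ve) / truth$gtv$ve, 0.02)
  expect_equal(fv[["GTV_ADC_Mean"]], truth$gtv$adc_mean, tolerance = 1e-9)
})
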