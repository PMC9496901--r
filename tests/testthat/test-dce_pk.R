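test_that("Parker AIF has the expected shape", {
  t <- seq(0, 360, by = 0.5)
  cp <- parker_aif(t)
  expect_true(all(cp >= 0))
  # pre-bolus value is negligible relative to the first-pass peak
  expect_lt(cp[1], 0.02 * max(cp))
  # single dominant first-pass peak within the first minute
  expect_lt(t[which.max(cp)], 60)
  # decays toward the recirculation tail after the peak region
  expect_gt(cp[t == 60], cp[t == 300])
  # doubling the Gaussian amplitudes doubles the Gaussian contribution
  s0 <- aif_spec(); s2 <- aif_spec(A1 = 2 * s0$A1, A2 = 2 * s0$A2)
  tail_only <- aif_spec(A1 = 0, A2 = 0)
  expect_equal(parker_aif(t, s2) - parker_aif(t, tail_only),
               2 * (parker_aif(t, s0) - parker_aif(t, tail_only)),
               tolerance = 1e-12)
})

test_that("Tofts forward model degenerate cases", {
  t <- seq(0, 300, 5)
  expect_error(tofts_forward(0.1, 0, 0, 0, t), "kep")
  expect_equal(tofts_forward(0, 0.5, 0, 0, t), rep(0, length(t)))
  # pure plasma term: Ct = vp * Cp exactly at the sample times
  ct <- tofts_forward(0, 0.5, 0.05, 0, t)
  expect_equal(ct, 0.05 * parker_aif(t), tolerance = 1e-9)
  # zero before onset
  ct2 <- tofts_forward(0.1, 0.5, 0.02, 50, t)
  expect_true(all(ct2[t < 50] == 0))
})

test_that("boxcar AIF reproduces the closed-form convolution within 0.5%", {
  t <- seq(0, 300, 2)
  box <- function(ts) as.numeric(ts >= 0 & ts <= 300)
  for (th in list(c(0.12, 0.49), c(0.3, 1.5), c(0.05, 0.16))) {
    ct <- tofts_forward(th[1], th[2], 0, 0, t, aif = box)
    ref <- th[1] / th[2] * (1 - exp(-th[2] / 60 * t))
    expect_lt(max(abs(ct[-1] - ref[-1]) / ref[-1]), 0.005)
  }
})

test_that("halving the quadrature step changes the curve by < 0.25%", {
  t <- seq(0, 300, 5)
  ct1 <- tofts_forward(0.12, 0.49, 0.02, 20, t, dt_fine = 0.5)
  ct2 <- tofts_forward(0.12, 0.49, 0.02, 20, t, dt_fine = 0.25)
  rel <- abs(ct2 - ct1)[ct1 > 0] / ct1[ct1 > 0]
  expect_lt(max(rel), 0.0025)
})

test_that("noise-free forward/fit round trip recovers parameters within 1%", {
  t <- seq(0, 300, 5)
  grid <- expand.grid(Ktrans = c(0.08, 0.12, 0.14), kep = c(0.16, 0.37, 0.49))
  for (i in seq_len(nrow(grid))) {
    th <- c(grid$Ktrans[i], grid$kep[i], 0.02, 20)
    cur <- contrast_curve(t, tofts_forward(th[1], th[2], th[3], th[4], t),
                          n_baseline = 3)
    f <- fit_tofts(cur)
    expect_true(f$converged)
    expect_lt(abs(f$Ktrans - th[1]) / th[1], 0.01)
    expect_lt(abs(f$kep - th[2]) / th[2], 0.01)
    expect_equal(f$ve, f$Ktrans / f$kep)   # identity by construction
  }
})

test_that("the fit is deterministic and flags the null curve", {
  t <- seq(0, 300, 5)
  cur <- contrast_curve(t, tofts_forward(0.12, 0.49, 0.02, 20, t) +
                          0.01 * sin(seq_along(t)), n_baseline = 3)
  f1 <- fit_tofts(cur); f2 <- fit_tofts(cur)
  expect_identical(unclass(f1), unclass(f2))

  flat <- contrast_curve(t, rep(0, length(t)), n_baseline = 3)
  f0 <- fit_tofts(flat)
  expect_true(f0$converged)
  expect_lt(f0$Ktrans, 1e-6)
  expect_lt(f0$fit_rss, 1e-12)
})

test_that("onset and AUC semi-quantification", {
  # zero curve: no onset, zero AUCs
  t <- 0:200
  sq0 <- semi_quant(contrast_curve(t, rep(0, length(t)), n_baseline = 5))
  expect_false(sq0$onset_detected)
  expect_equal(sq0$AUC90, 0); expect_equal(sq0$AUC120, 0)

  # step 0 -> 1 at t = 30 s with 1 s sampling
  c_step <- as.numeric(t >= 30)
  sq <- semi_quant(contrast_curve(t, c_step, n_baseline = 5))
  expect_lte(abs(sq$t_onset - 30), 1)
  expect_lt(abs(sq$AUC90 - 90), 1.5)
  expect_lt(abs(sq$AUC120 - 120), 1.5)

  # AUC120 >= AUC90 for nonnegative baseline-subtracted curves
  set.seed(3)
  for (i in 1:10) {
    cc <- cumsum(runif(241) / 10)
    sqi <- semi_quant(contrast_curve(0:240, cc, n_baseline = 3))
    expect_gte(sqi$AUC120, sqi$AUC90)
  }
})

test_that("ROI curves are voxel means per frame", {
  d <- c(4L, 4L, 2L); nt <- 31L
  arr <- array(0, c(d, nt))
  t <- seq(0, 150, 5)
  a <- sin(t / 20) + 2; b <- cos(t / 30) + 2
  arr[1, 1, 1, ] <- a; arr[2, 1, 1, ] <- b
  dce <- image_volume(arr, c(1, 1, 1), t_s = t)
  roi <- array(FALSE, d); roi[1:2, 1, 1] <- TRUE
  cur <- roi_curve(dce, roi)
  expect_equal(cur$c, (a + b) / 2)

  const <- image_volume(array(rep(t, each = prod(d)), c(d, nt)),
                        c(1, 1, 1), t_s = t)
  roi_all <- array(TRUE, d)
  expect_equal(roi_curve(const, roi_all)$c, t)

  expect_error(roi_curve(dce, array(FALSE, d)), "empty")
})

test_that("ROI mean of homogeneous tissue equals the single-voxel curve", {
  spec <- small_phantom(noise_sd = list(adc = 0, dce = 0), seed = 2)
  ph <- generate_phantom(spec)
  cur <- roi_curve(ph$dce, ph$masks$gtv, n_baseline = ph$truth$n_baseline)
  expect_equal(cur$c, unname(ph$truth$curves$gtv), tolerance = 1e-12)
})
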