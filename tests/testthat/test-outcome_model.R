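# small deterministic feature table for comparison-building tests
make_table <- function(n = 8, scans = c("S1", "S2", "S3", "S4"), seed = 1) {
  set.seed(seed)
  ids <- sprintf("P%02d", seq_len(n))
  do.call(rbind, lapply(seq_along(scans), function(s)
    data.frame(patient_id = ids, scan_point = scans[s],
               f1 = rnorm(n, 10 * s), f2 = runif(n),
               stringsAsFactors = FALSE)))
}

test_that("ten comparisons are built with presence rules and delta naming", {
  tab <- make_table()
  y <- setNames(rep(c(0, 1), 4), sprintf("P%02d", 1:8))
  cmp <- build_comparisons(tab, y)
  expect_length(cmp, 10)
  expect_setequal(names(cmp), c("S1", "S2", "S3", "S4", "S2-S1", "S3-S1",
                                "S4-S1", "S3-S2", "S4-S2", "S4-S3"))
  expect_true(all(c("f1_S2-S1", "f2_S2-S1") %in% names(cmp[["S2-S1"]]$X)))
  # 6 difference matrices = C(4,2)
  expect_equal(sum(grepl("-", names(cmp))), 6)

  # patient missing S4 appears in S1-S3 comparisons and their deltas only
  tab2 <- tab[!(tab$patient_id == "P03" & tab$scan_point == "S4"), ]
  cmp2 <- build_comparisons(tab2, y)
  expect_false("P03" %in% cmp2[["S4"]]$patient_id)
  expect_false("P03" %in% cmp2[["S4-S1"]]$patient_id)
  expect_true("P03" %in% cmp2[["S3-S1"]]$patient_id)
  expect_equal(length(cmp2[["S4-S2"]]$y), 7)

  # a labeled patient with no scans is excluded and reported
  y3 <- c(y, P99 = 1)
  cmp3 <- build_comparisons(tab, y3)
  expect_equal(attr(cmp3, "excluded"), "P99")
})

test_that("delta features equal the generator's scan shift on a zero-noise cohort", {
  spec <- small_phantom(noise_sd = list(adc = 0, dce = 0.0), seed = 31)
  co <- generate_cohort(cohort_spec(n_patients = 6, seed = 31), spec)
  # analysis grid equal to the phantom grid so values pass through exactly
  cfg <- default_config(grid = list(in_plane_mm = 2, slice_mm = 3))
  tab <- cohort_feature_table(co, cfg, scans = c("S1", "S2"))
  cmp <- build_comparisons(tab, co$labels)
  d <- cmp[["S2-S1"]]$X[["GTV_ADC_Mean_S2-S1"]]
  truth_d <- sapply(co$params, function(p) p$S2$gtv$adc_mean - p$S1$gtv$adc_mean)
  expect_equal(d, unname(truth_d), tolerance = 1e-9)
})

test_that("univariate logistic screen ranks signal and nulls correctly", {
  set.seed(5)
  n <- 60
  y <- rep(c(0, 1), each = n / 2)
  X <- data.frame(null_f = rnorm(n),
                  same = rep(1.5, n) + rnorm(n, sd = 1e-9),
                  signal = y + rnorm(n, sd = 0.1))
  scr <- univariate_screen(X, y)
  expect_gt(scr$p[scr$feature == "null_f"], 0.05)
  expect_lt(scr$p[scr$feature == "signal"], 1e-6)
  expect_true(scr$separation[scr$feature == "signal"])

  # grouped binary feature: LRT matches the closed-form deviance test
  x <- rep(c(0, 1), times = c(30, 30))
  y2 <- c(rep(0, 22), rep(1, 8), rep(0, 10), rep(1, 20))
  scr2 <- univariate_screen(data.frame(x = x), y2)
  # deviance of a 2x2 table: 2 * sum O log(O/E) over the saturated-vs-null split
  ll <- function(k, n) ifelse(k == 0 | k == n, 0,
                              k * log(k / n) + (n - k) * log(1 - k / n))
  dev_null <- -2 * ll(28, 60)
  dev_fit <- -2 * (ll(8, 30) + ll(20, 30))
  p_ref <- pchisq(dev_null - dev_fit, df = 1, lower.tail = FALSE)
  expect_equal(scr2$p, p_ref, tolerance = 1e-8)
})

test_that("greedy decorrelated selection follows the hand-traced rule", {
  # A strongest, B correlated with A, C weak but independent
  set.seed(13)
  n <- 40
  y <- rep(c(0, 1), each = n / 2)
  A <- y * 2 + rnorm(n, sd = 0.6)
  B <- A + rnorm(n, sd = 0.25)           # r(A, B) > 0.85
  C <- y * 0.9 + rnorm(n, sd = 0.9)      # weaker, r(A, C) < 0.85
  stopifnot(cor(A, B) > 0.85, abs(cor(A, C)) < 0.85)
  X <- data.frame(A = A, B = B, C = C)
  sel <- select_features(X, y, max_k = 4)
  expect_equal(as.character(sel), c("A", "C"))

  # two perfect copies: exactly one survives
  X2 <- data.frame(A = A, A2 = A)
  sel2 <- select_features(X2, y)
  expect_length(sel2, 1)

  # max_k caps the selection size
  X3 <- data.frame(A = A, C = C,
                   D = y * 1.5 + rnorm(n, 0, 0.8),
                   E = y * 1.2 + rnorm(n, 0, 0.8),
                   F = y * 1.1 + rnorm(n, 0, 0.8))
  expect_lte(length(select_features(X3, y, max_k = 4)), 4)
  expect_lte(length(select_features(X3, y, max_k = 2)), 2)

  # nothing passing the screen yields an empty selection
  Xnull <- data.frame(a = rnorm(n), b = rnorm(n))
  expect_length(select_features(Xnull, y, p_pass = 1e-6), 0)

  # selected features always satisfy the pairwise correlation bound
  set.seed(19)
  for (i in 1:10) {
    Xr <- as.data.frame(matrix(rnorm(n * 8), n))
    Xr$sig <- y + rnorm(n, sd = 0.5)
    sr <- select_features(Xr, y, p_pass = 0.5, max_k = 0)
    if (length(sr) > 1) {
      cm <- abs(cor(Xr[, as.character(sr)]))
      expect_lte(max(cm[upper.tri(cm)]), 0.85)
    }
  }
})

test_that("confusion matrix and F1 arithmetic", {
  y <- c(1, 1, 1, 1, 0, 0, 0, 0, 0, 0)
  probs <- c(1, 1, 1, 1, 1, 1, 0, 0, 0, 0)   # TP=4, FP=2, FN=0
  cf <- confusion_and_f1(probs, y)
  expect_equal(cf$f1, 0.80)
  expect_equal(sum(cf$confusion), length(y))
  expect_equal(f1_score(tp = 4, fp = 3, fn = 0), 8 / 11)  # 0.727...
  expect_equal(round(f1_score(4, 3, 0), 3), 0.727)
  # probs equal to labels give a perfect F1
  expect_equal(confusion_and_f1(y, y)$f1, 1)
  # no positives: undefined
  expect_true(is.na(confusion_and_f1(rep(0, 4), rep(0, 4))$f1))
})

test_that("leave-one-out evaluation: separable, null, and permutation behavior", {
  set.seed(23)
  n <- 40
  y <- rep(c(0, 1), each = n / 2)
  X <- data.frame(good = y * 6 + rnorm(n, sd = 0.4), junk = rnorm(n))
  m <- fit_and_evaluate_loo(X, y, features = "good")
  expect_equal(m$auc, 1)
  expect_equal(m$f1, 1)
  expect_equal(sum(m$confusion), n)

  # label-independent features: AUC near chance (leave-one-out probabilities
  # of null models are slightly pessimistic, so the band is one-sided wide)
  set.seed(29)
  aucs <- replicate(15, {
    yb <- rep(c(0, 1), each = 60)
    Xb <- data.frame(a = rnorm(120), b = rnorm(120))
    fit_and_evaluate_loo(Xb, yb, features = c("a", "b"))$auc
  })
  expect_gt(mean(aucs), 0.38)
  expect_lt(mean(aucs), 0.58)

  # permuting labels destroys an informative model (AUC falls from 1 to
  # chance; at n = 40 the LOO pessimism shifts the null centre below 0.5)
  set.seed(31)
  perm_aucs <- replicate(20, {
    yp <- sample(y)
    fit_and_evaluate_loo(X, yp, features = "good")$auc
  })
  expect_gt(mean(perm_aucs), 0.2)
  expect_lt(mean(perm_aucs), 0.65)

  # AUC is invariant under strictly monotone transforms of the probabilities
  r1 <- pROC::roc(y, m$heldout_probs, levels = c(0, 1), direction = "<",
                  quiet = TRUE)
  r2 <- pROC::roc(y, plogis(qlogis(pmin(pmax(m$heldout_probs, 1e-9),
                                        1 - 1e-9)) / 3),
                  levels = c(0, 1), direction = "<", quiet = TRUE)
  expect_equal(as.numeric(pROC::auc(r1)), as.numeric(pROC::auc(r2)))

  # rank-based (Mann-Whitney) oracle agrees with the reported AUC
  mw <- mean(outer(m$heldout_probs[y == 1], m$heldout_probs[y == 0], ">")) +
    0.5 * mean(outer(m$heldout_probs[y == 1], m$heldout_probs[y == 0], "=="))
  expect_equal(m$auc, mw)
})

test_that("a fold losing one class falls back to the prior rate with a warning", {
  y <- c(1, rep(0, 7))
  X <- data.frame(x = rnorm(8))
  m <- fit_and_evaluate_loo(X, y, features = "x")
  expect_true(any(grepl("lost a class", m$warnings)))
  expect_equal(m$heldout_probs[1], 0)   # prior rate of all-negative training set
})
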