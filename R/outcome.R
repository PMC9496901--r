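#' Build the ten scan-point and delta-feature comparisons
#'
#' One design matrix per scan point (S1..S4) and one per pairwise difference
#' (S2-S1, S3-S1, S4-S1, S3-S2, S4-S2, S4-S3). Delta features are named by
#' appending \code{"_<later>-<earlier>"} to the feature name. Difference
#' matrices only include patients present at both scans; patients with a
#' label but no scans are excluded (attribute \code{excluded}).
#'
#' @param table wide feature table with \code{patient_id}, \code{scan_point}
#'   and feature columns.
#' @param labels named binary vector (names = patient ids) or data.frame
#'   with columns \code{patient_id}, \code{label}.
#' @return named list of 10 comparisons, each \code{list(name, X, y,
#'   patient_id)}.
#' @export
build_comparisons <- function(table, labels) {
  if (is.data.frame(labels)) {
    y_all <- stats::setNames(labels$label, labels$patient_id)
  } else y_all <- labels
  if (!all(y_all %in% c(0, 1))) stop("labels must be binary 0/1")
  feats <- setdiff(names(table), c("patient_id", "scan_point"))
  per_scan <- lapply(scan_levels(), function(s) {
    sub <- table[table$scan_point == s & table$patient_id %in% names(y_all), ]
    sub[match(unique(sub$patient_id), sub$patient_id), , drop = FALSE]
  })
  names(per_scan) <- scan_levels()
  excluded <- setdiff(names(y_all), unique(table$patient_id))
  out <- list()
  for (s in scan_levels()) {
    sub <- per_scan[[s]]
    if (nrow(sub) == 0L) next
    out[[s]] <- list(name = s,
                     X = sub[, feats, drop = FALSE],
                     y = unname(y_all[sub$patient_id]),
                     patient_id = sub$patient_id)
  }
  combs <- utils::combn(scan_levels(), 2)
  for (k in seq_len(ncol(combs))) {
    s_a <- combs[1, k]; s_b <- combs[2, k]          # earlier, later
    nm <- paste0(s_b, "-", s_a)
    a <- per_scan[[s_a]]; b <- per_scan[[s_b]]
    ids <- intersect(a$patient_id, b$patient_id)
    if (length(ids) == 0L) next
    Xd <- b[match(ids, b$patient_id), feats, drop = FALSE] -
          a[match(ids, a$patient_id), feats, drop = FALSE]
    names(Xd) <- paste0(feats, "_", nm)
    out[[nm]] <- list(name = nm, X = Xd, y = unname(y_all[ids]),
                      patient_id = ids)
  }
  attr(out, "excluded") <- excluded
  out
}

# drop constant / all-missing columns, impute remaining NAs by column median
clean_design <- function(X) {
  keep <- vapply(X, function(v) {
    v <- v[is.finite(v)]
    length(v) >= 2 && stats::sd(v) > 0
  }, TRUE)
  X <- X[, keep, drop = FALSE]
  for (j in seq_along(X)) {
    v <- X[[j]]
    v[!is.finite(v)] <- stats::median(v[is.finite(v)])
    X[[j]] <- v
  }
  X
}

#' Univariate logistic screen
#'
#' For each feature, the likelihood-ratio p-value of a one-feature logistic
#' model against the intercept-only model. Complete separation is detected
#' (fitted probabilities pinned at 0/1) and flagged; the LRT p-value is still
#' reported from the capped fit.
#'
#' @param X data.frame of features.
#' @param y binary outcome vector.
#' @return data.frame with \code{feature}, \code{p}, \code{separation}.
#' @export
univariate_screen <- function(X, y) {
  stopifnot(length(unique(y)) == 2L)
  null_dev <- stats::glm(y ~ 1, family = stats::binomial())$deviance
  res <- lapply(names(X), function(f) {
    x <- X[[f]]
    ok <- is.finite(x)
    if (sum(ok) < 3L || stats::sd(x[ok]) == 0)
      return(data.frame(feature = f, p = 1, separation = FALSE))
    sep <- FALSE
    fit <- withCallingHandlers(
      stats::glm(y[ok] ~ x[ok], family = stats::binomial(),
                 control = stats::glm.control(maxit = 50)),
      warning = function(w) {
        if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
          sep <<- TRUE
        invokeRestart("muffleWarning")
      })
    nd <- if (all(ok)) null_dev
          else stats::glm(y[ok] ~ 1, family = stats::binomial())$deviance
    p <- stats::pchisq(nd - fit$deviance, df = 1, lower.tail = FALSE)
    data.frame(feature = f, p = p, separation = sep)
  })
  do.call(rbind, res)
}

# Welch t-test p-value of each feature between the two outcome groups
welch_rank_p <- function(X, y) {
  vapply(names(X), function(f) {
    cmp <- compare_groups(X[[f]][y == 1], X[[f]][y == 0], welch = TRUE)
    if (is.na(cmp$p)) 1 else cmp$p
  }, 0)
}

#' Screened, decorrelated feature selection
#'
#' Features passing the univariate logistic screen (LRT p < \code{p_pass})
#' are ranked by ascending Welch t-test p-value between the outcome groups;
#' the greedy loop repeatedly takes the best-ranked remaining feature and
#' drops every remaining feature whose absolute Pearson correlation with it
#' exceeds \code{r_max}. Ties in p are broken lexicographically by name.
#'
#' @param X data.frame of features.
#' @param y binary outcome.
#' @param p_pass screen threshold (default 0.05).
#' @param r_max correlation cutoff (default 0.85).
#' @param max_k maximum number of selected features (default 4; 0 =
#'   unlimited).
#' @return character vector of selected feature names (possibly empty),
#'   with the screen table as attribute \code{screen}.
#' @export
select_features <- function(X, y, p_pass = 0.05, r_max = 0.85, max_k = 4L) {
  X <- clean_design(X)
  if (ncol(X) == 0L) return(character(0))
  screen <- univariate_screen(X, y)
  cand <- screen$feature[screen$p < p_pass]
  if (length(cand) == 0L) {
    out <- character(0)
    attr(out, "screen") <- screen
    return(out)
  }
  wp <- welch_rank_p(X[, cand, drop = FALSE], y)
  ord <- order(wp, names(wp))
  remaining <- names(wp)[ord]
  selected <- character(0)
  while (length(remaining) > 0L && (max_k == 0L || length(selected) < max_k)) {
    pick <- remaining[1]
    selected <- c(selected, pick)
    remaining <- remaining[-1]
    if (length(remaining)) {
      r <- abs(stats::cor(X[[pick]], X[, remaining, drop = FALSE]))
      remaining <- remaining[!(r > r_max) | is.na(r)]
    }
  }
  attr(selected, "screen") <- screen
  selected
}

#' Confusion matrix and F1 score at a probability threshold
#'
#' F1 = 2TP / (2TP + FP + FN). With no positive labels the F1 is undefined
#' and returned as \code{NA}.
#'
#' @param heldout_probs predicted probabilities in [0, 1].
#' @param y binary labels.
#' @param threshold classification threshold (default 0.5).
#' @return list with \code{confusion} (2x2 matrix) and \code{f1}.
#' @export
confusion_and_f1 <- function(heldout_probs, y, threshold = 0.5) {
  stopifnot(all(heldout_probs >= 0 & heldout_probs <= 1))
  pred <- as.integer(heldout_probs >= threshold)
  tp <- sum(pred == 1 & y == 1); fp <- sum(pred == 1 & y == 0)
  fn <- sum(pred == 0 & y == 1); tn <- sum(pred == 0 & y == 0)
  conf <- matrix(c(tn, fp, fn, tp), 2, 2,
                 dimnames = list(predicted = c("0", "1"),
                                 actual = c("0", "1")))
  list(confusion = conf, f1 = f1_score(tp, fp, fn))
}

#' F1 score from confusion-matrix counts
#'
#' @param tp,fp,fn true-positive, false-positive, false-negative counts.
#' @return 2TP / (2TP + FP + FN), or \code{NA} when there are no actual
#'   positives.
#' @export
f1_score <- function(tp, fp, fn) {
  if (tp + fn == 0) return(NA_real_)
  2 * tp / (2 * tp + fp + fn)
}

#' Multivariate logistic model with leave-one-out evaluation
#'
#' Fits an unpenalized multivariate logistic regression on the selected
#' features and evaluates it by leave-one-out: each patient's probability is
#' predicted from a model refit on the remaining patients. In the default
#' flat mode the feature selection is done once on the full cohort and only
#' the coefficients are re-estimated per fold (optimistically biased);
#' \code{nested = TRUE} redoes the selection inside every fold. ROC and AUC
#' are computed over the held-out probabilities.
#'
#' @param X data.frame of features.
#' @param y binary outcome.
#' @param features pre-selected feature names; selected from the full data
#'   when \code{NULL}.
#' @param threshold classification threshold for the confusion matrix.
#' @param nested redo feature selection within each fold.
#' @param p_pass,r_max,max_k selection parameters (see
#'   \code{\link{select_features}}).
#' @return an object of class \code{model_result}: \code{selected_features},
#'   \code{coefficients}, \code{heldout_probs}, \code{roc}, \code{auc},
#'   \code{confusion}, \code{f1}, \code{n}, \code{warnings}.
#' @export
fit_and_evaluate_loo <- function(X, y, features = NULL, threshold = 0.5,
                                 nested = FALSE, p_pass = 0.05,
                                 r_max = 0.85, max_k = 4L) {
  stopifnot(length(unique(y)) == 2L)
  X <- clean_design(X)
  if (is.null(features))
    features <- select_features(X, y, p_pass = p_pass, r_max = r_max,
                                max_k = max_k)
  features <- intersect(features, names(X))
  if (!nested && length(features) == 0L)
    stop("no features passed the screen; model skipped")
  n <- length(y)
  probs <- numeric(n)
  warns <- character(0)
  fit_glm <- function(Xs, ys) {
    df <- cbind(data.frame(.y = ys), Xs)
    suppressWarnings(stats::glm(.y ~ ., data = df, family = stats::binomial(),
                                control = stats::glm.control(maxit = 100)))
  }
  for (i in seq_len(n)) {
    ytr <- y[-i]
    if (length(unique(ytr)) < 2L) {
      probs[i] <- mean(ytr)
      warns <- c(warns, sprintf("fold %d lost a class; prior rate used", i))
      next
    }
    feats_i <- if (nested) {
      fi <- select_features(X[-i, , drop = FALSE], ytr, p_pass = p_pass,
                            r_max = r_max, max_k = max_k)
      as.character(fi)
    } else features
    if (length(feats_i) == 0L) {
      probs[i] <- mean(ytr)
      warns <- c(warns, sprintf("fold %d selected no features; prior rate used", i))
      next
    }
    m <- fit_glm(X[-i, feats_i, drop = FALSE], ytr)
    probs[i] <- suppressWarnings(
      stats::predict(m, newdata = X[i, feats_i, drop = FALSE],
                     type = "response"))
  }
  probs <- pmin(pmax(probs, 0), 1)
  r <- pROC::roc(response = y, predictor = probs, levels = c(0, 1),
                 direction = "<", quiet = TRUE)
  cf <- confusion_and_f1(probs, y, threshold)
  full <- if (length(features)) fit_glm(X[, features, drop = FALSE], y) else NULL
  structure(list(selected_features = features,
                 coefficients = if (!is.null(full)) stats::coef(full) else NULL,
                 heldout_probs = probs,
                 roc = data.frame(threshold = r$thresholds,
                                  tpr = r$sensitivities,
                                  fpr = 1 - r$specificities),
                 auc = as.numeric(pROC::auc(r)),
                 confusion = cf$confusion, f1 = cf$f1,
                 n = n, nested = nested, warnings = warns),
            class = "model_result")
}

#' @export
print.model_result <- function(x, ...) {
  cat(sprintf("<model_result> n=%d, %s LOO, AUC=%.3f, F1=%s\n",
              x$n, if (x$nested) "nested" else "flat", x$auc,
              ifelse(is.na(x$f1), "NA", sprintf("%.3f", x$f1))))
  cat("features:", if (length(x$selected_features))
    paste(x$selected_features, collapse = ", ") else "(none)", "\n")
  invisible(x)
}
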