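#' Percent change between two values
#'
#' \code{100 * (v_new - v_ref) / v_ref}, sign retained (a decrease comes out
#' negative). Undefined for a zero reference and emitted as \code{NA}.
#'
#' @param v_ref reference (earlier) value.
#' @param v_new new (later) value.
#' @return percent change (vectorized).
#' @export
percent_change <- function(v_ref, v_new) {
  out <- 100 * (v_new - v_ref) / v_ref
  out[!is.finite(v_ref) | v_ref == 0 | !is.finite(v_new)] <- NA_real_
  out
}

#' Two-sample comparison of a feature between groups or scan points
#'
#' Two-tailed t-test, pooled-variance Student by default with the Welch
#' variant selectable; optionally paired, in which case samples are aligned
#' by id with listwise deletion of incomplete pairs. Degenerate inputs yield
#' a missing result with a reason instead of an error.
#'
#' @param a,b numeric samples.
#' @param paired logical; align by \code{ids_a}/\code{ids_b} when TRUE.
#' @param welch use the Welch (unequal-variance) statistic.
#' @param ids_a,ids_b ids for paired alignment.
#' @param conf_level confidence level for the mean-difference CI.
#' @return list with \code{t}, \code{p}, \code{df}, \code{mean_a},
#'   \code{mean_b}, \code{ci}, \code{n_a}, \code{n_b}, \code{reason}.
#' @export
compare_groups <- function(a, b, paired = FALSE, welch = FALSE,
                           ids_a = NULL, ids_b = NULL, conf_level = 0.95) {
  miss <- function(reason, n_a = NA_integer_, n_b = NA_integer_)
    list(t = NA_real_, p = NA_real_, df = NA_real_,
         mean_a = NA_real_, mean_b = NA_real_, ci = c(NA_real_, NA_real_),
         n_a = n_a, n_b = n_b, reason = reason)
  if (paired) {
    if (!is.null(ids_a) && !is.null(ids_b)) {
      common <- intersect(ids_a[!is.na(a)], ids_b[!is.na(b)])
      a <- a[match(common, ids_a)]
      b <- b[match(common, ids_b)]
    }
    keep <- is.finite(a) & is.finite(b)
    a <- a[keep]; b <- b[keep]
  } else {
    a <- a[is.finite(a)]; b <- b[is.finite(b)]
  }
  if (length(a) < 2L || length(b) < 2L)
    return(miss("fewer than 2 observations per group after deletion",
                length(a), length(b)))
  ht <- tryCatch(
    stats::t.test(a, b, paired = paired, var.equal = !welch,
                  conf.level = conf_level),
    error = function(e) NULL)
  if (is.null(ht)) {
    if (isTRUE(all.equal(c(a - b), rep(0, length(a)))) ||
        (stats::var(a) == 0 && stats::var(b) == 0 && mean(a) == mean(b)))
      return(utils::modifyList(miss("constant data", length(a), length(b)),
                               list(t = 0, p = 1,
                                    mean_a = mean(a), mean_b = mean(b))))
    return(miss("t-test failed (essentially constant data)", length(a), length(b)))
  }
  list(t = unname(ht$statistic), p = ht$p.value, df = unname(ht$parameter),
       mean_a = mean(a), mean_b = mean(b), ci = unname(ht$conf.int),
       n_a = length(a), n_b = length(b), reason = NA_character_)
}

scan_levels <- function() c("S1", "S2", "S3", "S4")

#' Longitudinal report over a feature table
#'
#' For every feature: per-scan n, mean and SD; percent change of the mean
#' versus baseline (S1) and versus the previous scan; and two-sample
#' scan-point tests versus baseline and versus the previous scan. Missing
#' scans simply reduce the per-scan n.
#'
#' @param table wide feature table: columns \code{patient_id},
#'   \code{scan_point} (S1..S4), then one column per feature.
#' @param welch,paired passed to \code{\link{compare_groups}}.
#' @param p_adjust optional multiple-testing correction applied per column
#'   of p-values (\code{"none"} by default; \code{"BH"} available).
#' @return data.frame with one row per feature x scan point.
#' @export
longitudinal_report <- function(table, welch = FALSE, paired = FALSE,
                                p_adjust = c("none", "BH")) {
  p_adjust <- match.arg(p_adjust)
  stopifnot(all(c("patient_id", "scan_point") %in% names(table)))
  if (!all(table$scan_point %in% scan_levels()))
    stop("scan_point must be one of S1..S4")
  scans <- intersect(scan_levels(), unique(table$scan_point))
  if (length(scans) < 2L) stop("need at least 2 scan points")
  feats <- setdiff(names(table), c("patient_id", "scan_point"))
  rows <- list()
  for (f in feats) {
    per <- lapply(scans, function(s) {
      sub <- table[table$scan_point == s, ]
      list(v = sub[[f]], ids = sub$patient_id)
    })
    names(per) <- scans
    base <- per[[scans[1]]]
    for (j in seq_along(scans)) {
      cur <- per[[scans[j]]]
      v <- cur$v[is.finite(cur$v)]
      prev <- if (j > 1) per[[scans[j - 1]]] else NULL
      cmp_b <- if (j > 1) compare_groups(base$v, cur$v, paired = paired,
                                         welch = welch, ids_a = base$ids,
                                         ids_b = cur$ids) else NULL
      cmp_p <- if (j > 1) compare_groups(prev$v, cur$v, paired = paired,
                                         welch = welch, ids_a = prev$ids,
                                         ids_b = cur$ids) else NULL
      m_base <- mean(base$v, na.rm = TRUE)
      m_prev <- if (j > 1) mean(prev$v, na.rm = TRUE) else NA_real_
      m <- if (length(v)) mean(v) else NA_real_
      rows[[length(rows) + 1L]] <- data.frame(
        feature = f, scan_point = scans[j], n = length(v),
        mean = m, sd = if (length(v) > 1) stats::sd(v) else NA_real_,
        pct_change_vs_baseline = if (j > 1) percent_change(m_base, m) else 0,
        pct_change_vs_prev = if (j > 1) percent_change(m_prev, m) else NA_real_,
        p_vs_baseline = if (j > 1) cmp_b$p else NA_real_,
        p_vs_prev = if (j > 1) cmp_p$p else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  if (p_adjust == "BH") {
    out$p_vs_baseline <- stats::p.adjust(out$p_vs_baseline, "BH")
    out$p_vs_prev <- stats::p.adjust(out$p_vs_prev, "BH")
  }
  out
}

#' Cross-ROI baseline comparison of one feature
#'
#' Compares a feature (e.g. \code{_ADC_Mean}) between the GTV, NAT-PZ and
#' NAT-TZ regions at one scan point, all three pairwise tests.
#'
#' @param table wide feature table (see \code{\link{longitudinal_report}}).
#' @param feature feature suffix, e.g. \code{"ADC_Mean"}.
#' @param scan scan point (default \code{"S1"}).
#' @param rois ROI name prefixes to compare.
#' @param welch use the Welch statistic.
#' @return data.frame of pairwise tests (roi_a, roi_b, t, p, means).
#' @export
compare_rois_at_scan <- function(table, feature, scan = "S1",
                                 rois = c("GTV", "NAT-PZ", "NAT-TZ"),
                                 welch = FALSE) {
  sub <- table[table$scan_point == scan, ]
  cols <- paste0(rois, "_", feature)
  missing_cols <- setdiff(cols, names(table))
  if (length(missing_cols)) stop("unknown feature columns: ",
                                 paste(missing_cols, collapse = ", "))
  pairs <- utils::combn(seq_along(rois), 2)
  out <- list()
  for (k in seq_len(ncol(pairs))) {
    i <- pairs[1, k]; j <- pairs[2, k]
    cmp <- compare_groups(sub[[cols[i]]], sub[[cols[j]]], welch = welch)
    out[[k]] <- data.frame(roi_a = rois[i], roi_b = rois[j],
                           mean_a = cmp$mean_a, mean_b = cmp$mean_b,
                           t = cmp$t, p = cmp$p, stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}
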