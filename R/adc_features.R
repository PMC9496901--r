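#' First-order statistics of a sample of ADC values
#'
#' Eleven first-order histogram statistics: the 10/25/50/75/90th percentiles
#' (linear interpolation between closest ranks), mean, standard deviation,
#' skewness, excess kurtosis (normal = 0), minimum, and maximum. Skewness and
#' kurtosis of a constant sample are undefined and emitted as \code{NA}.
#'
#' @param values numeric vector of voxel values (e.g. ADC in 1e-6 mm^2/s).
#' @param min_voxels minimum sample size; below it the whole fragment is
#'   returned as \code{NA} (missing, not an error).
#' @param include_min,include_max toggles for the min/max statistics.
#' @return named numeric vector with names \code{10, 25, 50, 75, 90, Mean,
#'   SD, Skew, Kurt, Min, Max}.
#' @export
first_order_stats <- function(values, min_voxels = 10L,
                              include_min = TRUE, include_max = TRUE) {
  nms <- c("10", "25", "50", "75", "90", "Mean", "SD", "Skew", "Kurt",
           if (include_min) "Min", if (include_max) "Max")
  values <- values[is.finite(values)]
  if (length(values) < min_voxels) {
    out <- rep(NA_real_, length(nms)); names(out) <- nms
    attr(out, "missing_reason") <- sprintf("only %d voxels (min %d)",
                                           length(values), min_voxels)
    return(out)
  }
  q <- stats::quantile(values, probs = c(.10, .25, .50, .75, .90),
                       names = FALSE, type = 7)
  s <- stats::sd(values)
  if (s > 0) {
    sk <- e1071::skewness(values)
    ku <- e1071::kurtosis(values)
  } else {
    sk <- NA_real_; ku <- NA_real_
  }
  out <- c(q, mean(values), s, sk, ku,
           if (include_min) min(values), if (include_max) max(values))
  out[is.nan(out)] <- NA_real_
  names(out) <- nms
  out
}

# canonical ROI labels used in feature names, in pipeline order
roi_labels <- function() c(GTV = "gtv", `PT-PZ` = "pt_pz", `PT-TZ` = "pt_tz",
                           `NAT-PZ` = "nat_pz", `NAT-TZ` = "nat_tz")

#' Extract first-order ADC features for every analysis ROI
#'
#' Feature names follow the ROI_Sequence_Feature convention, e.g.
#' \code{GTV_ADC_90} or \code{NAT-TZ_ADC_SD}.
#'
#' @param adc an \code{image_volume} or 3-D array of ADC values.
#' @param rois a \code{roi_set} on the same grid.
#' @param min_voxels per-ROI minimum voxel count (default 10).
#' @param ... passed to \code{\link{first_order_stats}}.
#' @return named numeric vector (one fragment per ROI, concatenated).
#' @export
extract_adc_features <- function(adc, rois, min_voxels = 10L, ...) {
  arr <- vol_data(adc)
  if (!identical(dim(arr), dim(rois$gtv)))
    stop("ADC volume and ROI masks are not on the same grid")
  labs <- roi_labels()
  out <- numeric(0)
  for (i in seq_along(labs)) {
    frag <- first_order_stats(arr[rois[[labs[i]]]], min_voxels = min_voxels, ...)
    names(frag) <- paste0(names(labs)[i], "_ADC_", names(frag))
    out <- c(out, frag)
  }
  out
}
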