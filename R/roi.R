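#' @title ROI geometry: tumor, peritumoral ring, and normally-appearing tissue
#' @description
#' The five analysis regions are derived from three input masks (prostate,
#' peripheral zone PZ, gross tumor volume GTV) on a common grid:
#' the transition zone TZ is the prostate minus the PZ; a peritumoral ring of
#' fixed physical thickness is grown around the (merged) GTV; the ring is
#' split by zone into PT-PZ and PT-TZ; and the normally-appearing tissue
#' NAT-PZ / NAT-TZ is whatever remains of each zone outside tumor and ring.
#' @name roi_geometry
NULL

check_same_grid <- function(...) {
  masks <- list(...)
  d <- dim(masks[[1]])
  for (m in masks[-1])
    if (!identical(dim(m), d)) stop("masks are not on a common grid")
  invisible(TRUE)
}

#' Derive the transition zone
#'
#' TZ = prostate AND NOT PZ. A small fraction of PZ voxels may fall outside
#' the prostate after resampling; up to \code{tol_frac} of them are clipped
#' silently, more is an error.
#'
#' @param prostate,pz logical masks on one grid.
#' @param tol_frac tolerated fraction of PZ voxels outside the prostate
#'   (default 0.01).
#' @return logical TZ mask.
#' @export
derive_tz <- function(prostate, pz, tol_frac = 0.01) {
  check_same_grid(prostate, pz)
  outside <- sum(pz & !prostate)
  if (sum(pz) > 0 && outside > tol_frac * sum(pz))
    stop(sprintf("PZ is not inside the prostate: %d voxels outside (tolerance %.3g%%)",
                 outside, 100 * tol_frac))
  prostate & !pz
}

#' Peritumoral ring of fixed physical thickness
#'
#' Returns every voxel outside the GTV whose centre lies within
#' \code{thickness_mm} (Euclidean distance in millimetres, honouring
#' anisotropic spacing) of some GTV voxel centre. The dilation is 3-D.
#'
#' @param gtv logical GTV mask (non-empty).
#' @param spacing_mm per-axis voxel spacing in mm.
#' @param thickness_mm ring thickness in mm (default 5).
#' @return logical ring mask (disjoint from \code{gtv}).
#' @export
peritumoral_ring <- function(gtv, spacing_mm, thickness_mm = 5.0) {
  if (!any(gtv)) stop("empty GTV mask: cannot build a peritumoral ring")
  spacing_mm <- as.numeric(spacing_mm)
  stopifnot(length(spacing_mm) == 3L, all(spacing_mm > 0))
  d <- dim(gtv)
  if (thickness_mm <= 0) return(array(FALSE, d))
  r <- floor(thickness_mm / spacing_mm)
  off <- as.matrix(expand.grid(dx = -r[1]:r[1], dy = -r[2]:r[2], dz = -r[3]:r[3]))
  dist <- sqrt((off[, 1] * spacing_mm[1])^2 +
               (off[, 2] * spacing_mm[2])^2 +
               (off[, 3] * spacing_mm[3])^2)
  off <- off[dist <= thickness_mm + 1e-9, , drop = FALSE]
  cc <- which(gtv, arr.ind = TRUE)
  out <- array(FALSE, d)
  for (k in seq_len(nrow(off))) {
    x <- cc[, 1] + off[k, 1]; y <- cc[, 2] + off[k, 2]; z <- cc[, 3] + off[k, 3]
    keep <- x >= 1L & x <= d[1] & y >= 1L & y <= d[2] & z >= 1L & z <= d[3]
    if (any(keep)) out[cbind(x[keep], y[keep], z[keep])] <- TRUE
  }
  out & !gtv
}

#' Merge multifocal lesions into one tumor mask
#'
#' Voxelwise union, so a ring grown from the result never double-counts
#' overlapping per-lesion rings.
#'
#' @param gtvs list of logical masks on one grid (length >= 1).
#' @return logical union mask.
#' @export
merge_multifocal <- function(gtvs) {
  stopifnot(length(gtvs) >= 1L)
  do.call(check_same_grid, gtvs)
  Reduce(`|`, gtvs)
}

#' Split the ring by zone and derive normally-appearing tissue
#'
#' PT-PZ / PT-TZ are the intersections of the ring with each zone; NAT-PZ /
#' NAT-TZ are the zone voxels outside both tumor and ring. The ring is
#' clipped to the prostate, so all five regions lie inside it.
#'
#' @param ring,gtv,pz,tz,prostate logical masks on one grid.
#' @param spacing_mm per-axis spacing recorded on the result.
#' @return an object of class \code{roi_set} with masks \code{gtv},
#'   \code{pt_pz}, \code{pt_tz}, \code{nat_pz}, \code{nat_tz}.
#' @export
split_ring_and_nat <- function(ring, gtv, pz, tz, prostate, spacing_mm) {
  for (nm in c("ring", "gtv", "pz", "tz", "prostate"))
    if (is.null(get(nm))) stop(sprintf("required mask '%s' is missing", nm))
  check_same_grid(ring, gtv, pz, tz, prostate)
  ring <- ring & prostate & !gtv
  rs <- structure(list(gtv = gtv & prostate,
                       pt_pz = ring & pz,
                       pt_tz = ring & tz,
                       nat_pz = pz & !ring & !gtv,
                       nat_tz = tz & !ring & !gtv,
                       spacing_mm = as.numeric(spacing_mm)),
                  class = "roi_set")
  validate_roi_set(rs, prostate)
  rs
}

#' Validate the disjointness and containment invariants of an ROI set
#'
#' @param rs a \code{roi_set}.
#' @param prostate optional prostate mask for containment checks.
#' @return \code{TRUE} invisibly; stops on violation.
#' @export
validate_roi_set <- function(rs, prostate = NULL) {
  m <- rs[c("gtv", "pt_pz", "pt_tz", "nat_pz", "nat_tz")]
  if (sum(m$pt_pz & m$gtv) > 0 || sum(m$pt_tz & m$gtv) > 0)
    stop("peritumoral ring overlaps the GTV")
  if (sum(m$pt_pz & m$pt_tz) > 0) stop("PT-PZ and PT-TZ overlap")
  ring <- m$pt_pz | m$pt_tz
  if (sum(m$nat_pz & (m$gtv | ring)) > 0 || sum(m$nat_tz & (m$gtv | ring)) > 0)
    stop("NAT overlaps tumor or ring")
  if (sum(m$nat_pz & m$nat_tz) > 0) stop("NAT-PZ and NAT-TZ overlap")
  if (!is.null(prostate)) {
    for (nm in names(m))
      if (sum(m[[nm]] & !prostate) > 0)
        stop(sprintf("ROI '%s' extends outside the prostate", nm))
  }
  invisible(TRUE)
}

#' Derive all five analysis ROIs from prostate, PZ, and GTV masks
#'
#' Convenience wrapper: merges multifocal lesions, derives the TZ, grows the
#' peritumoral ring, and splits ring and normally-appearing tissue by zone.
#'
#' @param prostate,pz logical masks.
#' @param gtvs a single logical mask or a list of per-lesion masks.
#' @param spacing_mm per-axis voxel spacing in mm.
#' @param thickness_mm ring thickness in mm (default 5).
#' @param tol_frac PZ-outside-prostate tolerance passed to
#'   \code{\link{derive_tz}}.
#' @return a \code{roi_set}.
#' @export
derive_rois <- function(prostate, pz, gtvs, spacing_mm, thickness_mm = 5.0,
                        tol_frac = 0.01) {
  gtv <- if (is.list(gtvs)) merge_multifocal(gtvs) else gtvs
  pz <- pz & prostate
  tz <- derive_tz(prostate, pz, tol_frac = tol_frac)
  # zone priority: voxels claimed by both zones after resampling go to PZ
  tz <- tz & !pz
  ring <- peritumoral_ring(gtv, spacing_mm, thickness_mm)
  split_ring_and_nat(ring, gtv, pz, tz, prostate, spacing_mm)
}

#' @export
print.roi_set <- function(x, ...) {
  cnt <- vapply(x[c("gtv", "pt_pz", "pt_tz", "nat_pz", "nat_tz")], sum, 0L)
  cat("<roi_set> voxel counts:\n")
  print(cnt)
  invisible(x)
}
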