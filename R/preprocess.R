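#' Analysis grid specification
#'
#' Target grid that every sequence is standardized onto before ROI geometry
#' and feature extraction: uniform in-plane pixel spacing, a common slice
#' thickness, and the in-plane padding (in pixels) used when cropping to the
#' prostate.
#'
#' @param in_plane_mm target in-plane pixel spacing in mm (default 0.5).
#' @param slice_mm target slice thickness in mm (default 3).
#' @param pad_px crop padding in pixels along x and y (default 10).
#' @return an object of class \code{grid_spec}.
#' @export
grid_spec <- function(in_plane_mm = 0.5, slice_mm = 3.0, pad_px = 10L) {
  stopifnot(in_plane_mm > 0, slice_mm > 0, pad_px >= 0)
  structure(list(in_plane_mm = in_plane_mm, slice_mm = slice_mm,
                 pad_px = as.integer(pad_px)),
            class = "grid_spec")
}

# clamp continuous source indices and gather with trilinear weights
trilinear_gather <- function(arr, xi, yi, zi) {
  d <- dim(arr)
  nx <- length(xi); ny <- length(yi); nz <- length(zi)
  prep <- function(v, n) {
    v0 <- pmin(pmax(floor(v), 1), max(n - 1L, 1L))
    f <- pmin(pmax(v - v0, 0), 1)
    if (n == 1L) f[] <- 0
    list(i0 = as.integer(v0), f = f)
  }
  px <- prep(xi, d[1]); py <- prep(yi, d[2]); pz <- prep(zi, d[3])
  X0 <- rep(px$i0, times = ny * nz); FX <- rep(px$f, times = ny * nz)
  Y0 <- rep(rep(py$i0, each = nx), times = nz)
  FY <- rep(rep(py$f, each = nx), times = nz)
  Z0 <- rep(pz$i0, each = nx * ny); FZ <- rep(pz$f, each = nx * ny)
  X1 <- pmin(X0 + 1L, d[1]); Y1 <- pmin(Y0 + 1L, d[2]); Z1 <- pmin(Z0 + 1L, d[3])
  lin <- function(i, j, k) i + (j - 1L) * d[1] + (k - 1L) * (d[1] * d[2])
  v <- arr[lin(X0, Y0, Z0)] * (1 - FX) * (1 - FY) * (1 - FZ) +
       arr[lin(X1, Y0, Z0)] * FX       * (1 - FY) * (1 - FZ) +
       arr[lin(X0, Y1, Z0)] * (1 - FX) * FY       * (1 - FZ) +
       arr[lin(X1, Y1, Z0)] * FX       * FY       * (1 - FZ) +
       arr[lin(X0, Y0, Z1)] * (1 - FX) * (1 - FY) * FZ +
       arr[lin(X1, Y0, Z1)] * FX       * (1 - FY) * FZ +
       arr[lin(X0, Y1, Z1)] * (1 - FX) * FY       * FZ +
       arr[lin(X1, Y1, Z1)] * FX       * FY       * FZ
  array(v, c(nx, ny, nz))
}

nearest_gather <- function(arr, xi, yi, zi) {
  d <- dim(arr)
  ix <- pmin(pmax(as.integer(round(xi)), 1L), d[1])
  iy <- pmin(pmax(as.integer(round(yi)), 1L), d[2])
  iz <- pmin(pmax(as.integer(round(zi)), 1L), d[3])
  nx <- length(ix); ny <- length(iy); nz <- length(iz)
  X <- rep(ix, times = ny * nz)
  Y <- rep(rep(iy, each = nx), times = nz)
  Z <- rep(iz, each = nx * ny)
  array(arr[X + (Y - 1L) * d[1] + (Z - 1L) * (d[1] * d[2])], c(nx, ny, nz))
}

#' Resample a volume or mask onto the analysis grid
#'
#' Images are interpolated trilinearly (value-preserving for constants, no
#' overshoot); masks use nearest-neighbour so binarity is preserved. If the
#' source spacing already matches the target the data pass through unchanged.
#'
#' @param vol an \code{image_volume} (3-D or 4-D) or a logical/numeric array
#'   with a \code{spacing_mm} attribute.
#' @param grid a \code{grid_spec}.
#' @param kind \code{"image"} or \code{"mask"}.
#' @return an \code{image_volume} (or logical array with spacing attribute
#'   when the input was a bare mask array) on the target grid.
#' @export
resample <- function(vol, grid, kind = c("image", "mask")) {
  kind <- match.arg(kind)
  sp <- vol_spacing(vol)
  arr <- vol_data(vol)
  was_logical <- is.logical(arr)
  target <- c(grid$in_plane_mm, grid$in_plane_mm, grid$slice_mm)
  if (all(abs(sp - target) < 1e-9)) {
    if (is_image_volume(vol)) return(vol)
    out <- arr
    attr(out, "spacing_mm") <- sp
    return(out)
  }
  d <- dim(arr)[1:3]
  extent <- d * sp
  nd <- pmax(1L, as.integer(round(extent / target)))
  # voxel-centre coordinates of the target grid mapped to source indices
  xi <- ((seq_len(nd[1]) - 0.5) * target[1]) / sp[1] + 0.5
  yi <- ((seq_len(nd[2]) - 0.5) * target[2]) / sp[2] + 0.5
  zi <- ((seq_len(nd[3]) - 0.5) * target[3]) / sp[3] + 0.5
  one <- function(a) {
    if (kind == "mask") nearest_gather(a, xi, yi, zi)
    else trilinear_gather(a, xi, yi, zi)
  }
  if (length(dim(arr)) == 4L) {
    nt <- dim(arr)[4]
    out <- array(0, c(nd, nt))
    for (f in seq_len(nt)) out[, , , f] <- one(arr[, , , f, drop = TRUE])
    return(image_volume(out, target, t_s = if (is_image_volume(vol)) vol$t_s else NULL))
  }
  out <- one(arr * 1.0)
  if (was_logical && kind == "mask") {
    out <- array(out > 0.5, dim(out))
    if (!is_image_volume(vol)) {
      attr(out, "spacing_mm") <- target
      return(out)
    }
  }
  image_volume(out, target)
}

#' Bounding box of the prostate with in-plane padding
#'
#' @param prostate logical mask array.
#' @param pad_px padding in pixels applied along x and y (clamped at edges);
#'   z is restricted to the prostate extent with no padding.
#' @return list with integer ranges \code{x}, \code{y}, \code{z}.
#' @export
crop_box <- function(prostate, pad_px = 10L) {
  if (!any(prostate)) stop("empty prostate mask")
  d <- dim(prostate)
  idx <- which(prostate, arr.ind = TRUE)
  list(x = c(max(1L, min(idx[, 1]) - pad_px), min(d[1], max(idx[, 1]) + pad_px)),
       y = c(max(1L, min(idx[, 2]) - pad_px), min(d[2], max(idx[, 2]) + pad_px)),
       z = c(min(idx[, 3]), max(idx[, 3])))
}

apply_crop <- function(arr, box) {
  if (length(dim(arr)) == 4L)
    arr[box$x[1]:box$x[2], box$y[1]:box$y[2], box$z[1]:box$z[2], , drop = FALSE]
  else
    arr[box$x[1]:box$x[2], box$y[1]:box$y[2], box$z[1]:box$z[2], drop = FALSE]
}

#' Crop a volume to the prostate region of interest
#'
#' The output bounding box is the prostate bounding box expanded by
#' \code{grid$pad_px} pixels along x and y (clamped at the image edges); the
#' z range is the prostate extent. The returned zero-based \code{offset}
#' maps cropped coordinates back to the original grid.
#'
#' @param vol an \code{image_volume} or array.
#' @param prostate logical prostate mask on the same grid.
#' @param grid a \code{grid_spec} (only \code{pad_px} is used).
#' @return list with elements \code{volume} and \code{offset}.
#' @export
crop_to_prostate <- function(vol, prostate, grid = grid_spec()) {
  arr <- vol_data(vol)
  if (!all(dim(arr)[1:3] == dim(prostate))) stop("grid mismatch between volume and prostate mask")
  box <- crop_box(prostate, grid$pad_px)
  out <- apply_crop(arr, box)
  offset <- c(box$x[1], box$y[1], box$z[1]) - 1L
  if (is_image_volume(vol)) out <- image_volume(out, vol$spacing_mm, t_s = vol$t_s)
  list(volume = out, offset = offset, box = box)
}

#' Undo a prostate crop
#'
#' Places a cropped array back at its original coordinates inside a grid of
#' dimensions \code{full_dim}; voxels outside the crop are filled with
#' \code{fill}.
#'
#' @param arr cropped array (3-D).
#' @param offset zero-based offset returned by \code{\link{crop_to_prostate}}.
#' @param full_dim dimensions of the original grid.
#' @param fill fill value (default \code{NA}).
#' @return array of dimensions \code{full_dim}.
#' @export
uncrop <- function(arr, offset, full_dim, fill = NA_real_) {
  arr <- vol_data(arr)
  out <- array(fill, full_dim)
  d <- dim(arr)
  out[offset[1] + seq_len(d[1]), offset[2] + seq_len(d[2]), offset[3] + seq_len(d[3])] <- arr
  out
}
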