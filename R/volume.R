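#' Image volume container
#'
#' A minimal container for a scalar 3-D volume or a 4-D dynamic series:
#' a numeric array plus per-axis voxel spacing in millimetres and, for 4-D
#' data, the frame time stamps in seconds.
#'
#' @param data numeric 3-D array (x, y, z) or 4-D array (x, y, z, t).
#' @param spacing_mm numeric length-3 vector of voxel spacing in mm.
#' @param t_s optional numeric vector of frame times in seconds; required for
#'   4-D data, with one entry per frame.
#' @return an object of class \code{image_volume}.
#' @export
image_volume <- function(data, spacing_mm, t_s = NULL) {
  stopifnot(is.array(data), length(dim(data)) %in% c(3L, 4L))
  spacing_mm <- as.numeric(spacing_mm)
  if (length(spacing_mm) != 3L || any(!is.finite(spacing_mm)) || any(spacing_mm <= 0))
    stop("spacing_mm must be three strictly positive values")
  if (length(dim(data)) == 4L) {
    if (is.null(t_s) || length(t_s) != dim(data)[4L])
      stop("4-D volumes need one time stamp per frame")
    t_s <- as.numeric(t_s)
    if (any(diff(t_s) <= 0)) stop("time stamps must be strictly increasing")
  }
  structure(list(data = data, spacing_mm = spacing_mm, t_s = t_s),
            class = "image_volume")
}

#' @export
print.image_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<image_volume> %s voxels, spacing %s mm%s\n",
              paste(d, collapse = "x"),
              paste(signif(x$spacing_mm, 4), collapse = "x"),
              if (is.null(x$t_s)) "" else sprintf(", %d frames over %.0f s",
                                                  length(x$t_s), max(x$t_s))))
  invisible(x)
}

is_image_volume <- function(x) inherits(x, "image_volume")

# spacing accessor that accepts a bare array carrying a "spacing_mm" attribute
vol_spacing <- function(x) {
  if (is_image_volume(x)) return(x$spacing_mm)
  sp <- attr(x, "spacing_mm")
  if (is.null(sp)) stop("no spacing metadata on volume")
  sp
}

vol_data <- function(x) if (is_image_volume(x)) x$data else x

#' Write a volume or mask to NIfTI-1
#'
#' @param vol an \code{image_volume} or plain array.
#' @param path output file path (\code{.nii} or \code{.nii.gz}).
#' @param spacing_mm spacing override when \code{vol} is a bare array.
#' @return the path, invisibly.
#' @export
write_volume_nifti <- function(vol, path, spacing_mm = NULL) {
  arr <- vol_data(vol)
  sp <- if (is.null(spacing_mm)) vol_spacing(vol) else spacing_mm
  if (is.logical(arr)) arr <- array(as.integer(arr), dim(arr))
  img <- RNifti::asNifti(arr)
  pd <- RNifti::pixdim(img)
  pd[seq_along(sp)] <- sp
  RNifti::pixdim(img) <- pd
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a NIfTI-1 volume
#'
#' @param path file path.
#' @param t_s optional frame times for 4-D series.
#' @return an \code{image_volume}.
#' @export
read_volume_nifti <- function(path, t_s = NULL) {
  img <- RNifti::readNifti(path)
  sp <- RNifti::pixdim(img)[1:3]
  image_volume(array(as.numeric(img), dim(img)), sp, t_s = t_s)
}
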