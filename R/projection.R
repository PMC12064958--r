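#' En face projections
#'
#' A flow volume is projected to 2D either by a plain maximum intensity
#' projection (MIP) or by a depth-encoded MIP in which the depth of the
#' brightest voxel selects a hue on a green-to-red colorbar (green =
#' superficial, red = deep) and the MIP value sets the brightness.
#'
#' @name projection
NULL

#' Maximum intensity projection
#'
#' @param volume flow volume (3D array, axes z, y, x)
#' @param z_range optional inclusive depth range \code{c(z0, z1)}; the whole
#'   depth range when omitted
#' @return en face image: matrix of per-pixel maxima over the depth range
#' @export
mip <- function(volume, z_range = NULL) {
  stopifnot(is.array(volume), length(dim(volume)) == 3)
  nz <- dim(volume)[1]
  if (is.null(z_range)) z_range <- c(1L, nz)
  z0 <- z_range[1]; z1 <- z_range[2]
  if (z0 > z1 || z0 < 1 || z1 > nz) {
    stop(sprintf("invalid z_range [%d, %d] for depth %d", z0, z1, nz),
         call. = FALSE)
  }
  apply(volume[z0:z1, , , drop = FALSE], c(2, 3), max)
}

#' Depth-encoded maximum intensity projection
#'
#' For each lateral position the depth of the intensity argmax is mapped
#' linearly from green (z = 1) to red (z = depth), and the RGB triple is
#' scaled by the MIP value, so empty columns stay black.
#'
#' @param volume flow volume
#' @return RGB array of shape (height, width, 3) in \code{[0,1]}
#' @export
depth_encoded_mip <- function(volume) {
  stopifnot(is.array(volume), length(dim(volume)) == 3)
  d <- dim(volume)
  zmax <- apply(volume, c(2, 3), which.max)
  m <- apply(volume, c(2, 3), max)
  t_ <- if (d[1] > 1) (zmax - 1) / (d[1] - 1) else matrix(0, d[2], d[3])
  rgb <- array(0, c(d[2], d[3], 3))
  rgb[, , 1] <- t_ * m        # red grows with depth
  rgb[, , 2] <- (1 - t_) * m  # green at the surface
  rgb
}
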