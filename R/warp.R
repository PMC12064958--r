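# Bilinear sampling and rigid in-plane warps.
#
# Coordinate convention: pixel (i, j) sits at coordinates (i, j), 1-based;
# rotations are about the image center ((h+1)/2, (w+1)/2). A rigid transform
# (dy, dx, theta) maps source coordinates p to R(theta) %*% (p - c) + c + t,
# i.e. rotate about the center, then translate. warp_image_rigid() produces
# the image *seen* after that motion: output pixel q samples the source at
# the inverse-transformed location. Out-of-frame samples are NA so callers
# can distinguish "invalid" from "dark".

# Sample img at (ys, xs) (same-length vectors) by bilinear interpolation.
# Returns NA where the 2x2 support leaves the image.
bilinear_sample <- function(img, ys, xs) {
  h <- nrow(img); w <- ncol(img)
  y0 <- floor(ys); x0 <- floor(xs)
  fy <- ys - y0;  fx <- xs - x0
  ok <- y0 >= 1 & y0 + 1 <= h & x0 >= 1 & x0 + 1 <= w
  # exact grid points on the far edge are valid too
  edge <- (ys >= 1 & ys <= h & xs >= 1 & xs <= w) & !ok
  out <- rep(NA_real_, length(ys))
  if (any(ok)) {
    i00 <- (x0[ok] - 1) * h + y0[ok]
    v00 <- img[i00];      v10 <- img[i00 + 1]
    v01 <- img[i00 + h];  v11 <- img[i00 + h + 1]
    out[ok] <- (1 - fy[ok]) * (1 - fx[ok]) * v00 + fy[ok] * (1 - fx[ok]) * v10 +
               (1 - fy[ok]) * fx[ok] * v01 + fy[ok] * fx[ok] * v11
  }
  if (any(edge)) {
    yc <- pmin(pmax(y0[edge], 1), h); xc <- pmin(pmax(x0[edge], 1), w)
    yb <- pmin(y0[edge] + 1, h); xb <- pmin(x0[edge] + 1, w)
    v00 <- img[(xc - 1) * h + yc]; v10 <- img[(xc - 1) * h + yb]
    v01 <- img[(xb - 1) * h + yc]; v11 <- img[(xb - 1) * h + yb]
    out[edge] <- (1 - fy[edge]) * (1 - fx[edge]) * v00 +
                 fy[edge] * (1 - fx[edge]) * v10 +
                 (1 - fy[edge]) * fx[edge] * v01 + fy[edge] * fx[edge] * v11
  }
  out
}

# Apply the rigid motion (dy, dx, theta_deg about center) to an image.
# Output pixel q = T(p): sample source at p = T^{-1}(q).
warp_image_rigid <- function(img, dy, dx, theta_deg, fill = NA_real_) {
  h <- nrow(img); w <- ncol(img)
  cy <- (h + 1) / 2; cx <- (w + 1) / 2
  th <- theta_deg * pi / 180
  g <- expand.grid(y = seq_len(h), x = seq_len(w))
  # inverse transform: undo translation, rotate by -theta about center
  uy <- g$y - dy - cy; ux <- g$x - dx - cx
  sy <- cos(th) * uy + sin(th) * ux + cy
  sx <- -sin(th) * uy + cos(th) * ux + cx
  vals <- bilinear_sample(img, sy, sx)
  if (!is.na(fill)) vals[is.na(vals)] <- fill
  matrix(vals, h, w)
}

# Same rigid motion applied to every C-scan slice of a volume.
warp_volume_rigid <- function(volume, dy, dx, theta_deg, fill = 0) {
  out <- volume
  for (z in seq_len(dim(volume)[1])) {
    out[z, , ] <- warp_image_rigid(volume[z, , ], dy, dx, theta_deg, fill = fill)
  }
  out
}

# Validity mask of a rigid warp: TRUE where the warped image is defined.
warp_valid_mask <- function(h, w, dy, dx, theta_deg) {
  ones <- matrix(1, h, w)
  !is.na(warp_image_rigid(ones, dy, dx, theta_deg, fill = NA_real_))
}
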