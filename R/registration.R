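#' Registration and averaging of repeated en face acquisitions
#'
#' Repeated acquisitions of the same tissue drift by small rigid motions.
#' To build a high-quality reference label, one repeat is chosen as the
#' reference, every other repeat is registered to it with scale-invariant
#' blob keypoints, ratio-test matching and a RANSAC similarity model, the
#' unmatched peripheral areas are cut off, and the co-registered crops are
#' averaged pixelwise.
#'
#' @name registration
NULL

# --- keypoint detection ----------------------------------------------------

# Difference-of-Gaussian blob keypoints with subpixel quadratic refinement.
# Returns a matrix with columns y, x, response.
detect_keypoints <- function(img, n_max = 500) {
  sigmas <- c(1.2, 1.7, 2.4, 3.4)
  blurred <- lapply(sigmas, function(s) EBImage::gblur(img, sigma = s))
  h <- nrow(img); w <- ncol(img)
  kps <- NULL
  for (k in seq_len(length(sigmas) - 1)) {
    dog <- blurred[[k]] - blurred[[k + 1]]
    a <- abs(dog)
    # strict local maxima of |DoG| in the 3x3 neighborhood (interior only)
    ic <- 2:(h - 1); jc <- 2:(w - 1)
    c0 <- a[ic, jc]
    is_max <- c0 > a[ic - 1, jc] & c0 > a[ic + 1, jc] &
              c0 > a[ic, jc - 1] & c0 > a[ic, jc + 1] &
              c0 > a[ic - 1, jc - 1] & c0 > a[ic - 1, jc + 1] &
              c0 > a[ic + 1, jc - 1] & c0 > a[ic + 1, jc + 1] &
              c0 > 0.02 * max(a)
    idx <- which(is_max, arr.ind = TRUE)
    if (nrow(idx) == 0) next
    ys <- idx[, 1] + 1; xs <- idx[, 2] + 1
    # subpixel offset from a 2D quadratic fit of the DoG response
    gy <- (dog[cbind(ys + 1, xs)] - dog[cbind(ys - 1, xs)]) / 2
    gx <- (dog[cbind(ys, xs + 1)] - dog[cbind(ys, xs - 1)]) / 2
    hyy <- dog[cbind(ys + 1, xs)] + dog[cbind(ys - 1, xs)] - 2 * dog[cbind(ys, xs)]
    hxx <- dog[cbind(ys, xs + 1)] + dog[cbind(ys, xs - 1)] - 2 * dog[cbind(ys, xs)]
    hxy <- (dog[cbind(ys + 1, xs + 1)] - dog[cbind(ys + 1, xs - 1)] -
            dog[cbind(ys - 1, xs + 1)] + dog[cbind(ys - 1, xs - 1)]) / 4
    det <- hyy * hxx - hxy^2
    oy <- ifelse(abs(det) > 1e-12, -(hxx * gy - hxy * gx) / det, 0)
    ox <- ifelse(abs(det) > 1e-12, -(hyy * gx - hxy * gy) / det, 0)
    oy <- pmax(pmin(oy, 0.5), -0.5); ox <- pmax(pmin(ox, 0.5), -0.5)
    kps <- rbind(kps, cbind(y = ys + oy, x = xs + ox,
                            response = c0[is_max], scale = k))
  }
  if (is.null(kps)) return(matrix(0, 0, 4))
  kps <- kps[order(-kps[, 3]), , drop = FALSE]
  head(kps, n_max)
}

# Normalized intensity-patch descriptors (11x11, zero mean, unit norm) from a
# lightly smoothed image; keypoints whose patch leaves the frame are dropped.
extract_descriptors <- function(img, kps, half = 5L) {
  sm <- EBImage::gblur(img, sigma = 1.2)
  h <- nrow(img); w <- ncol(img)
  yr <- round(kps[, 1]); xr <- round(kps[, 2])
  keep <- yr > half & yr <= h - half & xr > half & xr <= w - half
  kps <- kps[keep, , drop = FALSE]; yr <- yr[keep]; xr <- xr[keep]
  if (nrow(kps) == 0) return(list(kps = kps, desc = matrix(0, 0, (2 * half + 1)^2)))
  desc <- t(vapply(seq_len(nrow(kps)), function(i) {
    p <- sm[(yr[i] - half):(yr[i] + half), (xr[i] - half):(xr[i] + half)]
    p <- p - mean(p)
    nrm <- sqrt(sum(p^2))
    if (nrm > 1e-12) as.vector(p / nrm) else as.vector(p)
  }, numeric((2 * half + 1)^2)))
  list(kps = kps, desc = desc)
}

# Lowe-style ratio-test matching on Euclidean distance between unit-norm
# descriptors. Returns index pairs (i in a, j in b).
match_descriptors <- function(da, db, ratio = 0.75) {
  if (nrow(da$desc) == 0 || nrow(db$desc) < 2) return(matrix(0L, 0, 2))
  sim <- da$desc %*% t(db$desc)             # correlation; dist^2 = 2 - 2 sim
  best <- max.col(sim)
  n <- nrow(sim)
  b1 <- sim[cbind(seq_len(n), best)]
  sim[cbind(seq_len(n), best)] <- -Inf
  b2 <- sim[cbind(seq_len(n), max.col(sim))]
  d1 <- sqrt(pmax(2 - 2 * b1, 0)); d2 <- sqrt(pmax(2 - 2 * b2, 0))
  ok <- d1 < ratio * d2
  cbind(which(ok), best[ok])
}

# RANSAC similarity estimation between matched point sets (complex form
# z' = q z + t with z = x + i y in absolute pixel coordinates).
# Returns NULL when no model with enough inliers exists.
ransac_similarity <- function(pa, pb, n_iter = 1000, thresh = 2, min_inliers = 6) {
  za <- complex(real = pa[, 2], imaginary = pa[, 1])
  zb <- complex(real = pb[, 2], imaginary = pb[, 1])
  n <- length(za)
  if (n < min_inliers) return(NULL)
  best <- NULL; best_n <- 0
  for (it in seq_len(n_iter)) {
    s <- sample.int(n, 2)
    dz <- za[s[2]] - za[s[1]]
    if (Mod(dz) < 1e-9) next
    q <- (zb[s[2]] - zb[s[1]]) / dz
    # drift is rigid: reject models with scale far from 1
    if (Mod(q) < 0.8 || Mod(q) > 1.25) next
    t0 <- zb[s[1]] - q * za[s[1]]
    err <- Mod(q * za + t0 - zb)
    nin <- sum(err < thresh)
    if (nin > best_n) { best_n <- nin; best <- which(err < thresh) }
  }
  if (is.null(best) || best_n < min_inliers) return(NULL)
  # least-squares refinement on the inliers (complex Umeyama)
  for (pass in 1:2) {
    ai <- za[best]; bi <- zb[best]
    ma <- mean(ai); mb <- mean(bi)
    q <- sum((bi - mb) * Conj(ai - ma)) / sum(Mod(ai - ma)^2)
    t0 <- mb - q * ma
    err <- Mod(q * za + t0 - zb)
    best <- which(err < thresh)
    if (length(best) < min_inliers) return(NULL)
  }
  list(q = q, t = t0, inliers = best)
}

# Decompose z' = q z + t into center-based rigid parameters matching
# warp_image_rigid()'s (dy, dx, theta_deg) convention (theta about center,
# then translate). In the (y, x) frame a rotation by theta is the complex
# rotation by -theta, hence the sign flip.
similarity_to_rigid <- function(q, t0, h, w) {
  zc <- complex(real = (w + 1) / 2, imaginary = (h + 1) / 2)
  tc <- t0 - zc * (1 - q)
  list(dy = Im(tc), dx = Re(tc), theta_deg = -Arg(q) * 180 / pi,
       scale = Mod(q))
}

# Warp `img` (the moving image) into the reference frame of the mapping
# z_ref = q z_mov + t: each reference pixel samples the moving image at
# (z - t)/q. NA outside the moving frame.
warp_to_reference <- function(img, q, t0) {
  h <- nrow(img); w <- ncol(img)
  g <- expand.grid(y = seq_len(h), x = seq_len(w))
  z <- complex(real = g$x, imaginary = g$y)
  src <- (z - t0) / q
  matrix(bilinear_sample(img, Im(src), Re(src)), h, w)
}

# Largest axis-aligned rectangle of jointly valid pixels, found by greedily
# trimming the border line carrying the most invalid pixels.
largest_valid_rect <- function(valid) {
  top <- 1L; bottom <- nrow(valid); left <- 1L; right <- ncol(valid)
  repeat {
    if (top > bottom || left > right) {
      stop("registration left no common valid region", call. = FALSE)
    }
    sub <- valid[top:bottom, left:right, drop = FALSE]
    if (all(sub)) break
    bad <- c(top = sum(!sub[1, ]), bottom = sum(!sub[nrow(sub), ]),
             left = sum(!sub[, 1]), right = sum(!sub[, ncol(sub)]))
    side <- names(which.max(bad))
    switch(side, top = top <- top + 1L, bottom = bottom <- bottom - 1L,
           left = left <- left + 1L, right = right <- right - 1L)
  }
  c(top = top, left = left, height = bottom - top + 1L,
    width = right - left + 1L)
}

#' Register repeated en face images to a common reference
#'
#' Every non-reference image is matched to the reference through
#' scale-invariant difference-of-Gaussian keypoints, ratio-test descriptor
#' matching and a RANSAC-estimated similarity transform, then warped into
#' the reference frame with bilinear interpolation. Pixels that fall outside
#' a source frame are marked invalid (never zero-filled) and the common
#' valid region is cropped.
#'
#' @param images list of >= 2 en face matrices, identical shapes
#' @param reference_index 1-based index of the reference image
#' @param ratio Lowe ratio-test threshold for descriptor matching
#' @param ransac_thresh RANSAC reprojection threshold in pixels
#' @param seed seed for the RANSAC sampler
#' @return an object of class \code{octa_registration}: list with
#'   \code{registered} (list of cropped, aligned images), \code{transforms}
#'   (per image: \code{dy}, \code{dx}, \code{theta_deg}, \code{scale}; the
#'   reference holds the identity) and \code{crop_box}
#'   (\code{top, left, height, width}, 1-based)
#' @export
register_enface <- function(images, reference_index = 1, ratio = 0.75,
                            ransac_thresh = 2, seed = 1L) {
  stopifnot(is.list(images), length(images) >= 2)
  shp <- dim(images[[1]])
  for (im in images) {
    if (!identical(dim(im), shp)) stop("images must share one shape", call. = FALSE)
  }
  stopifnot(reference_index >= 1, reference_index <= length(images))
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(as.integer(seed))

  h <- shp[1]; w <- shp[2]
  ref <- images[[reference_index]]
  dref <- extract_descriptors(ref, detect_keypoints(ref))
  registered <- vector("list", length(images))
  transforms <- vector("list", length(images))
  valid <- matrix(TRUE, h, w)
  for (i in seq_along(images)) {
    if (i == reference_index) {
      registered[[i]] <- ref
      transforms[[i]] <- list(dy = 0, dx = 0, theta_deg = 0, scale = 1)
      next
    }
    dmov <- extract_descriptors(images[[i]], detect_keypoints(images[[i]]))
    m <- match_descriptors(dmov, dref, ratio = ratio)
    if (nrow(m) < 8) {
      stop(sprintf("registration failed for image %d: only %d feature matches",
                   i, nrow(m)), call. = FALSE)
    }
    fit <- ransac_similarity(dmov$kps[m[, 1], 1:2, drop = FALSE],
                             dref$kps[m[, 2], 1:2, drop = FALSE],
                             thresh = ransac_thresh)
    if (is.null(fit)) {
      stop(sprintf("registration failed for image %d: no consistent transform",
                   i), call. = FALSE)
    }
    wimg <- warp_to_reference(images[[i]], fit$q, fit$t)
    valid <- valid & !is.na(wimg)
    registered[[i]] <- wimg
    transforms[[i]] <- similarity_to_rigid(fit$q, fit$t, h, w)
  }
  box <- largest_valid_rect(valid)
  rows <- box["top"]:(box["top"] + box["height"] - 1)
  cols <- box["left"]:(box["left"] + box["width"] - 1)
  registered <- lapply(registered, function(im) im[rows, cols, drop = FALSE])
  structure(list(registered = registered, transforms = transforms,
                 crop_box = box, reference_index = reference_index),
            class = "octa_registration")
}

#' Average registered en face images into a reference label
#'
#' @param result an \code{octa_registration} from [register_enface()], or a
#'   plain list of aligned same-shape images
#' @return pixelwise arithmetic mean, clamped to \code{[0,1]}
#' @export
average_registered <- function(result) {
  imgs <- if (inherits(result, "octa_registration")) result$registered else result
  stopifnot(is.list(imgs), length(imgs) >= 1)
  shp <- dim(imgs[[1]])
  acc <- matrix(0, shp[1], shp[2])
  for (im in imgs) {
    if (!identical(dim(im), shp)) {
      stop("internal error: registered images have unequal shapes", call. = FALSE)
    }
    acc <- acc + im
  }
  out <- acc / length(imgs)
  out[out > 1] <- 1; out[out < 0] <- 0
  out
}
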