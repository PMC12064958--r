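#' Vascular quality metrics
#'
#' Quantitative evaluation of angiograms: global Otsu binarization,
#' morphological skeletonization, and the four metrics
#' \itemize{
#'   \item CNR, contrast-to-noise ratio:
#'     \eqn{(\mu_s - \mu_b)/\sqrt{\sigma_s^2 + \sigma_b^2}} between the
#'     signal (vessel) and background regions, population standard
#'     deviations;
#'   \item VD, vessel density: white-pixel fraction of the binarized image;
#'   \item VDI, vessel diameter index: binarized vessel area divided by
#'     skeleton length, an average-caliber proxy;
#'   \item VC, vessel continuity: fraction of skeleton pixels lying in
#'     8-connected components of at least 5 pixels.
#' }
#'
#' @name vascular_metrics
NULL

#' Binarize an en face image with a global Otsu threshold
#'
#' @param image matrix in \code{[0,1]}, not constant
#' @return logical matrix; TRUE marks vessel/signal pixels (value above the
#'   threshold)
#' @export
binarize <- function(image) {
  check_volume_range(image, "image")
  if (diff(range(image)) < 1e-12) {
    stop("cannot threshold a constant image", call. = FALSE)
  }
  th <- EBImage::otsu(image, range = c(0, 1), levels = 256)
  image > th
}

#' Skeletonize a binary vessel mask
#'
#' Zhang-Suen morphological thinning to 1-pixel-wide centerlines; preserves
#' 8-connectivity and is idempotent. An empty mask yields an empty skeleton.
#'
#' @param binary logical matrix
#' @return logical matrix of centerline pixels
#' @export
skeletonize <- function(binary) {
  stopifnot(is.logical(binary) || all(binary %in% c(0, 1)))
  m <- matrix(FALSE, nrow(binary) + 2, ncol(binary) + 2)
  m[2:(nrow(binary) + 1), 2:(ncol(binary) + 1)] <- binary > 0
  h <- nrow(m); w <- ncol(m)
  ic <- 2:(h - 1); jc <- 2:(w - 1)
  shift <- function(x, dy, dx) x[ic + dy, jc + dx]
  repeat {
    changed <- FALSE
    for (step in 1:2) {
      p <- m[ic, jc]
      p2 <- shift(m, -1, 0); p3 <- shift(m, -1, 1); p4 <- shift(m, 0, 1)
      p5 <- shift(m, 1, 1);  p6 <- shift(m, 1, 0);  p7 <- shift(m, 1, -1)
      p8 <- shift(m, 0, -1); p9 <- shift(m, -1, -1)
      b <- p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9
      a <- (!p2 & p3) + (!p3 & p4) + (!p4 & p5) + (!p5 & p6) +
           (!p6 & p7) + (!p7 & p8) + (!p8 & p9) + (!p9 & p2)
      if (step == 1) {
        cond <- p & b >= 2 & b <= 6 & a == 1 &
                !(p2 & p4 & p6) & !(p4 & p6 & p8)
      } else {
        cond <- p & b >= 2 & b <= 6 & a == 1 &
                !(p2 & p4 & p8) & !(p2 & p6 & p8)
      }
      if (any(cond)) {
        sub <- m[ic, jc]; sub[cond] <- FALSE; m[ic, jc] <- sub
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  m[2:(nrow(binary) + 1), 2:(ncol(binary) + 1)]
}

#' Contrast-to-noise ratio between two regions
#'
#' \eqn{CNR = (\mu_s - \mu_b)/\sqrt{\sigma_s^2 + \sigma_b^2}} with
#' population standard deviations over the signal and background masks.
#'
#' @param image en face image
#' @param signal_mask,background_mask disjoint nonempty logical masks
#' @return scalar CNR
#' @export
cnr <- function(image, signal_mask, background_mask) {
  stopifnot(identical(dim(image), dim(signal_mask)),
            identical(dim(image), dim(background_mask)))
  if (any(signal_mask & background_mask)) {
    stop("signal and background masks overlap", call. = FALSE)
  }
  if (!any(signal_mask) || !any(background_mask)) {
    stop("signal and background masks must both be nonempty", call. = FALSE)
  }
  s <- image[signal_mask]; b <- image[background_mask]
  vs <- mean((s - mean(s))^2); vb <- mean((b - mean(b))^2)
  if (vs + vb == 0) {
    stop("both regions have zero variance; CNR undefined", call. = FALSE)
  }
  (mean(s) - mean(b)) / sqrt(vs + vb)
}

#' Per-B-scan CNR through a volume
#'
#' For each B-scan (fixed slow index) the frame is binarized with its own
#' Otsu threshold to define the signal region, a stated superficial
#' avascular depth band provides the background region (any thresholded
#' signal pixels inside the band are excluded with a warning), and the CNR
#' of the frame is computed.
#'
#' @param volume flow volume (z, y, x)
#' @param background_depth_band inclusive depth range \code{c(z0, z1)} known
#'   to be avascular
#' @return numeric vector of length \code{dim(volume)[2]} (one CNR per
#'   B-scan; NA where the frame is constant)
#' @export
cross_sectional_cnr <- function(volume, background_depth_band) {
  stopifnot(is.array(volume), length(dim(volume)) == 3)
  z0 <- background_depth_band[1]; z1 <- background_depth_band[2]
  nz <- dim(volume)[1]
  stopifnot(z0 >= 1, z1 <= nz, z0 <= z1)
  ny <- dim(volume)[2]
  overlap_seen <- FALSE
  out <- vapply(seq_len(ny), function(y) {
    frame <- volume[, y, ]                     # depth x fast
    if (diff(range(frame)) < 1e-12) return(NA_real_)
    th <- EBImage::otsu(frame, range = c(0, 1), levels = 256)
    sig <- frame > th
    bg <- matrix(FALSE, nrow(frame), ncol(frame))
    bg[z0:z1, ] <- TRUE
    if (any(bg & sig)) overlap_seen <<- TRUE
    bg <- bg & !sig
    if (!any(sig) || !any(bg)) return(NA_real_)
    s <- frame[sig]; b <- frame[bg]
    vs <- mean((s - mean(s))^2); vb <- mean((b - mean(b))^2)
    if (vs + vb == 0) return(NA_real_)
    (mean(s) - mean(b)) / sqrt(vs + vb)
  }, numeric(1))
  if (overlap_seen) {
    warning("background depth band overlaps detected signal; overlapping ",
            "pixels excluded from the background region", call. = FALSE)
  }
  out
}

#' Vessel density
#'
#' @param binary logical vessel mask
#' @return white-pixel fraction in \code{[0,1]}
#' @export
vessel_density <- function(binary) {
  stopifnot(length(binary) > 0)
  sum(binary) / length(binary)
}

#' Vessel diameter index
#'
#' Total vessel area of the binarized image divided by total vessel length
#' of its skeleton; a proxy for the average vessel caliber.
#'
#' @param binary logical vessel mask
#' @param skeleton logical skeleton of `binary`
#' @return scalar >= 1 when the skeleton is a subset of the mask
#' @export
vessel_diameter_index <- function(binary, skeleton) {
  if (!any(skeleton)) stop("empty skeleton; VDI undefined", call. = FALSE)
  sum(binary) / sum(skeleton)
}

# 8-connected component sizes of a logical mask (iterative flood fill).
component_sizes <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  lab <- matrix(0L, h, w)
  sizes <- integer(0)
  nb <- expand.grid(dy = -1:1, dx = -1:1)
  nb <- nb[!(nb$dy == 0 & nb$dx == 0), ]
  idx <- which(mask)
  for (start in idx) {
    if (lab[start] != 0L) next
    id <- length(sizes) + 1L
    stack <- start
    lab[start] <- id
    n <- 0L
    while (length(stack) > 0) {
      cur <- stack[length(stack)]; stack <- stack[-length(stack)]
      n <- n + 1L
      y <- ((cur - 1) %% h) + 1; x <- ((cur - 1) %/% h) + 1
      yy <- y + nb$dy; xx <- x + nb$dx
      ok <- yy >= 1 & yy <= h & xx >= 1 & xx <= w
      cand <- (xx[ok] - 1) * h + yy[ok]
      cand <- cand[mask[cand] & lab[cand] == 0L]
      if (length(cand) > 0) {
        lab[cand] <- id
        stack <- c(stack, cand)
      }
    }
    sizes <- c(sizes, n)
  }
  sizes
}

#' Vessel continuity
#'
#' A skeleton pixel counts as "connected vasculature" when its 8-connected
#' component has at least `min_length` pixels; VC is the fraction of
#' skeleton pixels that qualify. Values near 1 indicate well-connected
#' vessels.
#'
#' @param skeleton logical skeleton image
#' @param min_length minimum component size (default 5 pixels)
#' @return scalar in \code{[0,1]}
#' @export
vessel_continuity <- function(skeleton, min_length = 5) {
  if (!any(skeleton)) stop("empty skeleton; VC undefined", call. = FALSE)
  sizes <- component_sizes(skeleton)
  sum(sizes[sizes >= min_length]) / sum(sizes)
}

#' Evaluate all vascular metrics of an en face image
#'
#' Chains [binarize()] and [skeletonize()] and computes CNR (signal = white
#' pixels, background = black pixels), VD, VDI and VC.
#'
#' @param image non-constant en face image
#' @return an \code{octa_metrics} list with fields \code{cnr}, \code{vd},
#'   \code{vdi}, \code{vc}
#' @export
evaluate_image <- function(image) {
  b <- binarize(image)
  s <- skeletonize(b)
  structure(list(cnr = cnr(image, b, !b),
                 vd = vessel_density(b),
                 vdi = vessel_diameter_index(b, s),
                 vc = vessel_continuity(s),
                 per_slice_cnr = NULL),
            class = "octa_metrics")
}

#' @export
as.data.frame.octa_metrics <- function(x, ...) {
  data.frame(cnr = x$cnr, vd = x$vd, vdi = x$vdi, vc = x$vc)
}

#' @export
print.octa_metrics <- function(x, ...) {
  cat(sprintf("vascular metrics: CNR %.4f | VD %.4f | VDI %.4f | VC %.4f\n",
              x$cnr, x$vd, x$vdi, x$vc))
  invisible(x)
}
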