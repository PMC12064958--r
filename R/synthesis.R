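#' Training-set synthesis
#'
#' Degraded network inputs are synthesized by superimposing a single-shot
#' en face angiogram E on an avascular C-scan noise image C,
#' \eqn{S = norm(\alpha E + \beta C)}, where norm is per-image min-max
#' normalization to \code{[0,1]}. The averaged registered en face image is
#' the training label. Noise-only and all-black pairs (both with zero
#' labels) are appended so the network learns to silence avascular slices,
#' and pairs are augmented by 90-degree rotations and random crop-resize.
#'
#' @name synthesis
NULL

#' Synthesis weights
#'
#' @param alpha weight of the en face image E (>= 0)
#' @param beta weight of the avascular noise image C (>= 0)
#' @return a `synthesis_weights` list; `alpha + beta` must be positive
#' @export
synthesis_weights <- function(alpha = 0.25, beta = 0.75) {
  stopifnot(alpha >= 0, beta >= 0, alpha + beta > 0)
  structure(list(alpha = alpha, beta = beta), class = "synthesis_weights")
}

#' Synthesize one degraded input image
#'
#' Computes the min-max normalization of \code{alpha * E + beta * C}. If the
#' weighted sum is constant the zero image is returned (all-black inputs are
#' a sanctioned training class, so the degenerate case is not an error).
#'
#' @param E single-shot en face image, matrix in \code{[0,1]}
#' @param C avascular C-scan noise image, same shape
#' @param w a [synthesis_weights()]
#' @return matrix in \code{[0,1]} with min 0 and max 1 (unless degenerate)
#' @export
synthesize_input <- function(E, C, w = synthesis_weights()) {
  stopifnot(inherits(w, "synthesis_weights"))
  if (!identical(dim(E), dim(C))) {
    stop("E and C must share one shape", call. = FALSE)
  }
  s <- w$alpha * E + w$beta * C
  rng <- range(s)
  if (rng[2] - rng[1] < 1e-12) return(matrix(0, nrow(E), ncol(E)))
  (s - rng[1]) / (rng[2] - rng[1])
}

#' Build the full training set
#'
#' For each (E, label) pair a noise image is drawn uniformly with
#' replacement from the avascular pool and the input is synthesized by
#' [synthesize_input()]. Then `n_noise_only` pairs (noise image, zero label)
#' and `n_black` pairs (zero image, zero label) are appended.
#'
#' @param pairs list of \code{list(E = , label = )} en face image pairs
#' @param noise_images list of avascular noise images (same shape)
#' @param w a [synthesis_weights()]
#' @param n_noise_only number of noise-only pairs to append (default 20)
#' @param n_black number of black pairs to append (default 20)
#' @param seed integer seed controlling the noise-image draws
#' @return list of \code{training_pair} objects: \code{list(input, label,
#'   tag)} with tag one of \code{"vascular"}, \code{"noise_only"},
#'   \code{"black"}
#' @export
build_training_set <- function(pairs, noise_images, w = synthesis_weights(),
                               n_noise_only = 20, n_black = 20, seed = 1L) {
  stopifnot(length(pairs) >= 1)
  if ((length(pairs) > 0 || n_noise_only > 0) && length(noise_images) == 0) {
    stop("noise image pool is empty", call. = FALSE)
  }
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(as.integer(seed))
  shp <- dim(pairs[[1]]$E)
  out <- vector("list", length(pairs) + n_noise_only + n_black)
  for (i in seq_along(pairs)) {
    C <- noise_images[[sample.int(length(noise_images), 1)]]
    out[[i]] <- structure(list(input = synthesize_input(pairs[[i]]$E, C, w),
                               label = pairs[[i]]$label, tag = "vascular"),
                          class = "training_pair")
  }
  zero <- matrix(0, shp[1], shp[2])
  for (k in seq_len(n_noise_only)) {
    C <- noise_images[[sample.int(length(noise_images), 1)]]
    out[[length(pairs) + k]] <- structure(
      list(input = C, label = zero, tag = "noise_only"), class = "training_pair")
  }
  for (k in seq_len(n_black)) {
    out[[length(pairs) + n_noise_only + k]] <- structure(
      list(input = zero, label = zero, tag = "black"), class = "training_pair")
  }
  out
}

#' Split pairs into training and test sets
#'
#' Mirrors the 350/50 partition used with 400 acquired volumes; the split is
#' by pair identity, so no image appears on both sides.
#'
#' @param n number of pairs
#' @param n_train number assigned to training (default \code{round(7n/8)},
#'   i.e. 350 of 400)
#' @param seed integer seed
#' @return list with integer index vectors \code{train} and \code{test}
#' @export
split_train_test <- function(n, n_train = round(n * 7 / 8), seed = 1L) {
  stopifnot(n >= 2, n_train >= 1, n_train < n)
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(as.integer(seed))
  idx <- sample.int(n)
  list(train = sort(idx[seq_len(n_train)]), test = sort(idx[-seq_len(n_train)]))
}

#' Augment a training pair
#'
#' Applies one random rotation (a multiple of 90 degrees, no interpolation)
#' and one random crop-then-resize (crop fraction in \code{[0.75, 1]},
#' bilinear resize back to the original size) identically to input and
#' label, preserving pixel alignment and output shape.
#'
#' @param pair a \code{training_pair}
#' @param seed integer seed
#' @return augmented \code{training_pair}
#' @export
augment <- function(pair, seed) {
  stopifnot(inherits(pair, "training_pair"))
  h <- nrow(pair$input); w <- ncol(pair$input)
  if (h != w) stop("augment requires square images", call. = FALSE)
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(as.integer(seed))
  k <- sample.int(4, 1) - 1L            # number of 90-degree rotations
  frac <- runif(1, 0.75, 1)
  cs <- max(8L, round(h * frac))
  y0 <- if (cs < h) sample.int(h - cs + 1, 1) else 1L
  x0 <- if (cs < h) sample.int(h - cs + 1, 1) else 1L
  tf <- function(im) {
    im <- rot90k(im, k)
    crop <- im[y0:(y0 + cs - 1), x0:(x0 + cs - 1), drop = FALSE]
    if (cs == h) crop
    else as.matrix(EBImage::resize(EBImage::Image(crop), w = h, h = h))
  }
  structure(list(input = tf(pair$input), label = tf(pair$label),
                 tag = pair$tag), class = "training_pair")
}

# Rotate a matrix counter-clockwise by k * 90 degrees.
rot90k <- function(m, k) {
  k <- k %% 4L
  if (k == 0) return(m)
  for (i in seq_len(k)) m <- t(m)[ncol(m):1, , drop = FALSE]
  m
}
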