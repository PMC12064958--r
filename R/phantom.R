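#' Synthetic OCTA phantom
#'
#' Generates volumetric OCTA-like data with the statistical structure the
#' enhancement method assumes: laterally biased branching vessel networks,
#' exponential depth attenuation of the flow signal, granular multiplicative
#' speckle plus additive background noise, repeated acquisitions of the same
#' tissue under small rigid motion drift, and pure-noise avascular C-scans.
#' Every operation is a deterministic function of its inputs and seed.
#'
#' @name phantom
NULL

#' Phantom configuration
#'
#' @param shape integer vector (depth, height, width), each at least 8 voxels
#' @param n_trees number of vessel root points
#' @param branch_prob per-step bifurcation probability in \code{[0,1]}
#' @param radius_range (min, max) vessel radius in voxels
#' @param lateral_bias fraction in \code{[0,1]} of the step direction
#'   constrained to the en face plane; 1 keeps centerlines at fixed depth
#' @param attenuation_coeff per-voxel exponential decay of signal with depth
#' @param speckle_shape gamma shape parameter (> 0) of the unit-mean
#'   multiplicative speckle; larger is less noisy
#' @param background_level mean of the additive background noise in \code{[0,1)}
#' @param axial_corr axial correlation length of the noise in voxels
#'   (speckle grains are elongated along depth by the imaging point-spread
#'   function, so volumetric noise is not independent per depth voxel);
#'   1 gives independent voxels
#' @param seed integer RNG seed
#' @return a `phantom_config` list
#' @export
phantom_config <- function(shape = c(64, 128, 128), n_trees = 8,
                           branch_prob = 0.03, radius_range = c(1, 2.5),
                           lateral_bias = 0.9, attenuation_coeff = 0.01,
                           speckle_shape = 3, background_level = 0.12,
                           axial_corr = 8, seed = 1L) {
  shape <- as.integer(shape)
  if (length(shape) != 3 || any(shape < 8)) {
    stop("shape must be three values, each >= 8 voxels", call. = FALSE)
  }
  stopifnot(n_trees >= 0, branch_prob >= 0, branch_prob <= 1,
            length(radius_range) == 2, radius_range[1] <= radius_range[2],
            radius_range[1] > 0, lateral_bias >= 0, lateral_bias <= 1,
            attenuation_coeff >= 0, speckle_shape > 0,
            background_level >= 0, background_level < 1, axial_corr >= 1)
  structure(list(shape = shape, n_trees = n_trees, branch_prob = branch_prob,
                 radius_range = radius_range, lateral_bias = lateral_bias,
                 attenuation_coeff = attenuation_coeff,
                 speckle_shape = speckle_shape,
                 background_level = background_level,
                 axial_corr = as.integer(axial_corr),
                 seed = as.integer(seed)), class = "phantom_config")
}

#' Rigid drift parameters for repeated acquisitions
#'
#' @param max_shift translation bound in pixels (>= 0)
#' @param max_rotation rotation bound in degrees (>= 0)
#' @param seed integer RNG seed
#' @return a `drift_params` list
#' @export
drift_params <- function(max_shift = 4, max_rotation = 2, seed = 1L) {
  stopifnot(max_shift >= 0, max_rotation >= 0)
  structure(list(max_shift = max_shift, max_rotation = max_rotation,
                 seed = as.integer(seed)), class = "drift_params")
}

# Precomputed integer voxel offsets of a ball of radius r.
ball_offsets <- function(r) {
  ri <- ceiling(r)
  g <- expand.grid(dz = -ri:ri, dy = -ri:ri, dx = -ri:ri)
  g <- g[g$dz^2 + g$dy^2 + g$dx^2 <= r^2 + 1e-9, , drop = FALSE]
  as.matrix(g)
}

#' Generate a clean (noise-free) vascular phantom volume
#'
#' Vessel centerlines are biased 3D random walks with Bernoulli bifurcation,
#' dilated by a ball of the branch's radius. Voxels on the dilated
#' centerlines carry intensity \code{exp(-attenuation_coeff * (z - 1))};
#' all other voxels are zero.
#'
#' @param config a [phantom_config()]
#' @return list with \code{volume} (3D array, axes z/y/x, values in
#'   \code{[0,1]}) and \code{mask} (logical array, the ground-truth vessel
#'   voxels)
#' @export
generate_clean_volume <- function(config) {
  stopifnot(inherits(config, "phantom_config"))
  d <- config$shape
  volume <- array(0, d)
  mask <- array(FALSE, d)
  if (config$n_trees == 0) return(list(volume = volume, mask = mask))

  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(config$seed)

  max_steps <- ceiling(0.8 * max(d[2], d[3]))
  centers <- list()
  # stack of walkers: each is (position, direction, radius, steps left)
  walkers <- vector("list", 0)
  for (i in seq_len(config$n_trees)) {
    pos <- c(runif(1, d[1] * 0.2, d[1] * 0.8),
             runif(1, 2, d[2] - 1), runif(1, 2, d[3] - 1))
    ang <- runif(1, 0, 2 * pi)
    dir <- c((1 - config$lateral_bias) * rnorm(1, 0, 0.3),
             sin(ang), cos(ang))
    dir <- dir / sqrt(sum(dir^2))
    r <- runif(1, config$radius_range[1], config$radius_range[2])
    walkers[[length(walkers) + 1]] <- list(pos = pos, dir = dir, r = r,
                                           steps = max_steps)
  }
  pts <- matrix(0, 0, 4) # z, y, x, r
  while (length(walkers) > 0) {
    w <- walkers[[length(walkers)]]
    walkers[[length(walkers)]] <- NULL
    for (s in seq_len(w$steps)) {
      p <- w$pos
      if (p[1] < 1 || p[1] > d[1] || p[2] < 1 || p[2] > d[2] ||
          p[3] < 1 || p[3] > d[3]) break
      pts <- rbind(pts, c(p, w$r))
      # perturb direction; damp the axial (z) component by the lateral bias
      dir <- w$dir + rnorm(3, 0, 0.15)
      dir[1] <- dir[1] * (1 - config$lateral_bias)
      dir <- dir / sqrt(sum(dir^2))
      w$dir <- dir
      w$pos <- p + dir
      if (runif(1) < config$branch_prob && length(walkers) < 64) {
        bd <- w$dir + rnorm(3, 0, 0.6)
        bd[1] <- bd[1] * (1 - config$lateral_bias)
        bd <- bd / sqrt(sum(bd^2))
        walkers[[length(walkers) + 1]] <-
          list(pos = w$pos, dir = bd, r = max(w$r * 0.8,
               config$radius_range[1]), steps = ceiling(w$steps / 2))
      }
    }
  }
  if (nrow(pts) > 0) {
    for (r in unique(round(pts[, 4] * 2) / 2)) {
      sel <- pts[round(pts[, 4] * 2) / 2 == r, , drop = FALSE]
      off <- ball_offsets(r)
      ctr <- round(sel[, 1:3, drop = FALSE])
      idx <- do.call(rbind, lapply(seq_len(nrow(off)), function(k) {
        sweep(ctr, 2, off[k, ], "+")
      }))
      keep <- idx[, 1] >= 1 & idx[, 1] <= d[1] &
              idx[, 2] >= 1 & idx[, 2] <= d[2] &
              idx[, 3] >= 1 & idx[, 3] <= d[3]
      idx <- idx[keep, , drop = FALSE]
      if (nrow(idx) > 0) mask[idx] <- TRUE
    }
    zatt <- exp(-config$attenuation_coeff * (seq_len(d[1]) - 1))
    volume <- array(0, d)
    wh <- which(mask)
    z_of <- ((wh - 1) %% d[1]) + 1
    volume[wh] <- zatt[z_of]
  }
  list(volume = volume, mask = mask)
}

#' Corrupt a volume with multiplicative speckle and additive background
#'
#' Returns \code{clip(volume * Gamma(shape, mean 1) + B, 0, 1)} where the
#' gamma field is unit-mean multiplicative speckle and \code{B} is
#' exponential background noise with mean \code{background_level}. For 3D
#' volumes both noise fields are drawn on a coarse depth grid every
#' \code{axial_corr} voxels and linearly interpolated between grid slices,
#' reproducing the axial elongation of speckle grains by the imaging
#' point-spread function; lateral neighbours remain independent. A 2D input
#' (a single C-scan) gets an independent draw per pixel.
#'
#' @param volume 3D array (or 2D matrix) with values in \code{[0,1]}
#' @param config a [phantom_config()] supplying `speckle_shape`,
#'   `background_level` and `axial_corr`
#' @param seed integer RNG seed
#' @return corrupted array, same shape, values in \code{[0,1]}
#' @export
add_speckle <- function(volume, config, seed) {
  stopifnot(inherits(config, "phantom_config"))
  if (!all(is.finite(volume))) stop("volume has non-finite values", call. = FALSE)
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(as.integer(seed))
  k <- config$speckle_shape
  d <- dim(volume)
  if (length(d) == 3 && config$axial_corr > 1) {
    speckle <- axial_field(d, config$axial_corr,
                           function(n) rgamma(n, shape = k, rate = k))
    bg <- if (config$background_level > 0) {
      axial_field(d, config$axial_corr,
                  function(n) rexp(n, rate = 1 / config$background_level))
    } else 0
  } else {
    n <- length(volume)
    speckle <- rgamma(n, shape = k, rate = k)
    bg <- if (config$background_level > 0) {
      rexp(n, rate = 1 / config$background_level)
    } else 0
  }
  out <- volume * speckle + bg
  out[out > 1] <- 1
  out[out < 0] <- 0
  dim(out) <- dim(volume)
  out
}

# Noise field with axial correlation: i.i.d. draws on depth knots every
# `corr` voxels, linear interpolation between knots. Marginal mean is the
# draw distribution's mean everywhere.
axial_field <- function(d, corr, rdraw) {
  knots <- unique(c(seq(1, d[1], by = corr), d[1]))
  field_k <- array(rdraw(length(knots) * d[2] * d[3]),
                   c(length(knots), d[2], d[3]))
  out <- array(0, d)
  for (z in seq_len(d[1])) {
    i <- findInterval(z, knots)
    if (i >= length(knots)) {
      out[z, , ] <- field_k[length(knots), , ]
    } else {
      f <- (z - knots[i]) / (knots[i + 1] - knots[i])
      out[z, , ] <- (1 - f) * field_k[i, , ] + f * field_k[i + 1, , ]
    }
  }
  out
}

# Seed for the k-th repeat's noise, derived from the drift seed.
repeat_noise_seed <- function(seed, k) (as.integer(seed) + 7919L * as.integer(k)) %% .Machine$integer.max

#' Simulate repeated acquisitions of the same tissue
#'
#' Each repeat is the clean volume warped by a random in-plane rigid
#' transform (drawn within the drift bounds, identical for every depth slice)
#' and then corrupted with independent speckle/background noise. The applied
#' transforms are returned so tests can invert them.
#'
#' @param clean clean flow volume (from [generate_clean_volume()])
#' @param n_repeats number of repeats (>= 1)
#' @param drift a [drift_params()]
#' @param config a [phantom_config()] (noise parameters)
#' @return list with \code{volumes} (list of arrays) and \code{transforms}
#'   (list of \code{list(dy, dx, theta_deg)} applied to each repeat)
#' @export
simulate_repeat_acquisitions <- function(clean, n_repeats, drift, config) {
  if (n_repeats < 1) stop("n_repeats must be >= 1", call. = FALSE)
  stopifnot(inherits(drift, "drift_params"), inherits(config, "phantom_config"))
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(drift$seed)
  tf <- lapply(seq_len(n_repeats), function(k) {
    list(dy = runif(1, -drift$max_shift, drift$max_shift),
         dx = runif(1, -drift$max_shift, drift$max_shift),
         theta_deg = runif(1, -drift$max_rotation, drift$max_rotation))
  })
  volumes <- lapply(seq_len(n_repeats), function(k) {
    warped <- warp_volume_rigid(clean, tf[[k]]$dy, tf[[k]]$dx,
                                tf[[k]]$theta_deg, fill = 0)
    add_speckle(warped, config, repeat_noise_seed(drift$seed, k))
  })
  list(volumes = volumes, transforms = tf)
}

#' Generate an avascular noise C-scan
#'
#' A pure background-noise en face slice with no vessel structure, as found
#' at superficial depths above the vascular plexus; used as the noise source
#' C of the training-input synthesis.
#'
#' @param config a [phantom_config()] (uses height/width, noise parameters)
#' @param seed integer RNG seed
#' @return matrix in \code{[0,1]}
#' @export
avascular_cscan <- function(config, seed) {
  stopifnot(inherits(config, "phantom_config"))
  zero <- matrix(0, config$shape[2], config$shape[3])
  add_speckle(zero, config, seed)
}
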