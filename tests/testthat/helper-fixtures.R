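# Shared fixtures, generated in code at test time.

# small phantom config for fast tests
tiny_config <- function(seed = 1, ...) {
  phantom_config(shape = c(16, 48, 48), n_trees = 4, seed = seed, ...)
}

# a speckled vascular en face image with repeatable features
vascular_image <- function(seed = 1, shape = c(16, 96, 96)) {
  cfg <- phantom_config(shape = shape, seed = seed)
  mip(add_speckle(generate_clean_volume(cfg)$volume, cfg, seed + 1000))
}

make_pair <- function(size = 16, seed = 1, tag = "vascular") {
  set.seed(seed)
  structure(list(input = matrix(runif(size^2), size, size),
                 label = matrix(runif(size^2), size, size), tag = tag),
            class = "training_pair")
}

# random blob mask with a few connected structures
random_mask <- function(size = 16, p = 0.3) {
  matrix(runif(size^2) < p, size, size)
}

# shrink a logical mask away from its FALSE border by n 8-neighbour erosions
erode_mask <- function(bg, n = 1) {
  for (k in seq_len(n)) {
    er <- bg
    h <- nrow(bg); w <- ncol(bg)
    for (di in -1:1) for (dj in -1:1) {
      if (di == 0 && dj == 0) next
      sh <- matrix(FALSE, h, w)
      ys <- max(1, 1 + di):min(h, h + di)
      xs <- max(1, 1 + dj):min(w, w + dj)
      sh[ys - di, xs - dj] <- bg[ys, xs]
      er <- er & sh
    }
    bg <- er
  }
  bg
}
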