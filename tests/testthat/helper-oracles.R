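# Independent brute-force oracles. These deliberately avoid the package's
# code paths: explicit scalar loops, exhaustive sweeps, and a
# label-propagation connected-component pass.

oracle_vd <- function(mask) {
  n <- 0L
  for (i in seq_len(nrow(mask))) for (j in seq_len(ncol(mask))) {
    if (mask[i, j]) n <- n + 1L
  }
  n / (nrow(mask) * ncol(mask))
}

oracle_vdi <- function(mask, skel) {
  a <- 0L; s <- 0L
  for (i in seq_len(nrow(mask))) for (j in seq_len(ncol(mask))) {
    if (mask[i, j]) a <- a + 1L
    if (skel[i, j]) s <- s + 1L
  }
  a / s
}

oracle_cnr <- function(img, sig, bg) {
  sv <- c(); bv <- c()
  for (i in seq_len(nrow(img))) for (j in seq_len(ncol(img))) {
    if (sig[i, j]) sv <- c(sv, img[i, j])
    if (bg[i, j]) bv <- c(bv, img[i, j])
  }
  ms <- sum(sv) / length(sv); mb <- sum(bv) / length(bv)
  vs <- sum((sv - ms)^2) / length(sv); vb <- sum((bv - mb)^2) / length(bv)
  (ms - mb) / sqrt(vs + vb)
}

# 8-connected component sizes by iterative min-label propagation (a
# different algorithm from the package's flood fill).
oracle_components <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  lab <- matrix(seq_len(h * w), h, w)
  lab[!mask] <- 0L
  repeat {
    changed <- FALSE
    for (i in seq_len(h)) for (j in seq_len(w)) {
      if (!mask[i, j]) next
      for (di in -1:1) for (dj in -1:1) {
        ii <- i + di; jj <- j + dj
        if (ii >= 1 && ii <= h && jj >= 1 && jj <= w && mask[ii, jj] &&
            lab[ii, jj] < lab[i, j]) {
          lab[i, j] <- lab[ii, jj]; changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  as.integer(table(lab[mask]))
}

oracle_vc <- function(skel, min_length = 5) {
  sizes <- oracle_components(skel)
  sum(sizes[sizes >= min_length]) / sum(sizes)
}

# exhaustive Otsu: threshold on a 256-bin grid maximizing between-class
# variance
oracle_otsu <- function(img, levels = 256) {
  best_t <- NA; best_v <- -Inf
  for (k in seq_len(levels - 1)) {
    th <- k / levels
    a <- img[img <= th]; b <- img[img > th]
    if (length(a) == 0 || length(b) == 0) next
    wv <- length(a) * length(b) / length(img)^2 * (mean(a) - mean(b))^2
    if (wv > best_v) { best_v <- wv; best_t <- th }
  }
  best_t
}

# brute-force MIP by triple loop
oracle_mip <- function(volume, z0, z1) {
  d <- dim(volume)
  out <- matrix(-Inf, d[2], d[3])
  for (z in z0:z1) for (y in seq_len(d[2])) for (x in seq_len(d[3])) {
    if (volume[z, y, x] > out[y, x]) out[y, x] <- volume[z, y, x]
  }
  out
}

# central-difference numerical gradient
num_grad <- function(f, x, eps = 1e-6) {
  g <- x * 0
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    g[i] <- (f(xp) - f(xm)) / (2 * eps)
  }
  g
}
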