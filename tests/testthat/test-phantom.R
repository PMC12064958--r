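test_that("clean volume generation honours the vessel-free and degenerate cases", {
  cfg <- tiny_config()
  cfg0 <- cfg; cfg0$n_trees <- 0L
  out <- generate_clean_volume(cfg0)
  expect_true(all(out$volume == 0))
  expect_false(any(out$mask))
  expect_error(phantom_config(shape = c(4, 64, 64)), "8")
  expect_error(phantom_config(radius_range = c(3, 1)))
})

test_that("phantom generation is a pure function of config and seed", {
  cfg <- tiny_config(seed = 7)
  a <- generate_clean_volume(cfg)
  b <- generate_clean_volume(cfg)
  expect_identical(a, b)
  s1 <- add_speckle(a$volume, cfg, 11)
  s2 <- add_speckle(a$volume, cfg, 11)
  expect_identical(s1, s2)
  expect_false(identical(s1, add_speckle(a$volume, cfg, 12)))
  expect_identical(avascular_cscan(cfg, 3), avascular_cscan(cfg, 3))
})

test_that("vessel intensity follows exponential depth attenuation", {
  cfg <- tiny_config(seed = 3)
  cfg$attenuation_coeff <- 0
  out <- generate_clean_volume(cfg)
  expect_gt(sum(out$mask), 0)
  expect_true(all(out$volume[out$mask] == 1))
  cfg$attenuation_coeff <- 0.05
  out <- generate_clean_volume(cfg)
  idx <- which(out$mask, arr.ind = TRUE)
  expect_equal(out$volume[out$mask],
               exp(-0.05 * (idx[, 1] - 1)), tolerance = 1e-12)
})

test_that("speckle vanishes in the large-shape limit and respects clipping", {
  cfg <- tiny_config(seed = 5)
  clean <- generate_clean_volume(cfg)$volume
  cfg_lim <- cfg; cfg_lim$speckle_shape <- 1e6; cfg_lim$background_level <- 0
  out <- add_speckle(clean, cfg_lim, 2)
  expect_lt(max(abs(out - clean)), 0.01 * max(clean))
  zero <- array(0, cfg$shape)
  cfg0 <- cfg; cfg0$background_level <- 0
  expect_true(all(add_speckle(zero, cfg0, 9) == 0))
  for (s in 1:3) {
    out <- add_speckle(clean, cfg, s)
    expect_true(all(out >= 0 & out <= 1))
  }
  bad <- clean; bad[1] <- NaN
  expect_error(add_speckle(bad, cfg, 1), "finite")
})

test_that("vessel fraction grows with tree count and signal exceeds background", {
  fr <- sapply(c(2, 6, 12), function(nt) {
    cfg <- phantom_config(shape = c(16, 48, 48), n_trees = nt, seed = 21)
    mean(generate_clean_volume(cfg)$mask)
  })
  expect_true(all(diff(fr) >= 0))
  for (s in 1:3) {
    cfg <- tiny_config(seed = s)
    cl <- generate_clean_volume(cfg)
    sp <- add_speckle(cl$volume, cfg, s + 50)
    expect_gt(mean(sp[cl$mask]), mean(sp[!cl$mask]))
  }
})

test_that("avascular C-scans carry only background noise at the configured level", {
  cfg <- phantom_config(shape = c(16, 96, 96), background_level = 0.12)
  for (s in 1:10) {
    img <- avascular_cscan(cfg, s)
    se <- sd(img) / sqrt(length(img))
    expect_lt(abs(mean(img) - 0.12), 3 * se)
  }
  cfg0 <- cfg; cfg0$background_level <- 0; cfg0$speckle_shape <- 1e9
  expect_true(all(avascular_cscan(cfg0, 1) == 0))
})

test_that("repeat acquisitions reproduce the no-drift identity and are independent", {
  cfg <- tiny_config(seed = 2)
  clean <- generate_clean_volume(cfg)$volume
  dr0 <- drift_params(0, 0, seed = 31)
  one <- simulate_repeat_acquisitions(clean, 1, dr0, cfg)
  expect_equal(one$volumes[[1]],
               add_speckle(clean, cfg, octa3d:::repeat_noise_seed(31, 1)))
  expect_error(simulate_repeat_acquisitions(clean, 0, dr0, cfg), "n_repeats")
  dr <- drift_params(3, 1.5, seed = 31)
  ten <- simulate_repeat_acquisitions(clean, 10, dr, cfg)
  expect_length(ten$volumes, 10)
  for (k in 2:10) expect_false(identical(ten$volumes[[1]], ten$volumes[[k]]))
})

test_that("applied drift transforms invert to realign the warped volume", {
  # smooth volume so that the double interpolation error stays small
  cfg <- phantom_config(shape = c(8, 64, 64), seed = 4)
  base <- generate_clean_volume(cfg)$volume
  smooth <- base
  for (z in 1:8) smooth[z, , ] <- as.matrix(EBImage::gblur(base[z, , ], sigma = 2))
  dr <- drift_params(3, 2, seed = 77)
  reps <- simulate_repeat_acquisitions(smooth, 3, dr, cfg)
  for (k in 1:3) {
    tf <- reps$transforms[[k]]
    warped <- octa3d:::warp_volume_rigid(smooth, tf$dy, tf$dx, tf$theta_deg)
    # inverse of (rotate theta about centre, then shift): complex algebra
    q <- exp(-1i * tf$theta_deg * pi / 180)
    tc <- complex(real = tf$dx, imaginary = tf$dy)
    ti <- -tc / q
    undone <- octa3d:::warp_volume_rigid(warped, Im(ti), Re(ti), -tf$theta_deg)
    core <- 9:56
    expect_lt(mean(abs(undone[, core, core] - smooth[, core, core])), 0.01)
  }
})
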