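# The strided conv / transposed conv / instance-norm building blocks carry
# hand-derived backward passes; these tests pin them against central-
# difference numerical gradients on tiny tensors.

test_that("convolution forward/backward agree with numerical gradients", {
  set.seed(42)
  cf <- octa3d:::conv_forward; cb <- octa3d:::conv_backward
  x <- array(rnorm(6 * 6 * 2), c(6, 6, 2))
  W <- matrix(rnorm(32 * 3, 0, 0.1), 32, 3); b <- rnorm(3)
  loss <- function(y) sum(sin(y))
  fw <- cf(x, W, b, 4, 2, 1)
  expect_equal(dim(fw$y), c(3, 3, 3))
  bk <- cb(array(cos(fw$y), dim(fw$y)), W, fw$cache)
  gx <- num_grad(function(v) loss(cf(array(v, dim(x)), W, b, 4, 2, 1)$y),
                 as.vector(x))
  expect_lt(max(abs(gx - as.vector(bk$dx))), 1e-6)
  gW <- num_grad(function(v) loss(cf(x, matrix(v, 32), b, 4, 2, 1)$y),
                 as.vector(W))
  expect_lt(max(abs(gW - as.vector(bk$dW))), 1e-6)
  gb <- num_grad(function(v) loss(cf(x, W, v, 4, 2, 1)$y), b)
  expect_lt(max(abs(gb - bk$db)), 1e-6)
})

test_that("transposed convolution doubles the plane and backprops exactly", {
  set.seed(43)
  tf <- octa3d:::tconv_forward; tb <- octa3d:::tconv_backward
  x <- array(rnorm(3 * 3 * 3), c(3, 3, 3))
  W <- matrix(rnorm(32 * 3, 0, 0.1), 32, 3); b <- rnorm(2)
  loss <- function(y) sum(sin(y))
  fw <- tf(x, W, b, 4, 2, 1)
  expect_equal(dim(fw$y), c(6, 6, 2))
  bk <- tb(array(cos(fw$y), dim(fw$y)), W, fw$cache)
  gx <- num_grad(function(v) loss(tf(array(v, dim(x)), W, b, 4, 2, 1)$y),
                 as.vector(x))
  expect_lt(max(abs(gx - as.vector(bk$dx))), 1e-6)
  gW <- num_grad(function(v) loss(tf(x, matrix(v, 32), b, 4, 2, 1)$y),
                 as.vector(W))
  expect_lt(max(abs(gW - as.vector(bk$dW))), 1e-6)
})

test_that("instance normalization backprops through its own statistics", {
  set.seed(44)
  inf <- octa3d:::instnorm_forward; inb <- octa3d:::instnorm_backward
  x <- array(rnorm(4 * 4 * 2), c(4, 4, 2))
  g <- runif(2, 0.5, 1.5); be <- rnorm(2)
  loss <- function(y) sum(sin(y))
  fw <- inf(x, g, be, numeric(2), rep(1, 2), TRUE)
  bk <- inb(array(cos(fw$y), dim(fw$y)), g, fw$cache)
  gx <- num_grad(function(v)
    loss(inf(array(v, dim(x)), g, be, numeric(2), rep(1, 2), TRUE)$y),
    as.vector(x))
  expect_lt(max(abs(gx - as.vector(bk$dx))), 1e-6)
  gg <- num_grad(function(v)
    loss(inf(x, v, be, numeric(2), rep(1, 2), TRUE)$y), g)
  expect_lt(max(abs(gg - bk$dgamma)), 1e-6)
})

test_that("generator backward matches numerical gradients end to end", {
  gen <- build_generator(n_levels = 3, base_channels = 3, max_channels = 6,
                         seed = 2)
  set.seed(45)
  x <- matrix(runif(64), 8, 8)
  gf <- generator_forward(gen, x, train = TRUE)
  gr <- octa3d:::generator_backward(gf$gen, gf$caches, 3 * cos(3 * gf$y))
  for (side in c("enc", "dec")) for (bi in c(1, 3)) {
    W <- gf$gen[[side]][[bi]]$W
    idx <- sample(length(W), 4)
    gn <- sapply(idx, function(i) {
      f <- function(v) {
        g2 <- gf$gen; g2[[side]][[bi]]$W[i] <- v
        sum(sin(3 * generator_forward(g2, x, train = TRUE)$y))
      }
      (f(W[i] + 1e-6) - f(W[i] - 1e-6)) / 2e-6
    })
    expect_lt(max(abs(gn - gr[[side]][[bi]]$W[idx])), 1e-5)
  }
})

test_that("discriminator backward matches numerical gradients including the input", {
  disc <- build_discriminator(n_mid = 1, base_channels = 3, max_channels = 6,
                              seed = 3)
  set.seed(46)
  xi <- matrix(runif(16 * 16) * 2 - 1, 16, 16)
  df <- discriminator_forward(disc, xi, train = TRUE)
  bk <- octa3d:::discriminator_backward(df$disc, df$caches, df$raw, 1)
  for (bi in 1:3) {
    W <- df$disc$blocks[[bi]]$W
    idx <- sample(length(W), 4)
    gn <- sapply(idx, function(i) {
      f <- function(v) {
        d2 <- df$disc; d2$blocks[[bi]]$W[i] <- v
        discriminator_forward(d2, xi, train = TRUE)$p
      }
      (f(W[i] + 1e-6) - f(W[i] - 1e-6)) / 2e-6
    })
    expect_lt(max(abs(gn - bk$grads[[bi]]$W[idx])), 1e-6)
  }
  idx <- sample(length(xi), 6)
  gn <- sapply(idx, function(i) {
    f <- function(v) {
      x2 <- xi; x2[i] <- v
      discriminator_forward(df$disc, x2, train = TRUE)$p
    }
    (f(xi[i] + 1e-6) - f(xi[i] - 1e-6)) / 2e-6
  })
  expect_lt(max(abs(gn - as.vector(bk$dx)[idx])), 1e-6)
})

test_that("the generator preserves shape across valid sizes and rejects others", {
  for (sz in c(16, 32, 64)) {
    lv <- as.integer(log2(sz))
    gen <- build_generator(n_levels = lv, base_channels = 4, max_channels = 8,
                           seed = 1)
    y <- generator_forward(gen, matrix(runif(sz^2), sz, sz))
    expect_equal(dim(y), c(sz, sz))
    expect_true(all(y >= 0 & y <= 1))
  }
  gen <- build_generator(n_levels = 4, base_channels = 4, seed = 1)
  expect_error(generator_forward(gen, matrix(0.5, 24, 24)), "divisible")
})

test_that("the discriminator emits a probability and rejects too-small inputs", {
  disc <- build_discriminator(n_mid = 2, base_channels = 4, max_channels = 8,
                              seed = 5)
  p1 <- discriminator_forward(disc, matrix(runif(32 * 32), 32, 32))
  expect_true(p1 > 0 && p1 < 1)
  a <- matrix(0.1, 32, 32); b <- matrix(0.9, 32, 32)
  expect_false(discriminator_forward(disc, a) == discriminator_forward(disc, b))
  expect_error(discriminator_forward(disc, matrix(0.5, 8, 8)), "small")
})
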