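test_that("input synthesis matches the worked weighted-overlay example", {
  E <- matrix(c(0, 0.5, 1, 0), 2, 2, byrow = TRUE)
  C <- matrix(c(1, 0, 0, 0), 2, 2, byrow = TRUE)
  S <- synthesize_input(E, C, synthesis_weights(0.25, 0.75))
  expect_equal(S, matrix(c(1, 1 / 6, 1 / 3, 0), 2, 2, byrow = TRUE),
               tolerance = 1e-12)
})

test_that("synthesis normalizes to [0,1] and handles identity and degenerate cases", {
  set.seed(3)
  E <- matrix(runif(64), 8, 8); E[1] <- 0; E[64] <- 1
  C <- matrix(runif(64), 8, 8)
  expect_equal(synthesize_input(E, C, synthesis_weights(1, 0)), E)
  expect_true(all(synthesize_input(matrix(0.4, 4, 4), matrix(0.7, 4, 4),
                                   synthesis_weights()) == 0))
  S <- synthesize_input(E, C, synthesis_weights(0.3, 0.6))
  expect_equal(range(S), c(0, 1))
  expect_error(synthesize_input(E, matrix(0, 4, 4)), "shape")
  expect_error(synthesis_weights(0, 0))
})

test_that("min-max normalization makes the weights scale-free", {
  set.seed(5)
  for (i in 1:25) {
    E <- matrix(runif(36), 6, 6); C <- matrix(runif(36), 6, 6)
    a <- runif(1); b <- runif(1, 0.1, 1); k <- runif(1, 0.1, 10)
    expect_equal(synthesize_input(E, C, synthesis_weights(a, b)),
                 synthesize_input(E, C, synthesis_weights(k * a, k * b)),
                 tolerance = 1e-9)
  }
})

test_that("training-set assembly appends the stated noise-only and black pairs", {
  pairs <- lapply(1:350, function(i) list(E = matrix(runif(16), 4, 4),
                                          label = matrix(runif(16), 4, 4)))
  noise <- lapply(1:5, function(i) matrix(runif(16), 4, 4))
  ts <- build_training_set(pairs, noise, seed = 2)
  expect_length(ts, 390)
  expect_equal(sum(sapply(ts, `[[`, "tag") == "vascular"), 350)
  expect_equal(sum(sapply(ts, `[[`, "tag") == "noise_only"), 20)
  expect_equal(sum(sapply(ts, `[[`, "tag") == "black"), 20)
  for (p in ts[sapply(ts, `[[`, "tag") == "black"]) {
    expect_true(all(p$input == 0) && all(p$label == 0))
  }
  for (p in ts[sapply(ts, `[[`, "tag") == "noise_only"]) {
    expect_true(all(p$label == 0))
  }
  ts0 <- build_training_set(pairs[1:3], noise, n_noise_only = 0, n_black = 0)
  expect_length(ts0, 3)
  expect_true(all(sapply(ts0, `[[`, "tag") == "vascular"))
  expect_error(build_training_set(pairs[1:2], list(), n_noise_only = 2),
               "noise")
  expect_identical(build_training_set(pairs[1:5], noise, seed = 9),
                   build_training_set(pairs[1:5], noise, seed = 9))
})

test_that("the train/test partition is disjoint and honours 350/50 at n = 400", {
  sp <- split_train_test(400, seed = 1)
  expect_length(sp$train, 350)
  expect_length(sp$test, 50)
  expect_length(intersect(sp$train, sp$test), 0)
  expect_setequal(c(sp$train, sp$test), 1:400)
})

test_that("augmentation keeps input and label pixel-aligned", {
  img <- vascular_image(seed = 3, shape = c(8, 64, 64))
  p <- structure(list(input = img, label = img, tag = "vascular"),
                 class = "training_pair")
  for (s in c(2, 9, 17, 23)) {
    a <- augment(p, s)
    expect_identical(a$input, a$label)
    expect_equal(dim(a$input), dim(img))
  }
  # marker tracking: a bright dot at one position stays co-located
  m <- matrix(0, 64, 64); m[40, 12] <- 1
  pm <- structure(list(input = m, label = m, tag = "vascular"),
                  class = "training_pair")
  for (s in c(2, 9, 17)) {
    a <- augment(pm, s)
    expect_equal(which.max(a$input), which.max(a$label))
  }
})

test_that("augmentation identity draw and rotation group behave as expected", {
  img <- vascular_image(seed = 5, shape = c(8, 64, 64))
  p <- structure(list(input = img, label = img, tag = "vascular"),
                 class = "training_pair")
  a <- augment(p, 34)   # draw with 0-degree rotation and full crop
  expect_identical(a$input, p$input)
  r <- octa3d:::rot90k
  expect_identical(r(r(r(r(img, 1), 1), 1), 1), img)
  expect_identical(r(img, 4), img)
  expect_error(augment(structure(list(input = matrix(0, 4, 8),
                                      label = matrix(0, 4, 8), tag = "x"),
                                 class = "training_pair"), 1), "square")
})
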