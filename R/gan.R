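#' Adversarial enhancement model
#'
#' A Pix2Pix-style pair of networks. The generator is U-shaped: an encoder
#' of 4x4 / stride-2 / pad-1 convolution blocks (instance-normalized, leaky
#' ReLU) down to a 1x1 bottleneck, mirrored by transposed-convolution blocks
#' (normalized, ReLU) with skip connections between mirror levels, and a
#' tanh output head. The discriminator is a strided convolutional stack
#' ending in a 4x4 / stride-2 / pad-0 convolution and a sigmoid that emits
#' the probability of its input being a real (high-quality) image; per the
#' printed loss terms it sees only the label or the generated image, never
#' the degraded input. Training alternates one discriminator and one
#' generator Adam step per sample (batch size 1), with the generator loss
#' \deqn{G_{loss} = \lambda \cdot Content + Adversarial}
#' combining the mean absolute error to the label with
#' \eqn{E[\log(1 - D(G(x)))]}, and the discriminator trained with binary
#' cross-entropy.
#'
#' @name gan_model
NULL

LOG_EPS <- 1e-7

clamp_prob <- function(p) pmin(pmax(p, LOG_EPS), 1 - LOG_EPS)

#' Build a U-shaped generator
#'
#' @param n_levels encoder/decoder depth; the input spatial size must be
#'   divisible by \code{2^n_levels} (8 gives a 1x1 bottleneck at 256x256)
#' @param base_channels channels after the first convolution
#' @param max_channels cap on the channel progression (doubling per level)
#' @param seed seed for weight initialization (N(0, 0.02))
#' @return an \code{octa_generator} object
#' @export
build_generator <- function(n_levels = 8, base_channels = 64,
                            max_channels = 512, seed = 1L) {
  stopifnot(n_levels >= 1, base_channels >= 1)
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(as.integer(seed))
  ch <- pmin(base_channels * 2^(seq_len(n_levels) - 1), max_channels)
  enc <- vector("list", n_levels)
  for (i in seq_len(n_levels)) {
    cin <- if (i == 1) 1L else ch[i - 1]
    # first block has no normalization (Pix2Pix convention); inner blocks
    # skip it automatically on 1x1 maps
    enc[[i]] <- new_block("conv", cin, ch[i], act = "lrelu",
                          use_bn = (i > 1))
  }
  dec <- vector("list", n_levels)
  for (j in seq_len(n_levels)) {
    cin <- if (j == 1) ch[n_levels] else
      dec[[j - 1]]$cout + ch[n_levels - j + 1]
    cout <- if (j == n_levels) 1L else ch[n_levels - j]
    dec[[j]] <- new_block("tconv", cin, cout,
                          act = if (j == n_levels) "tanh" else "relu",
                          use_bn = (j < n_levels))
  }
  structure(list(n_levels = n_levels, base_channels = base_channels,
                 max_channels = max_channels, channels = ch,
                 enc = enc, dec = dec),
            class = "octa_generator")
}

#' Run the generator on an en face image
#'
#' Values in \code{[0,1]} are mapped to the tanh range \code{[-1,1]} at the
#' boundary and back on return; the output has the input's shape.
#'
#' @param gen an \code{octa_generator}
#' @param image matrix in \code{[0,1]}, both sides divisible by
#'   \code{2^n_levels}
#' @param train logical; TRUE caches intermediates for backpropagation and
#'   updates normalization running statistics
#' @return with \code{train = FALSE} (default) the enhanced image; with
#'   \code{train = TRUE} a list \code{(y, caches, gen)}
#' @export
generator_forward <- function(gen, image, train = FALSE) {
  h <- nrow(image); w <- ncol(image)
  div <- 2^gen$n_levels
  if (h %% div != 0 || w %% div != 0) {
    stop(sprintf("input size %dx%d not divisible by 2^n_levels = %d",
                 h, w, div), call. = FALSE)
  }
  x <- array(2 * image - 1, c(h, w, 1))
  L <- gen$n_levels
  enc_out <- vector("list", L)
  caches <- list(enc = vector("list", L), dec = vector("list", L))
  cur <- x
  for (i in seq_len(L)) {
    bf <- block_forward(gen$enc[[i]], cur, train)
    gen$enc[[i]] <- bf$blk
    caches$enc[[i]] <- bf$cache
    enc_out[[i]] <- bf$y
    cur <- bf$y
  }
  for (j in seq_len(L)) {
    if (j > 1) {
      skip <- enc_out[[L - j + 1]]
      d1 <- dim(cur); d2 <- dim(skip)
      cur <- array(c(cur, skip), c(d1[1], d1[2], d1[3] + d2[3]))
    }
    bf <- block_forward(gen$dec[[j]], cur, train)
    gen$dec[[j]] <- bf$blk
    caches$dec[[j]] <- bf$cache
    cur <- bf$y
  }
  y <- (matrix(cur, h, w) + 1) / 2
  if (!train) return(y)
  list(y = y, caches = caches, gen = gen)
}

# Backward pass through the generator. dy is the loss gradient w.r.t. the
# [0,1] output image; returns grads structured as list(enc = ..., dec = ...).
generator_backward <- function(gen, caches, dy) {
  h <- nrow(dy); w <- ncol(dy)
  L <- gen$n_levels
  dcur <- array(dy * 0.5, c(h, w, 1))  # d[0,1]/d tanh-range = 1/2
  enc_grads <- vector("list", L)
  dec_grads <- vector("list", L)
  denc_out <- vector("list", L)        # accumulated skip gradients
  for (j in rev(seq_len(L))) {
    bb <- block_backward(gen$dec[[j]], caches$dec[[j]], dcur)
    dec_grads[[j]] <- bb$grads
    dxin <- bb$dx
    if (j > 1) {
      nskip <- dim(caches$enc[[L - j + 1]]$post_act)[3]
      ncur <- dim(dxin)[3] - nskip
      denc_out[[L - j + 1]] <- dxin[, , (ncur + 1):(ncur + nskip), drop = FALSE]
      dcur <- dxin[, , seq_len(ncur), drop = FALSE]
    } else {
      dcur <- dxin
    }
  }
  # dcur now flows into enc_out[[L]]
  denc_out[[L]] <- if (is.null(denc_out[[L]])) dcur else denc_out[[L]] + dcur
  dnext <- NULL
  for (i in rev(seq_len(L))) {
    d <- denc_out[[i]]
    if (!is.null(dnext)) d <- d + dnext
    bb <- block_backward(gen$enc[[i]], caches$enc[[i]], d)
    enc_grads[[i]] <- bb$grads
    dnext <- NULL
    if (i > 1) {
      dnext <- NULL
      denc_out[[i - 1]] <- if (is.null(denc_out[[i - 1]])) bb$dx
                           else denc_out[[i - 1]] + bb$dx
    }
  }
  list(enc = enc_grads, dec = dec_grads)
}

#' Build the discriminator
#'
#' One 4x4/stride-2/pad-1 convolution with leaky ReLU, `n_mid` normalized
#' convolution blocks of the same geometry, then a final 4x4/stride-2/pad-0
#' convolution and a sigmoid. With the default five middle blocks a 256x256
#' input reduces to a single 1x1 probability.
#'
#' @param n_mid number of middle blocks (default 5); a valid input size is
#'   \code{2^(n_mid + 3)}
#' @param base_channels channels after the first convolution
#' @param max_channels channel cap
#' @param seed weight-init seed
#' @return an \code{octa_discriminator} object
#' @export
build_discriminator <- function(n_mid = 5, base_channels = 64,
                                max_channels = 512, seed = 1L) {
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(as.integer(seed))
  ch <- pmin(base_channels * 2^(0:n_mid), max_channels)
  blocks <- vector("list", n_mid + 2)
  blocks[[1]] <- new_block("conv", 1L, ch[1], act = "lrelu", use_bn = FALSE)
  for (i in seq_len(n_mid)) {
    blocks[[i + 1]] <- new_block("conv", ch[i], ch[i + 1], act = "lrelu",
                                 use_bn = TRUE)
  }
  blocks[[n_mid + 2]] <- new_block("conv", ch[n_mid + 1], 1L, act = "sigmoid",
                                   use_bn = FALSE)
  structure(list(n_mid = n_mid, blocks = blocks), class = "octa_discriminator")
}

#' Run the discriminator on an image
#'
#' @param disc an \code{octa_discriminator}
#' @param image matrix in the tanh range \code{[-1,1]} (labels are mapped by
#'   the training loop) or \code{[0,1]} images for standalone use
#' @param train logical; cache intermediates for backpropagation
#' @return with \code{train = FALSE} the scalar probability in (0,1); else a
#'   list \code{(p, caches, disc)}
#' @export
discriminator_forward <- function(disc, image, train = FALSE) {
  x <- array(image, c(nrow(image), ncol(image), 1))
  n <- length(disc$blocks)
  caches <- vector("list", n)
  for (i in seq_len(n)) {
    last <- i == n
    if (last && (dim(x)[1] < 4 || dim(x)[2] < 4)) {
      stop(sprintf("input too small: %dx%d reaching the final 4x4 layer ",
                   dim(x)[1], dim(x)[2]), call. = FALSE)
    }
    bf <- block_forward(disc$blocks[[i]], x, train,
                        pad = if (last) 0L else 1L)
    disc$blocks[[i]] <- bf$blk
    caches[[i]] <- bf$cache
    x <- bf$y
  }
  p <- mean(x)  # 1x1 map for the designed sizes; mean pools larger inputs
  if (!train) return(clamp_prob(p))
  list(p = clamp_prob(p), raw = x, caches = caches, disc = disc)
}

# Backward through the discriminator given dL/dp; returns grads per block
# and the gradient w.r.t. the input image (for the generator's adversarial
# term).
discriminator_backward <- function(disc, caches, raw, dp) {
  dcur <- array(dp / length(raw), dim(raw))
  n <- length(disc$blocks)
  grads <- vector("list", n)
  for (i in rev(seq_len(n))) {
    bb <- block_backward(disc$blocks[[i]], caches[[i]], dcur)
    grads[[i]] <- bb$grads
    dcur <- bb$dx
  }
  list(grads = grads, dx = matrix(dcur, dim(dcur)[1], dim(dcur)[2]))
}

# --- losses ----------------------------------------------------------------

#' L1 content loss
#'
#' Mean absolute difference between the label and the generated image,
#' \eqn{\frac{1}{hw}\sum_{i,j} |I_{label} - G(I_{input})|}.
#'
#' @param label,pred same-shape matrices
#' @return scalar
#' @export
content_loss <- function(label, pred) {
  if (!identical(dim(label), dim(pred))) {
    stop("label and prediction must share one shape", call. = FALSE)
  }
  mean(abs(label - pred))
}

#' Adversarial generator loss
#'
#' \eqn{E[\log(1 - D(G(I_{input})))]}, minimized by the generator (driving
#' \eqn{D(G) \to 1}); probabilities are clamped away from 0/1 by 1e-7.
#'
#' @param d_on_generated discriminator probability (or vector of them) on
#'   generated images
#' @return scalar
#' @export
adversarial_loss <- function(d_on_generated) {
  mean(log(1 - clamp_prob(d_on_generated)))
}

#' Total generator loss
#'
#' \eqn{G_{loss} = \lambda \cdot Content + Adversarial}.
#'
#' @param content content (L1) loss
#' @param adversarial adversarial loss
#' @param lambda_content weight of the content term (default 1000)
#' @return scalar
#' @export
generator_loss <- function(content, adversarial, lambda_content = 1000) {
  lambda_content * content + adversarial
}

#' Discriminator binary cross-entropy loss
#'
#' \eqn{-E[\log D(I_{label})] - E[\log(1 - D(G(I_{input})))]}.
#'
#' @param d_on_label probability on real label images
#' @param d_on_generated probability on generated images
#' @return scalar
#' @export
discriminator_loss <- function(d_on_label, d_on_generated) {
  -mean(log(clamp_prob(d_on_label))) - mean(log(1 - clamp_prob(d_on_generated)))
}

#' Training configuration
#'
#' @param learning_rate Adam learning rate (default 1e-3)
#' @param epochs number of epochs (default 120)
#' @param lambda_content content-loss weight (default 1000)
#' @param beta1,beta2 Adam moment decays (default 0.5, 0.999)
#' @param batch_size fixed at 1; present for the record
#' @param seed root seed for weight init, shuffling and augmentation
#' @param augment_each_epoch rotate/crop pairs anew every epoch
#' @param checkpoint_every write a checkpoint every this many epochs (0 = off)
#' @param checkpoint_dir directory for checkpoints
#' @return a `train_config` list
#' @export
train_config <- function(learning_rate = 1e-3, epochs = 120,
                         lambda_content = 1000, beta1 = 0.5, beta2 = 0.999,
                         batch_size = 1, seed = 1L,
                         augment_each_epoch = TRUE,
                         checkpoint_every = 0, checkpoint_dir = NULL) {
  stopifnot(learning_rate > 0, epochs >= 1, lambda_content >= 0,
            batch_size == 1)
  structure(list(learning_rate = learning_rate, epochs = as.integer(epochs),
                 lambda_content = lambda_content, beta1 = beta1, beta2 = beta2,
                 batch_size = 1L, seed = as.integer(seed),
                 augment_each_epoch = augment_each_epoch,
                 checkpoint_every = as.integer(checkpoint_every),
                 checkpoint_dir = checkpoint_dir), class = "train_config")
}

aug_seed <- function(seed, epoch, idx) {
  (as.double(seed) * 7 + 104729 * epoch + 31 * idx) %% 2147483647
}

#' Train the adversarial enhancement model
#'
#' Alternates one discriminator update (binary cross-entropy on a real
#' label and the current generated image) and one generator update
#' (\eqn{\lambda} L1 + adversarial) per training pair at batch size 1,
#' optionally re-augmenting every pair each epoch. Fully deterministic for
#' a fixed seed on CPU.
#'
#' @param dataset nonempty list of \code{training_pair}s (square images,
#'   sides divisible by \code{2^n_levels})
#' @param config a [train_config()]
#' @param generator optionally a pre-built [build_generator()] (e.g. when
#'   resuming); sized to the data otherwise
#' @param discriminator optional pre-built [build_discriminator()]
#' @param base_channels width of the networks when they are built here
#' @param n_levels generator depth when built here; the default fits the
#'   image size exactly (1x1 bottleneck)
#' @param resume_from path to a checkpoint written by a previous run
#' @param verbose print per-epoch losses
#' @return list with \code{generator}, \code{discriminator}, \code{epochs}
#'   (per-epoch mean losses, a data.frame), and \code{steps} (per-step
#'   \code{g_loss}, \code{content_loss}, \code{adversarial_loss},
#'   \code{d_loss})
#' @export
train_gan <- function(dataset, config = train_config(), generator = NULL,
                      discriminator = NULL, base_channels = 16,
                      n_levels = NULL, resume_from = NULL, verbose = FALSE) {
  stopifnot(length(dataset) >= 1, inherits(config, "train_config"))
  size <- nrow(dataset[[1]]$input)
  if (is.null(n_levels)) n_levels <- as.integer(round(log2(size)))
  start_epoch <- 1L
  steps <- NULL; epochs_log <- NULL
  adam_g <- adam_init(); adam_d <- adam_init()
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  if (!is.null(resume_from)) {
    ck <- readRDS(resume_from)
    generator <- ck$generator; discriminator <- ck$discriminator
    adam_g <- ck$adam_g; adam_d <- ck$adam_d
    start_epoch <- ck$epoch + 1L
    steps <- ck$steps; epochs_log <- ck$epochs
    assign(".Random.seed", ck$rng, .GlobalEnv)
  } else {
    set.seed(config$seed)
    if (is.null(generator)) {
      generator <- build_generator(n_levels, base_channels,
                                   max_channels = base_channels * 4,
                                   seed = config$seed)
    }
    if (is.null(discriminator)) {
      n_mid <- as.integer(round(log2(size)) - 3)
      discriminator <- build_discriminator(n_mid, base_channels,
                                           max_channels = base_channels * 4,
                                           seed = config$seed + 1L)
    }
  }
  lam <- config$lambda_content
  n <- length(dataset)
  for (epoch in start_epoch:config$epochs) {
    order <- sample.int(n)
    ep_mat <- matrix(0, n, 4)
    for (step_i in seq_along(order)) {
      idx <- order[step_i]
      pair <- dataset[[idx]]
      if (config$augment_each_epoch) {
        pair <- augment(pair, aug_seed(config$seed, epoch, idx))
      }
      x <- pair$input; label <- pair$label
      label_t <- 2 * label - 1

      gf <- generator_forward(generator, x, train = TRUE)
      generator <- gf$gen
      y01 <- gf$y
      y_t <- 2 * y01 - 1

      # -- discriminator step -------------------------------------------
      dfr <- discriminator_forward(discriminator, label_t, train = TRUE)
      discriminator <- dfr$disc
      dff <- discriminator_forward(discriminator, y_t, train = TRUE)
      discriminator <- dff$disc
      d_loss <- discriminator_loss(dfr$p, dff$p)
      gr_r <- discriminator_backward(discriminator, dfr$caches, dfr$raw,
                                     -1 / dfr$p)
      gr_f <- discriminator_backward(discriminator, dff$caches, dff$raw,
                                     1 / (1 - dff$p))
      d_grads <- mapply(function(a, b) {
        list(W = a$W + b$W, b = a$b + b$b, gamma = a$gamma + b$gamma,
             beta = a$beta + b$beta)
      }, gr_r$grads, gr_f$grads, SIMPLIFY = FALSE)
      upd <- adam_step(discriminator$blocks, d_grads, adam_d,
                       config$learning_rate, config$beta1, config$beta2)
      discriminator$blocks <- upd$blocks; adam_d <- upd$state

      # -- generator step -----------------------------------------------
      dfg <- discriminator_forward(discriminator, y_t, train = TRUE)
      discriminator <- dfg$disc
      c_loss <- content_loss(label, y01)
      a_loss <- adversarial_loss(dfg$p)
      g_loss <- generator_loss(c_loss, a_loss, lam)
      if (!is.finite(g_loss) || !is.finite(d_loss)) {
        stop(sprintf("non-finite loss at epoch %d, step %d (g=%g, d=%g)",
                     epoch, step_i, g_loss, d_loss), call. = FALSE)
      }
      db <- discriminator_backward(discriminator, dfg$caches, dfg$raw,
                                   -1 / (1 - dfg$p))
      hw <- length(y01)
      dy01 <- lam * sign(y01 - label) / hw + 2 * db$dx  # d y_t/d y01 = 2
      g_grads <- generator_backward(generator, gf$caches, dy01)
      flatg <- c(g_grads$enc, g_grads$dec)
      flatb <- c(generator$enc, generator$dec)
      upd <- adam_step(flatb, flatg, adam_g, config$learning_rate,
                       config$beta1, config$beta2)
      generator$enc <- upd$blocks[seq_len(generator$n_levels)]
      generator$dec <- upd$blocks[generator$n_levels +
                                  seq_len(generator$n_levels)]
      adam_g <- upd$state

      ep_mat[step_i, ] <- c(g_loss, c_loss, a_loss, d_loss)
    }
    ep_steps <- data.frame(epoch = epoch, step = seq_len(n),
                           g_loss = ep_mat[, 1], content_loss = ep_mat[, 2],
                           adversarial_loss = ep_mat[, 3],
                           d_loss = ep_mat[, 4])
    steps <- rbind(steps, ep_steps)
    mns <- colMeans(ep_mat)
    epochs_log <- rbind(epochs_log,
      data.frame(epoch = epoch, g_loss = mns[1], content_loss = mns[2],
                 adversarial_loss = mns[3], d_loss = mns[4]))
    if (verbose) {
      message(sprintf("epoch %3d  G %.4f  content %.5f  adv %.4f  D %.4f",
                      epoch, mns[1], mns[2], mns[3], mns[4]))
    }
    if (config$checkpoint_every > 0 && !is.null(config$checkpoint_dir) &&
        (epoch %% config$checkpoint_every == 0 || epoch == config$epochs)) {
      dir.create(config$checkpoint_dir, recursive = TRUE, showWarnings = FALSE)
      saveRDS(list(generator = generator, discriminator = discriminator,
                   adam_g = adam_g, adam_d = adam_d, epoch = epoch,
                   steps = steps, epochs = epochs_log,
                   rng = get(".Random.seed", .GlobalEnv), config = config),
              file.path(config$checkpoint_dir,
                        sprintf("checkpoint_epoch%03d.rds", epoch)))
    }
  }
  list(generator = generator, discriminator = discriminator,
       epochs = epochs_log, steps = steps)
}
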