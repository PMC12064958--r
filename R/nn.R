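# Neural-network primitives: strided 4x4 convolutions and transposed
# convolutions via im2col lowering (src/im2col.cpp) with matrix products
# through BLAS, instance-style normalization (what batch normalization
# computes at batch size 1), activations, and Adam. Feature maps are arrays
# with dim (H, W, C); weights are matrices:
#   conv:  W is (k*k*Cin)  x Cout, y = t(im2col(x)) %*% W + b
#   tconv: W is (k*k*Cout) x Cin, y = col2im(W %*% t(X)) + b
# Backward passes are hand-derived adjoints of these forms and are verified
# against numerical gradients in the test suite.

conv_out_size <- function(n, k, stride, pad) (n + 2 * pad - k) %/% stride + 1

conv_forward <- function(x, W, b, k, stride, pad) {
  d <- dim(x)
  cin <- if (length(d) == 3) d[3] else 1L
  ho <- conv_out_size(d[1], k, stride, pad)
  wo <- conv_out_size(d[2], k, stride, pad)
  cols <- nn_im2col(as.double(x), d[1], d[2], cin, k, stride, pad)
  Y <- crossprod(cols, W)
  Y <- sweep(Y, 2, b, "+")
  list(y = array(Y, c(ho, wo, ncol(W))),
       cache = list(cols = cols, in_dim = c(d[1], d[2], cin),
                    k = k, stride = stride, pad = pad))
}

conv_backward <- function(dy, W, cache) {
  d <- dim(dy)
  dY <- matrix(dy, d[1] * d[2], d[3])
  dW <- cache$cols %*% dY
  db <- colSums(dY)
  dcols <- W %*% t(dY)
  dx <- nn_col2im(dcols, cache$in_dim[1], cache$in_dim[2], cache$in_dim[3],
                  cache$k, cache$stride, cache$pad)
  list(dx = dx, dW = dW, db = db)
}

tconv_forward <- function(x, W, b, k, stride, pad) {
  d <- dim(x)
  cin <- if (length(d) == 3) d[3] else 1L
  cout <- ncol(W)
  stopifnot(cout == cin)  # W is (k*k*Cout) x Cin
  cout <- nrow(W) / (k * k)
  ho <- (d[1] - 1) * stride - 2 * pad + k
  wo <- (d[2] - 1) * stride - 2 * pad + k
  X2 <- matrix(x, d[1] * d[2], cin)
  cols <- W %*% t(X2)
  y <- nn_col2im(cols, ho, wo, cout, k, stride, pad)
  y <- sweep(y, 3, b, "+")
  list(y = y, cache = list(X2 = X2, in_dim = c(d[1], d[2], cin),
                           k = k, stride = stride, pad = pad))
}

tconv_backward <- function(dy, W, cache) {
  d <- dim(dy)
  dcols <- nn_im2col(as.double(dy), d[1], d[2], d[3],
                     cache$k, cache$stride, cache$pad)
  dX2 <- crossprod(dcols, W)
  dW <- dcols %*% cache$X2
  db <- apply(dy, 3, sum)
  list(dx = array(dX2, cache$in_dim), dW = dW, db = db)
}

# Instance normalization (batch-1 batch norm): per-channel statistics over
# the spatial plane. Running statistics accumulate during training and are
# frozen for inference.
instnorm_forward <- function(x, gamma, beta, rmu, rvar, train, momentum = 0.1,
                             eps = 1e-5) {
  d <- dim(x)
  n <- d[1] * d[2]
  M <- matrix(x, n, d[3])
  if (train) {
    mu <- colMeans(M)
    xc <- sweep(M, 2, mu)
    v <- colMeans(xc^2)
    rmu <- (1 - momentum) * rmu + momentum * mu
    rvar <- (1 - momentum) * rvar + momentum * v
  } else {
    mu <- rmu; v <- rvar
    xc <- sweep(M, 2, mu)
  }
  ivstd <- 1 / sqrt(v + eps)
  xhat <- sweep(xc, 2, ivstd, "*")
  Y <- sweep(sweep(xhat, 2, gamma, "*"), 2, beta, "+")
  list(y = array(Y, d), cache = list(xhat = xhat, ivstd = ivstd, dim = d),
       rmu = rmu, rvar = rvar)
}

instnorm_backward <- function(dy, gamma, cache) {
  d <- cache$dim
  n <- d[1] * d[2]
  dY <- matrix(dy, n, d[3])
  dgamma <- colSums(dY * cache$xhat)
  dbeta <- colSums(dY)
  dxhat <- sweep(dY, 2, gamma, "*")
  s1 <- colSums(dxhat)
  s2 <- colSums(dxhat * cache$xhat)
  dX <- sweep(dxhat, 2, s1 / n) - sweep(cache$xhat, 2, s2 / n, "*")
  dX <- sweep(dX, 2, cache$ivstd, "*")
  list(dx = array(dX, d), dgamma = dgamma, dbeta = dbeta)
}

act_forward <- function(x, act, slope = 0.2) {
  switch(act,
    lrelu = ifelse(x > 0, x, slope * x),
    relu = pmax(x, 0),
    tanh = tanh(x),
    sigmoid = 1 / (1 + exp(-x)),
    none = x)
}

act_backward <- function(dy, x, y, act, slope = 0.2) {
  switch(act,
    lrelu = dy * ifelse(x > 0, 1, slope),
    relu = dy * (x > 0),
    tanh = dy * (1 - y^2),
    sigmoid = dy * y * (1 - y),
    none = dy)
}

# --- conv/tconv block: (t)conv -> [instance norm] -> activation -----------

new_block <- function(type, cin, cout, act, use_bn, k = 4L) {
  nw <- k * k * if (type == "conv") cin else cout
  W <- matrix(rnorm(nw * if (type == "conv") cout else cin, 0, 0.02),
              nw, if (type == "conv") cout else cin)
  list(type = type, k = k, cin = cin, cout = cout, act = act,
       use_bn = use_bn, W = W, b = numeric(cout),
       gamma = rep(1, cout), beta = numeric(cout),
       rmu = numeric(cout), rvar = rep(1, cout))
}

block_forward <- function(blk, x, train, stride = 2L, pad = 1L) {
  fw <- if (blk$type == "conv") {
    conv_forward(x, blk$W, blk$b, blk$k, stride, pad)
  } else {
    tconv_forward(x, blk$W, blk$b, blk$k, stride, pad)
  }
  z <- fw$y
  bn_cache <- NULL
  bn_applied <- blk$use_bn && dim(z)[1] * dim(z)[2] > 1
  if (bn_applied) {
    bn <- instnorm_forward(z, blk$gamma, blk$beta, blk$rmu, blk$rvar, train)
    blk$rmu <- bn$rmu; blk$rvar <- bn$rvar
    z_bn <- bn$y; bn_cache <- bn$cache
  } else {
    z_bn <- z
  }
  y <- act_forward(z_bn, blk$act)
  list(y = y, blk = blk,
       cache = list(conv = fw$cache, bn = bn_cache, bn_applied = bn_applied,
                    pre_act = z_bn, post_act = y, stride = stride, pad = pad))
}

block_backward <- function(blk, cache, dy) {
  dz <- act_backward(dy, cache$pre_act, cache$post_act, blk$act)
  if (cache$bn_applied) {
    bb <- instnorm_backward(dz, blk$gamma, cache$bn)
    dz <- bb$dx
    dgamma <- bb$dgamma; dbeta <- bb$dbeta
  } else {
    dgamma <- numeric(length(blk$gamma)); dbeta <- numeric(length(blk$beta))
  }
  cb <- if (blk$type == "conv") conv_backward(dz, blk$W, cache$conv)
        else tconv_backward(dz, blk$W, cache$conv)
  list(dx = cb$dx,
       grads = list(W = cb$dW, b = cb$db, gamma = dgamma, beta = dbeta))
}

# --- Adam ------------------------------------------------------------------

adam_init <- function() list(t = 0L, m = list(), v = list())

# params/grads: list of blocks, each holding numeric leaves W, b, gamma, beta.
adam_step <- function(blocks, grads, state, lr, beta1 = 0.5, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  t <- state$t
  for (i in seq_along(blocks)) {
    for (nm in c("W", "b", "gamma", "beta")) {
      g <- grads[[i]][[nm]]
      if (is.null(g)) next
      key <- paste0(i, ".", nm)
      m <- if (!is.null(state$m[[key]])) state$m[[key]] else g * 0
      v <- if (!is.null(state$v[[key]])) state$v[[key]] else g * 0
      m <- beta1 * m + (1 - beta1) * g
      v <- beta2 * v + (1 - beta2) * g^2
      state$m[[key]] <- m; state$v[[key]] <- v
      mhat <- m / (1 - beta1^t)
      vhat <- v / (1 - beta2^t)
      blocks[[i]][[nm]] <- blocks[[i]][[nm]] - lr * mhat / (sqrt(vhat) + eps)
    }
  }
  list(blocks = blocks, state = state)
}
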