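## Layer primitives wrapping the C++ kernels. Feature maps are arrays
## (X, Y, Z, C); every forward returns what its backward needs.
## Batch size is one volume (the training default), so batch
## normalization normalizes over the spatial voxels of each channel.

nn_conv_fwd <- function(x, w, b) {
  ks <- dim(w)[1]
  cpp_conv3d_fwd(x, dim(x), w, ks, dim(w)[5], b)
}

nn_conv_bwd <- function(x, w, gy) {
  cpp_conv3d_bwd(x, dim(x), w, dim(w)[1], dim(w)[5], gy)
}

nn_tconv_fwd <- function(x, w, b) {
  cpp_tconv3d_fwd(x, dim(x), w, dim(w)[5], b)
}

nn_tconv_bwd <- function(x, w, gy) {
  cpp_tconv3d_bwd(x, dim(x), w, dim(w)[5], gy)
}

nn_pool_fwd <- function(x) cpp_maxpool3d_fwd(x, dim(x))

nn_pool_bwd <- function(gy, idx, xdim) {
  ## C++ argmax indices are 0-based linear positions
  cpp_maxpool3d_bwd(gy, idx, as.integer(xdim))
}

nn_relu_fwd <- function(x) {
  out <- x
  out[out < 0] <- 0
  out
}

nn_relu_bwd <- function(x, gy) {
  gy * (x > 0)
}

BN_EPS <- 1e-5
BN_MOMENTUM <- 0.9

## Batch norm over spatial voxels per channel. `stats` is a list with
## running $mean and $var (used in evaluation mode); the updated list is
## returned alongside the activations.
nn_bn_fwd <- function(x, gamma, beta, stats, training) {
  d <- dim(x)
  C <- d[4]
  n <- prod(d[1:3])
  y <- numeric(n * C)
  xhat <- numeric(n * C)
  invstd <- numeric(C)
  mu <- numeric(C)
  v <- numeric(C)
  for (c in seq_len(C)) {
    idx <- ((c - 1) * n + 1):(c * n)
    xc <- x[idx]
    if (training) {
      m <- mean(xc)
      xcc <- xc - m
      vv <- sum(xcc * xcc) / n
      iv <- 1 / sqrt(vv + BN_EPS)
      xh <- xcc * iv
      mu[c] <- m
      v[c] <- vv
    } else {
      iv <- 1 / sqrt(stats$var[c] + BN_EPS)
      xh <- (xc - stats$mean[c]) * iv
    }
    invstd[c] <- iv
    xhat[idx] <- xh
    y[idx] <- gamma[c] * xh + beta[c]
  }
  if (training) {
    stats$mean <- BN_MOMENTUM * stats$mean + (1 - BN_MOMENTUM) * mu
    stats$var <- BN_MOMENTUM * stats$var + (1 - BN_MOMENTUM) * v
  }
  dim(y) <- d
  list(out = y, cache = list(xhat = xhat, invstd = invstd, d = d),
       stats = stats)
}

nn_bn_bwd <- function(cache, gamma, gy) {
  d <- cache$d
  C <- d[4]
  n <- prod(d[1:3])
  gx <- numeric(n * C)
  ggamma <- numeric(C)
  gbeta <- numeric(C)
  for (c in seq_len(C)) {
    idx <- ((c - 1) * n + 1):(c * n)
    gyc <- gy[idx]
    xh <- cache$xhat[idx]
    ggamma[c] <- sum(gyc * xh)
    gbeta[c] <- sum(gyc)
    ## training-mode batch statistics participate in the gradient
    gxhat <- gamma[c] * gyc
    gx[idx] <- cache$invstd[c] *
      (gxhat - mean(gxhat) - xh * (sum(gxhat * xh) / n))
  }
  dim(gx) <- d
  list(gx = gx, ggamma = ggamma, gbeta = gbeta)
}

## Fused batch-norm + ReLU (the per-block nonlinearity path); the C++
## kernel does the per-channel statistics and masking in one pass.
nn_bnrelu_fwd <- function(x, gamma, beta, stats, training) {
  d <- dim(x)
  n <- prod(d[1:3])
  r <- cpp_bn_relu_fwd(x, n, d[4], gamma, beta, training, stats$mean,
                       stats$var, BN_EPS)
  if (training) {
    stats$mean <- BN_MOMENTUM * stats$mean + (1 - BN_MOMENTUM) * r$bmean
    stats$var <- BN_MOMENTUM * stats$var + (1 - BN_MOMENTUM) * r$bvar
  }
  out <- r$y
  dim(out) <- d
  list(out = out,
       cache = list(xhat = r$xhat, pre = r$pre, invstd = r$invstd, d = d),
       stats = stats)
}

nn_bnrelu_bwd <- function(cache, gamma, gy) {
  d <- cache$d
  r <- cpp_bn_relu_bwd(gy, cache$pre, cache$xhat, cache$invstd, gamma,
                       prod(d[1:3]), d[4])
  gx <- r$gx
  dim(gx) <- d
  list(gx = gx, ggamma = r$ggamma, gbeta = r$gbeta)
}

## Inverted dropout with keep-probability `keep`.
nn_dropout_fwd <- function(x, keep, training) {
  if (!training || keep >= 1) return(list(out = x, mask = NULL))
  mask <- array(stats::rbinom(length(x), 1L, keep) / keep, dim(x))
  list(out = x * mask, mask = mask)
}

nn_dropout_bwd <- function(gy, mask) {
  if (is.null(mask)) gy else gy * mask
}

nn_fc_fwd <- function(x, w, b) {
  as.vector(w %*% as.vector(x)) + b
}

nn_fc_bwd <- function(x, w, gy) {
  list(gx = as.vector(crossprod(w, gy)),
       gw = tcrossprod(gy, as.vector(x)), gb = gy)
}

nn_sigmoid <- function(x) 1 / (1 + exp(-x))

## He-style fan-in initialization for conv and fc kernels.
init_conv_w <- function(ks, ci, co) {
  sd <- sqrt(2 / (ks^3 * ci))
  array(stats::rnorm(ks^3 * ci * co, sd = sd), c(ks, ks, ks, ci, co))
}

init_tconv_w <- function(ci, co) {
  sd <- sqrt(2 / (8 * ci))
  array(stats::rnorm(8 * ci * co, sd = sd), c(2, 2, 2, ci, co))
}

init_fc_w <- function(nin, nout, sd = sqrt(2 / nin)) {
  matrix(stats::rnorm(nin * nout, sd = sd), nrow = nout, ncol = nin)
}

## Evaluate thunk with a private RNG stream; the caller's stream is
## untouched.
with_seed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
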