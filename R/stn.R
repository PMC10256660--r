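#' 3x4 affine transform in voxel-index coordinates
#'
#' The transform maps target voxel coordinates to source coordinates:
#' `(x_s, y_s, z_s)' = phi %*% c(x_t, y_t, z_t, 1)`. Coordinates are raw
#' 0-based voxel indices (not normalized), exactly as the interpolation
#' kernel consumes them. The identity is `[I | 0]`.
#'
#' @param phi numeric 3x4 matrix, or a length-12 vector in row-major
#'   order.
#' @return An `affine_transform` object.
#' @export
affine_transform <- function(phi) {
  if (is.numeric(phi) && is.null(dim(phi)) && length(phi) == 12)
    phi <- matrix(phi, nrow = 3, byrow = TRUE)
  phi <- as.matrix(phi)
  if (!all(dim(phi) == c(3, 4))) stop("phi must be a 3x4 matrix")
  if (any(!is.finite(phi))) stop("phi entries must be finite")
  structure(list(phi = phi), class = "affine_transform")
}

#' @rdname affine_transform
#' @export
identity_affine <- function() affine_transform(cbind(diag(3), 0))

#' @export
print.affine_transform <- function(x, ...) {
  cat("<affine_transform> phi =\n")
  print(signif(x$phi, 6))
  invisible(x)
}

#' Row-major serialization of the 12 transform parameters
#'
#' @param phi an [affine_transform()].
#' @return numeric length-12 vector (row-major).
#' @export
affine_to_vector <- function(phi) as.vector(t(phi$phi))

#' Regressor (transformation-module) architecture specification
#'
#' Four 3x3x3 convolutional layers (batch-normalized, ReLU) each followed
#' by 2x max pooling, a flatten, and one fully connected layer emitting
#' the 12 affine parameters.
#'
#' @param widths feature maps of the four convolutional layers. The
#'   default puts the full-size module near 1.4 million weights; use
#'   `c(8, 16, 32, 64)` for the tiny CPU profile.
#' @return A `regressor_spec` object.
#' @export
regressor_spec <- function(widths = c(24L, 48L, 96L, 192L)) {
  widths <- as.integer(widths)
  stopifnot(length(widths) == 4, all(widths >= 1))
  structure(list(conv_layers = 4L, pool_layers = 4L, widths = widths,
                 fc_out = 12L),
            class = "regressor_spec")
}

## Spatial dims after the four pooling layers (dims saturate at 1).
stn_pooled_dims <- function(dims) {
  d <- as.integer(dims)
  for (i in 1:4) {
    if (any(d > 1 & d %% 2L != 0L))
      stop("regressor input dims (", paste(dims, collapse = ", "),
           ") must halve cleanly through 4 pooling layers")
    d <- as.integer(ifelse(d > 1L, d %/% 2L, 1L))
  }
  d
}

#' Build a seeded transformation-module model
#'
#' The final fully connected layer is initialized to zero weights with
#' bias equal to the identity transform, so an untrained module returns
#' `[I | 0]` and training starts from the untransformed prediction.
#'
#' @param spec a [regressor_spec()].
#' @param input_shape spatial dims (M, N, L) of the two-channel input.
#' @param seed integer RNG seed.
#' @return A model object holding the `stn.*` parameter blocks.
#' @export
build_regressor <- function(spec, input_shape, seed = 1L) {
  stopifnot(inherits(spec, "regressor_spec"))
  input_shape <- as.integer(input_shape)
  pd <- stn_pooled_dims(input_shape)
  n_flat <- prod(pd) * spec$widths[4]
  params <- list()
  bn <- list()
  with_seed(seed, {
    ci <- 2L
    for (l in 1:4) {
      co <- spec$widths[l]
      params[[sprintf("stn.conv%d.w", l)]] <- init_conv_w(3L, ci, co)
      params[[sprintf("stn.conv%d.b", l)]] <- numeric(co)
      params[[sprintf("stn.bn%d.gamma", l)]] <- rep(1, co)
      params[[sprintf("stn.bn%d.beta", l)]] <- numeric(co)
      bn[[sprintf("stn.bn%d", l)]] <- list(mean = numeric(co),
                                           var = rep(1, co))
      ci <- co
    }
    params[["stn.fc.w"]] <- matrix(0, nrow = 12, ncol = n_flat)
    params[["stn.fc.b"]] <- affine_to_vector(identity_affine())
  })
  structure(list(spec = NULL, stn_spec = spec,
                 stn_input_shape = input_shape, params = params, bn = bn,
                 stn_out_scale = min(1, 32 / n_flat),
                 mode = "training", seed = as.integer(seed)),
            class = "stvnet_model")
}

## Forward through the regressor. Input: two (X,Y,Z) arrays,
## concatenated channelwise (prediction first, prior second).
stn_forward_full <- function(model, y_prime, prior, training,
                             keep_cache = FALSE) {
  if (!all(dim(y_prime)[1:3] == dim(prior)[1:3]))
    stop("prediction and prior shapes differ: (",
         paste(dim(y_prime)[1:3], collapse = ", "), ") vs (",
         paste(dim(prior)[1:3], collapse = ", "), ")")
  p <- model$params
  d3 <- dim(y_prime)[1:3]
  h <- array(c(as.numeric(y_prime), as.numeric(prior)), c(d3, 2L))
  cache <- list(blocks = list(), input_dim = dim(h))
  for (l in 1:4) {
    cn <- sprintf("stn.conv%d", l)
    bnn <- sprintf("stn.bn%d", l)
    xin <- h
    z <- nn_conv_fwd(h, p[[paste0(cn, ".w")]], p[[paste0(cn, ".b")]])
    bnr <- nn_bnrelu_fwd(z, p[[paste0(bnn, ".gamma")]],
                         p[[paste0(bnn, ".beta")]], model$bn[[bnn]],
                         training)
    model$bn[[bnn]] <- bnr$stats
    pl <- nn_pool_fwd(bnr$out)
    if (keep_cache)
      cache$blocks[[cn]] <- list(xin = xin, bn = bnr$cache,
                                 pool_idx = pl$idx,
                                 pool_xdim = dim(bnr$out))
    h <- pl$y
  }
  if (keep_cache) cache$flat_dim <- dim(h)
  ## the weight path is scaled so that optimizer steps move the affine by
  ## a grid-size-invariant amount (a wide flat layer would otherwise let
  ## sign-like adaptive updates throw the transform out of the volume)
  s <- stn_scale(model)
  vec <- p[["stn.fc.b"]] +
    s * as.vector(p[["stn.fc.w"]] %*% as.vector(h))
  if (keep_cache) cache$fc_in <- h
  list(phi_vec = vec, cache = if (keep_cache) cache else NULL,
       model = model)
}

stn_scale <- function(model) model$stn_out_scale %||% 1

## Backward through the regressor; returns parameter gradients and the
## gradient w.r.t. the two-channel input.
stn_backward <- function(model, cache, gphi_vec) {
  p <- model$params
  grads <- list()
  s <- stn_scale(model)
  grads[["stn.fc.w"]] <- s * tcrossprod(gphi_vec, as.vector(cache$fc_in))
  grads[["stn.fc.b"]] <- gphi_vec
  gh <- array(s * as.vector(crossprod(p[["stn.fc.w"]], gphi_vec)),
              cache$flat_dim)
  for (l in 4:1) {
    cn <- sprintf("stn.conv%d", l)
    bnn <- sprintf("stn.bn%d", l)
    bc <- cache$blocks[[cn]]
    gh <- nn_pool_bwd(gh, bc$pool_idx, bc$pool_xdim)
    bb <- nn_bnrelu_bwd(bc$bn, p[[paste0(bnn, ".gamma")]], gh)
    grads[[paste0(bnn, ".gamma")]] <- bb$ggamma
    grads[[paste0(bnn, ".beta")]] <- bb$gbeta
    cw <- nn_conv_bwd(bc$xin, p[[paste0(cn, ".w")]], bb$gx)
    grads[[paste0(cn, ".w")]] <- cw$gw
    grads[[paste0(cn, ".b")]] <- cw$gb
    gh <- cw$gx
  }
  list(grads = grads, gx = gh)
}

#' Regress an affine transform from a prediction and a shape prior
#'
#' Concatenates the probability map and the prior channelwise
#' (prediction first), runs the four conv/pool stages and the fully
#' connected head, and returns the 12 emitted parameters as a 3x4
#' transform.
#'
#' @param y_prime a [probability_volume()] (V-Net output).
#' @param prior a [binary_mask()] shape prior of the same shape.
#' @param model a model holding `stn.*` parameter blocks.
#' @return An [affine_transform()].
#' @export
regress_affine <- function(y_prime, prior, model) {
  training <- identical(model$mode, "training")
  res <- stn_forward_full(model, unclass(y_prime), unclass(prior), training)
  affine_transform(res$phi_vec)
}

#' Sampling grid of source coordinates for an affine transform
#'
#' For every target voxel `(x_t, y_t, z_t)` (0-based) the source
#' coordinate is `phi %*% c(x_t, y_t, z_t, 1)`. Coordinates may fall
#' outside the grid; the sampler assigns such voxels zero contribution.
#'
#' @param phi an [affine_transform()].
#' @param shape target dims (M, N, L).
#' @return An `(M*N*L) x 3` matrix of real-valued source indices, with
#'   attribute `shape`; rows are ordered with the first axis fastest
#'   (R array order).
#' @export
affine_grid <- function(phi, shape) {
  stopifnot(inherits(phi, "affine_transform"), length(shape) == 3,
            all(shape >= 1))
  shape <- as.integer(shape)
  tx <- seq_len(shape[1]) - 1
  ty <- seq_len(shape[2]) - 1
  tz <- seq_len(shape[3]) - 1
  tgt <- cbind(rep(tx, times = shape[2] * shape[3]),
               rep(rep(ty, each = shape[1]), times = shape[3]),
               rep(tz, each = shape[1] * shape[2]), 1)
  src <- tgt %*% t(phi$phi)
  structure(src, shape = shape, target = tgt[, 1:3, drop = FALSE])
}

#' Trilinear (hat-kernel) resampling of a volume on a sampling grid
#'
#' Each output voxel is the hat-kernel-weighted sum of source voxels:
#' the weight of source voxel `(m, n, l)` at source coordinate
#' `(x, y, z)` is `max(0, 1-|x-m|) * max(0, 1-|y-n|) * max(0, 1-|z-l|)`.
#' Coordinates outside the grid contribute zero. The implementation uses
#' the 8-neighbour closed form, which equals the full triple sum because
#' the hat kernel vanishes beyond the two enclosing integer nodes.
#'
#' @param src a volume (probability, intensity, or plain 3D array).
#' @param grid a sampling grid from [affine_grid()].
#' @return An object of the same kind as `src`, at the grid's target
#'   shape.
#' @export
trilinear_sample <- function(src, grid) {
  shape <- attr(grid, "shape")
  out <- cpp_trilinear_fwd(as.numeric(unclass(src)), dim(src)[1:3],
                           unclass_grid(grid))
  out <- array(out, shape)
  if (is_probability_volume(src)) {
    out <- clip_unit(out)
    probability_volume(out, spacing = vol_spacing(src),
                       origin = vol_origin(src))
  } else if (is_intensity_volume(src)) {
    intensity_volume(out, spacing = vol_spacing(src),
                     origin = vol_origin(src))
  } else out
}

unclass_grid <- function(grid) {
  g <- unclass(grid)
  attr(g, "shape") <- NULL
  attr(g, "target") <- NULL
  g
}

## interpolation of a [0,1] volume is a convex combination plus zero
## padding, so only numeric noise can escape the interval
clip_unit <- function(x, tol = 1e-6) {
  if (min(x) < -tol || max(x) > 1 + tol)
    stop("sampled values escape [0,1] by more than numeric tolerance")
  pmin(pmax(x, 0), 1)
}

#' Analytic jacobians of the trilinear sampler
#'
#' Returns the partial derivatives of each output voxel with respect to
#' the source voxels (a sparse 8-neighbour representation: 0-based linear
#' indices, `NA` where the neighbour is out of bounds, with hat-kernel
#' weights) and with respect to each source coordinate (the piecewise
#' +/-1-weighted kernel products; at exact integer coordinates the
#' `x <= m` branch takes derivative +1).
#'
#' @param src source volume.
#' @param grid sampling grid from [affine_grid()].
#' @return list with `neighbors` (n x 8), `weights` (n x 8), and
#'   `dcoords` (n x 3).
#' @export
sample_jacobians <- function(src, grid) {
  g <- unclass_grid(grid)
  if (any(!is.finite(g))) stop("non-finite sampling coordinates")
  res <- cpp_trilinear_jac(as.numeric(unclass(src)), dim(src)[1:3], g)
  nbr <- res$neighbors
  nbr[nbr < 0] <- NA_integer_
  list(neighbors = nbr, weights = res$weights, dcoords = res$dcoords)
}

#' Apply an affine transform to a probability volume
#'
#' Composition of [affine_grid()] and [trilinear_sample()]: the deformed
#' map `Y''` used by the shape-prior alignment loss.
#'
#' @param y_prime a [probability_volume()].
#' @param phi an [affine_transform()].
#' @return A [probability_volume()] of the same shape.
#' @export
apply_transform <- function(y_prime, phi) {
  grid <- affine_grid(phi, dim(y_prime)[1:3])
  trilinear_sample(y_prime, grid)
}
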