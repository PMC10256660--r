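#' Segmenter architecture specification
#'
#' Describes the 3D V-Net encoder-decoder: `levels` max-pool
#' downsampling stages mirrored by transpose-convolution upsampling with
#' skip connections, a dropout layer before the final 1x1x1 convolution,
#' and a logistic output yielding one foreground probability per voxel.
#' Channel widths double per level starting from `base_width`; the
#' default width puts the full-size network near 8.6 million weights,
#' while `base_width` 4-8 with one convolution per block gives a "tiny"
#' profile that trains on a CPU.
#'
#' @param input_shape spatial dims (M, N, L); each must be divisible by
#'   `2^levels`.
#' @param levels number of down/up-sampling stages (default 3).
#' @param base_width feature maps in the first encoder block.
#' @param convs_per_block convolutions (3x3x3, batch-normalized, ReLU)
#'   per block.
#' @param dropout_keep keep-probability of the dropout layer preceding
#'   the output convolution (default 0.8).
#' @return A `segmenter_spec` object.
#' @export
segmenter_spec <- function(input_shape = c(192L, 192L, 32L), levels = 3L,
                           base_width = 40L, convs_per_block = 2L,
                           dropout_keep = 0.8) {
  input_shape <- as.integer(input_shape)
  stopifnot(length(input_shape) == 3, levels >= 1, base_width >= 1,
            convs_per_block >= 1)
  if (dropout_keep <= 0 || dropout_keep > 1)
    stop("dropout_keep must be in (0, 1]")
  div <- 2L^levels
  bad <- which(input_shape %% div != 0)
  if (length(bad))
    stop("input dimension ", input_shape[bad[1]], " (axis ", bad[1],
         ") is not divisible by 2^levels = ", div)
  structure(list(input_shape = input_shape, levels = as.integer(levels),
                 base_width = as.integer(base_width),
                 convs_per_block = as.integer(convs_per_block),
                 dropout_keep = dropout_keep),
            class = "segmenter_spec")
}

#' A tiny CPU-friendly segmenter profile
#'
#' @param input_shape spatial dims, default `c(64, 64, 32)`.
#' @param base_width default 4.
#' @return A [segmenter_spec()].
#' @export
segmenter_spec_tiny <- function(input_shape = c(64L, 64L, 32L),
                                base_width = 4L) {
  segmenter_spec(input_shape = input_shape, base_width = base_width,
                 convs_per_block = 1L)
}

vnet_widths <- function(spec) {
  spec$base_width * 2L^(0:(spec$levels)) # encoder widths + bottleneck
}

#' Build a seeded V-Net model
#'
#' Constructs all trainable parameter blocks (convolution and transpose
#' convolution kernels, biases, batch-norm scale/shift) with a seeded,
#' reproducible initialization. The returned model starts in training
#' mode.
#'
#' @param spec a [segmenter_spec()].
#' @param seed integer RNG seed for the initialization.
#' @return A model object (named parameter blocks plus batch-norm running
#'   statistics); pass to [vnet_forward()] or the training functions.
#' @export
build_vnet <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "segmenter_spec"))
  params <- list()
  bn <- list()
  add_conv <- function(name, ks, ci, co) {
    params[[paste0(name, ".w")]] <<- init_conv_w(ks, ci, co)
    params[[paste0(name, ".b")]] <<- numeric(co)
  }
  add_bn <- function(name, c) {
    params[[paste0(name, ".gamma")]] <<- rep(1, c)
    params[[paste0(name, ".beta")]] <<- numeric(c)
    bn[[name]] <<- list(mean = numeric(c), var = rep(1, c))
  }
  w <- vnet_widths(spec)
  with_seed(seed, {
    for (l in seq_len(spec$levels)) {
      for (j in seq_len(spec$convs_per_block)) {
        ci <- if (j > 1) w[l] else if (l == 1) 1L else w[l - 1]
        add_conv(sprintf("vnet.enc%d.conv%d", l, j), 3L, ci, w[l])
        add_bn(sprintf("vnet.enc%d.bn%d", l, j), w[l])
      }
    }
    for (j in seq_len(spec$convs_per_block)) {
      ci <- if (j > 1) w[spec$levels + 1] else w[spec$levels]
      add_conv(sprintf("vnet.bottom.conv%d", j), 3L, ci, w[spec$levels + 1])
      add_bn(sprintf("vnet.bottom.bn%d", j), w[spec$levels + 1])
    }
    for (l in rev(seq_len(spec$levels))) {
      ci_up <- if (l == spec$levels) w[spec$levels + 1] else w[l + 1]
      params[[sprintf("vnet.dec%d.up.w", l)]] <- init_tconv_w(ci_up, w[l])
      params[[sprintf("vnet.dec%d.up.b", l)]] <- numeric(w[l])
      for (j in seq_len(spec$convs_per_block)) {
        ci <- if (j > 1) w[l] else 2L * w[l] # concat skip + upsampled
        add_conv(sprintf("vnet.dec%d.conv%d", l, j), 3L, ci, w[l])
        add_bn(sprintf("vnet.dec%d.bn%d", l, j), w[l])
      }
    }
    add_conv("vnet.final", 1L, w[1], 1L)
  })
  structure(list(spec = spec, stn_spec = NULL, params = params, bn = bn,
                 mode = "training", seed = as.integer(seed)),
            class = "stvnet_model")
}

#' @export
print.stvnet_model <- function(x, ...) {
  cat("<stvnet_model> ", count_params(x), " parameters, mode: ", x$mode,
      "\n", sep = "")
  if (!is.null(x$spec))
    cat("  V-Net: input ", paste(x$spec$input_shape, collapse = "x"),
        ", levels ", x$spec$levels, ", base width ", x$spec$base_width,
        "\n", sep = "")
  if (!is.null(x$stn_spec))
    cat("  transformation module widths: ",
        paste(x$stn_spec$widths, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Total trainable parameter count
#'
#' @param model a model built by [build_vnet()], [build_regressor()] or
#'   [st_vnet_model()].
#' @return integer count over all parameter blocks.
#' @export
count_params <- function(model) {
  sum(vapply(model$params, length, integer(1)))
}

#' Switch a model between training and evaluation mode
#'
#' In evaluation mode dropout is disabled and batch normalization uses
#' its frozen running statistics, so the forward pass is deterministic.
#'
#' @param model a model object.
#' @param mode `"training"` or `"evaluation"`.
#' @return The model with its mode set.
#' @export
set_mode <- function(model, mode = c("evaluation", "training")) {
  model$mode <- match.arg(mode)
  model
}

## Forward pass. Returns list(prob, cache, model). `cache` is populated
## only when keep_cache = TRUE (training); `model` carries updated BN
## running statistics.
vnet_forward_full <- function(model, x, training, keep_cache = FALSE) {
  spec <- model$spec
  d3 <- dim(x)[1:3]
  if (!all(d3 == spec$input_shape))
    stop("input shape (", paste(d3, collapse = ", "),
         ") does not match the segmenter spec (",
         paste(spec$input_shape, collapse = ", "), ")")
  p <- model$params
  if (any(!vapply(p, function(b) all(is.finite(b)), logical(1))))
    stop("model parameters contain non-finite values")
  cache <- list(blocks = list())
  h <- array(as.numeric(x), c(d3, 1L))
  run_block <- function(h, name, nconv) {
    for (j in seq_len(nconv)) {
      cn <- sprintf("%s.conv%d", name, j)
      bnn <- sprintf("%s.bn%d", name, j)
      xin <- h
      z <- nn_conv_fwd(xin, p[[paste0(cn, ".w")]], p[[paste0(cn, ".b")]])
      bnr <- nn_bnrelu_fwd(z, p[[paste0(bnn, ".gamma")]],
                           p[[paste0(bnn, ".beta")]], model$bn[[bnn]],
                           training)
      model$bn[[bnn]] <<- bnr$stats
      if (keep_cache)
        cache$blocks[[cn]] <<- list(xin = xin, bn = bnr$cache)
      h <- bnr$out
    }
    h
  }
  skips <- vector("list", spec$levels)
  for (l in seq_len(spec$levels)) {
    h <- run_block(h, sprintf("vnet.enc%d", l), spec$convs_per_block)
    skips[[l]] <- h
    pl <- nn_pool_fwd(h)
    if (keep_cache)
      cache$blocks[[sprintf("vnet.pool%d", l)]] <-
        list(idx = pl$idx, xdim = dim(h))
    h <- pl$y
  }
  h <- run_block(h, "vnet.bottom", spec$convs_per_block)
  for (l in rev(seq_len(spec$levels))) {
    upn <- sprintf("vnet.dec%d.up", l)
    xin <- h
    h <- nn_tconv_fwd(h, p[[paste0(upn, ".w")]], p[[paste0(upn, ".b")]])
    if (keep_cache) cache$blocks[[upn]] <- list(xin = xin)
    ## concatenate the pre-pool encoder features channelwise
    sk <- skips[[l]]
    dd <- dim(h)
    h <- array(c(sk, h), c(dd[1:3], dim(sk)[4] + dd[4]))
    if (keep_cache)
      cache$blocks[[sprintf("vnet.cat%d", l)]] <-
        list(nskip = dim(sk)[4], nup = dd[4])
    h <- run_block(h, sprintf("vnet.dec%d", l), spec$convs_per_block)
  }
  dr <- nn_dropout_fwd(h, spec$dropout_keep, training)
  if (keep_cache) cache$blocks[["vnet.dropout"]] <- list(mask = dr$mask)
  h <- dr$out
  logit <- nn_conv_fwd(h, p[["vnet.final.w"]], p[["vnet.final.b"]])
  prob <- nn_sigmoid(logit)
  if (keep_cache) {
    cache$blocks[["vnet.final"]] <- list(xin = h)
    cache$prob <- prob
  }
  list(prob = array(prob, d3), cache = if (keep_cache) cache else NULL,
       model = model)
}

#' Run the segmenter on an intensity volume
#'
#' @param model a model containing V-Net weights.
#' @param v an [intensity_volume()] (or plain 3D array) matching the
#'   spec's `input_shape`.
#' @return A [probability_volume()] at the input resolution. In
#'   evaluation mode the map is deterministic for fixed weights.
#' @export
vnet_forward <- function(model, v) {
  training <- identical(model$mode, "training")
  res <- vnet_forward_full(model, unclass(v), training = training)
  probability_volume(res$prob, spacing = vol_spacing(v),
                     origin = vol_origin(v))
}

## Backward through the V-Net given d loss / d prob. Returns named
## gradient list for every vnet.* block.
vnet_backward <- function(model, cache, gprob) {
  spec <- model$spec
  p <- model$params
  grads <- list()
  prob <- cache$prob
  glogit <- array(as.numeric(gprob) * as.numeric(prob) *
                    (1 - as.numeric(prob)), dim(prob))
  fin <- cache$blocks[["vnet.final"]]
  bw <- nn_conv_bwd(fin$xin, p[["vnet.final.w"]], glogit)
  grads[["vnet.final.w"]] <- bw$gw
  grads[["vnet.final.b"]] <- bw$gb
  gh <- nn_dropout_bwd(bw$gx, cache$blocks[["vnet.dropout"]]$mask)
  bwd_block <- function(gh, name, nconv) {
    for (j in rev(seq_len(nconv))) {
      cn <- sprintf("%s.conv%d", name, j)
      bnn <- sprintf("%s.bn%d", name, j)
      bc <- cache$blocks[[cn]]
      bb <- nn_bnrelu_bwd(bc$bn, p[[paste0(bnn, ".gamma")]], gh)
      grads[[paste0(bnn, ".gamma")]] <<- bb$ggamma
      grads[[paste0(bnn, ".beta")]] <<- bb$gbeta
      cw <- nn_conv_bwd(bc$xin, p[[paste0(cn, ".w")]], bb$gx)
      grads[[paste0(cn, ".w")]] <<- cw$gw
      grads[[paste0(cn, ".b")]] <<- cw$gb
      gh <- cw$gx
    }
    gh
  }
  gskips <- vector("list", spec$levels)
  for (l in seq_len(spec$levels)) {
    gh <- bwd_block(gh, sprintf("vnet.dec%d", l), spec$convs_per_block)
    ct <- cache$blocks[[sprintf("vnet.cat%d", l)]]
    dd <- dim(gh)
    gsk <- array(gh[, , , seq_len(ct$nskip), drop = FALSE],
                 c(dd[1:3], ct$nskip))
    gup <- array(gh[, , , ct$nskip + seq_len(ct$nup), drop = FALSE],
                 c(dd[1:3], ct$nup))
    gskips[[l]] <- gsk
    upn <- sprintf("vnet.dec%d.up", l)
    uw <- nn_tconv_bwd(cache$blocks[[upn]]$xin, p[[paste0(upn, ".w")]], gup)
    grads[[paste0(upn, ".w")]] <- uw$gw
    grads[[paste0(upn, ".b")]] <- uw$gb
    gh <- uw$gx
  }
  gh <- bwd_block(gh, "vnet.bottom", spec$convs_per_block)
  for (l in rev(seq_len(spec$levels))) {
    pn <- sprintf("vnet.pool%d", l)
    pc <- cache$blocks[[pn]]
    gh <- nn_pool_bwd(gh, pc$idx, pc$xdim)
    gh <- gh + gskips[[l]]
    gh <- bwd_block(gh, sprintf("vnet.enc%d", l), spec$convs_per_block)
  }
  grads
}
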