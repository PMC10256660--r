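#' Stratified test/fold split of a cohort
#'
#' Holds out `test_frac` of the ids as an external test set and
#' partitions the remainder into `k` disjoint folds, preserving the
#' stratum proportions of the cohort within one sample in the test set
#' and in every fold (largest-remainder allocation, per-stratum
#' round-robin). Deterministic for a fixed seed.
#'
#' @param ids character vector of sample ids.
#' @param strata character vector of stratum labels, one per id.
#' @param k number of folds (default 10).
#' @param test_frac fraction held out as the external test set.
#' @param seed integer seed.
#' @return A `fold_split`: list with `test_ids`, `folds` (list of k id
#'   vectors) and `strata` (named lookup).
#' @export
stratified_split <- function(ids, strata, k = 10L, test_frac = 0.10,
                             seed = 1L) {
  ids <- as.character(ids)
  if (length(strata) != length(ids)) stop("every id needs a stratum label")
  strata <- as.character(strata)
  names(strata) <- ids
  levels <- unique(strata)
  n_test <- largest_remainder(
    vapply(levels, function(s) mean(strata == s), numeric(1)),
    round(test_frac * length(ids)))
  with_seed(seed, {
    test_ids <- character(0)
    rest <- list()
    for (si in seq_along(levels)) {
      pool <- sample(ids[strata == levels[si]])
      if (length(pool) - n_test[si] < k)
        stop("stratum '", levels[si], "' has ", length(pool) - n_test[si],
             " non-test samples but k = ", k, " folds were requested")
      test_ids <- c(test_ids, pool[seq_len(n_test[si])])
      rest[[si]] <- pool[-seq_len(n_test[si])]
    }
    folds <- rep(list(character(0)), k)
    for (si in seq_along(levels)) {
      pool <- rest[[si]]
      for (i in seq_along(pool)) {
        f <- ((i - 1) %% k) + 1
        folds[[f]] <- c(folds[[f]], pool[i])
      }
    }
    structure(list(test_ids = test_ids, folds = folds, strata = strata),
              class = "fold_split")
  })
}

#' Augmentation configuration
#'
#' Each transform fires independently with its configured probability.
#' Geometric transforms (rotation, mirror) are applied identically to
#' volume and mask; intensity transforms (brightness, gamma, noise) to
#' the volume only. Rotation angles are drawn uniformly within
#' +/-`rotation_max_deg` per axis.
#'
#' @param rotation_max_deg rotation bound per axis in degrees.
#' @param p_rotate,p_mirror,p_brightness,p_gamma,p_noise per-transform
#'   probabilities.
#' @param brightness_frac brightness shift bound as a fraction of the
#'   intensity range.
#' @param gamma_range range of the gamma exponent applied to
#'   range-normalized intensities.
#' @param noise_frac Gaussian noise sd as a fraction of the intensity
#'   range.
#' @return An `augment_config` object.
#' @export
augment_config <- function(rotation_max_deg = 15, p_rotate = 0.5,
                           p_mirror = 0.5, p_brightness = 0.5,
                           p_gamma = 0.5, p_noise = 0.5,
                           brightness_frac = 0.1,
                           gamma_range = c(0.7, 1.43), noise_frac = 0.02) {
  structure(list(rotation_max_deg = rotation_max_deg, p_rotate = p_rotate,
                 p_mirror = p_mirror, p_brightness = p_brightness,
                 p_gamma = p_gamma, p_noise = p_noise,
                 brightness_frac = brightness_frac,
                 gamma_range = gamma_range, noise_frac = noise_frac),
            class = "augment_config")
}

## rotation about the grid centre in voxel-index coordinates;
## target -> source map for resampling is the inverse rotation
rotation_phi <- function(angles_deg, dims) {
  a <- angles_deg * pi / 180
  rx <- matrix(c(1, 0, 0, 0, cos(a[1]), sin(a[1]), 0, -sin(a[1]),
                 cos(a[1])), 3, 3)
  ry <- matrix(c(cos(a[2]), 0, -sin(a[2]), 0, 1, 0, sin(a[2]), 0,
                 cos(a[2])), 3, 3)
  rz <- matrix(c(cos(a[3]), sin(a[3]), 0, -sin(a[3]), cos(a[3]), 0, 0, 0,
                 1), 3, 3)
  rot <- rx %*% ry %*% rz
  centre <- (dims - 1) / 2
  rinv <- t(rot)
  affine_transform(cbind(rinv, centre - rinv %*% centre))
}

nearest_sample <- function(src, grid) {
  shape <- attr(grid, "shape")
  g <- round(unclass_grid(grid))
  d <- dim(src)[1:3]
  ok <- g[, 1] >= 0 & g[, 1] < d[1] & g[, 2] >= 0 & g[, 2] < d[2] &
    g[, 3] >= 0 & g[, 3] < d[3]
  out <- numeric(nrow(g))
  idx <- g[ok, , drop = FALSE] + 1
  out[ok] <- unclass(src)[cbind(idx[, 1], idx[, 2], idx[, 3])]
  array(out, shape)
}

#' Randomly augment a volume/mask pair
#'
#' Uses the current RNG stream; seed the session (or wrap in a seeded
#' context) for reproducible draws. The volume is resampled trilinearly
#' under rotation; the mask with nearest-neighbour sampling, so it stays
#' binary.
#'
#' @param v an [intensity_volume()].
#' @param mask the paired [binary_mask()].
#' @param cfg an [augment_config()].
#' @return list with augmented `volume` and `mask`.
#' @export
augment <- function(v, mask, cfg = augment_config()) {
  check_same_shape(v, mask)
  d <- dim(v)[1:3]
  x <- unclass(v)
  m <- unclass(mask)
  if (stats::runif(1) < cfg$p_rotate) {
    ang <- stats::runif(3, -cfg$rotation_max_deg, cfg$rotation_max_deg)
    phi <- rotation_phi(ang, d)
    grid <- affine_grid(phi, d)
    x <- array(cpp_trilinear_fwd(as.numeric(x), d, unclass_grid(grid)), d)
    m <- (nearest_sample(m, grid) > 0.5) + 0
  }
  if (stats::runif(1) < cfg$p_mirror) {
    ax <- sample(3, 1)
    x <- flip_axis(x, ax)
    m <- flip_axis(m, ax)
  }
  rng <- diff(range(x))
  if (stats::runif(1) < cfg$p_brightness)
    x <- x + stats::runif(1, -cfg$brightness_frac, cfg$brightness_frac) * rng
  if (stats::runif(1) < cfg$p_gamma && rng > 0) {
    g <- stats::runif(1, cfg$gamma_range[1], cfg$gamma_range[2])
    lo <- min(x)
    x <- lo + (((x - lo) / rng)^g) * rng
  }
  if (stats::runif(1) < cfg$p_noise)
    x <- x + array(stats::rnorm(length(x), sd = cfg$noise_frac * rng), d)
  list(volume = intensity_volume(x, spacing = vol_spacing(v),
                                 origin = vol_origin(v)),
       mask = binary_mask(m, spacing = vol_spacing(mask),
                          origin = vol_origin(mask)))
}

flip_axis <- function(x, ax) {
  idx <- lapply(dim(x), seq_len)
  idx[[ax]] <- rev(idx[[ax]])
  x[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
}

#' Training configuration
#'
#' @param stage_epochs epochs for training stages I, II and III.
#' @param lr Adam learning rate (default 1e-4, the study setting).
#' @param batch_size volumes per optimizer step (default 1).
#' @param seed integer seed driving shuffling, dropout and augmentation.
#' @param weights a [loss_weights()].
#' @param augment_cfg an [augment_config()], or `NULL` to disable
#'   augmentation.
#' @param prior_element structuring element kind for the shape priors.
#' @return A `training_config` object.
#' @export
training_config <- function(stage_epochs = c(10L, 5L, 10L), lr = 1e-4,
                            batch_size = 1L, seed = 1L,
                            weights = loss_weights(),
                            augment_cfg = augment_config(),
                            prior_element = "cube5") {
  stopifnot(length(stage_epochs) == 3, all(stage_epochs >= 1), lr > 0)
  structure(list(stage_epochs = as.integer(stage_epochs), lr = lr,
                 batch_size = as.integer(batch_size),
                 seed = as.integer(seed), weights = weights,
                 augment_cfg = augment_cfg, prior_element = prior_element),
            class = "training_config")
}

#' Desk-scale training profile
#'
#' Configuration for CPU-scale experiments on small phantom cohorts:
#' short stage schedule (6/3/6 epochs) and a learning rate of 1e-3. The
#' tiny networks tolerate the larger rate, and the phantom task then
#' converges within a few epochs; the default [training_config()] keeps
#' the full-scale settings (1e-4, longer schedule).
#'
#' @param seed integer seed.
#' @return A [training_config()].
#' @export
training_config_desk <- function(seed = 1L) {
  training_config(stage_epochs = c(6L, 3L, 6L), lr = 1e-3, seed = seed)
}

## ---- Adam ---------------------------------------------------------------

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

adam_step <- function(params, grads, state, lr, include,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in include) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

## add the gradient of the (size-normalized) L2 penalty for the kernel
## blocks being updated; the normalizer is the total penalized entry
## count so the gradient matches gamma * l2_penalty(model, average=TRUE)
add_l2_grads <- function(grads, params, gamma, include) {
  if (gamma == 0) return(grads)
  kernels <- names(params)[grepl("\\.w$", names(params))]
  ntot <- sum(vapply(kernels, function(n) length(params[[n]]), numeric(1)))
  for (nm in include) {
    if (!grepl("\\.w$", nm)) next
    g0 <- grads[[nm]]
    gl2 <- (2 * gamma / ntot) * params[[nm]]
    grads[[nm]] <- if (is.null(g0)) gl2 else g0 + gl2
  }
  grads
}

param_names <- function(model, prefix) {
  nm <- names(model$params)
  nm[startsWith(nm, prefix)]
}

## hard-Dice validation score (Otsu-binarized forward pass, eval mode)
validation_dsc <- function(model, val_set) {
  em <- set_mode(model, "evaluation")
  mean(vapply(val_set, function(s) {
    pr <- vnet_forward_full(em, unclass(s$volume), training = FALSE)$prob
    bin <- suppressWarnings(otsu_binarize(probability_volume(pr)))
    dice_coefficient(bin, s$mask)
  }, numeric(1)))
}

maybe_augment <- function(s, cfg) {
  if (is.null(cfg$augment_cfg)) return(s)
  a <- augment(s$volume, s$mask, cfg$augment_cfg)
  list(id = s$id, stratum = s$stratum, volume = a$volume, mask = a$mask)
}

check_finite_loss <- function(loss, stage, epoch, id) {
  if (!is.finite(loss))
    stop("non-finite loss (", loss, ") in stage ", stage, ", epoch ",
         epoch, ", sample ", id)
}

## ---- stage steps --------------------------------------------------------

## One optimization step of stage I on one sample: only vnet.* blocks
## receive updates; objective alpha * L_dice(Y', Y) + gamma * L2.
step_stage1 <- function(model, opt, s, cfg) {
  fw <- vnet_forward_full(model, unclass(s$volume), training = TRUE,
                          keep_cache = TRUE)
  model <- fw$model
  w <- cfg$weights
  loss <- w$alpha * dice_loss(fw$prob, s$mask, "soft") +
    w$gamma * l2_penalty(model, average = TRUE)
  gprob <- w$alpha * soft_dice_grad(fw$prob, s$mask)
  grads <- vnet_backward(model, fw$cache, gprob)
  include <- param_names(model, "vnet.")
  grads <- add_l2_grads(grads, model$params, w$gamma, include)
  up <- adam_step(model$params, grads, opt, cfg$lr, include)
  model$params <- up$params
  list(model = model, opt = up$state, loss = loss)
}

## Stage II step: V-Net frozen (evaluation-mode forward, no V-Net
## gradients); only stn.* blocks updated; objective
## beta * L_dice(Y'', Y) + gamma * L2.
step_stage2 <- function(model, opt, s, prior, cfg) {
  yp <- vnet_forward_full(set_mode(model, "evaluation"),
                          unclass(s$volume), training = FALSE)$prob
  res <- stn_step_core(model, opt, s, yp, prior, cfg,
                       include = param_names(model, "stn."),
                       gy_prime_out = FALSE)
  res
}

## shared core: forward stn + sampler, backprop beta-term into stn (and
## optionally return the gradient w.r.t. Y')
stn_step_core <- function(model, opt, s, y_prime, prior, cfg, include,
                          gy_prime_out) {
  w <- cfg$weights
  sf <- stn_forward_full(model, y_prime, unclass(prior),
                         training = TRUE, keep_cache = TRUE)
  model <- sf$model
  phi <- affine_transform(sf$phi_vec)
  d <- dim(y_prime)[1:3]
  grid <- affine_grid(phi, d)
  coords <- unclass_grid(grid)
  ypp <- array(cpp_trilinear_fwd(as.numeric(y_prime), d, coords), d)
  ypp_cl <- array(pmin(pmax(ypp, 0), 1), d)
  loss_beta <- w$beta * dice_loss_raw_soft(ypp_cl, s$mask)
  gypp <- w$beta * soft_dice_grad(ypp_cl, s$mask)
  bw <- cpp_trilinear_bwd(as.numeric(y_prime), d, coords,
                          as.numeric(gypp))
  tgt <- cbind(attr(grid, "target"), 1)
  gphi <- crossprod(bw$gcoords, tgt) # 3 x 4
  gphi_vec <- as.vector(t(gphi))
  sg <- stn_backward(model, sf$cache, gphi_vec)
  grads <- sg$grads
  grads <- add_l2_grads(grads, model$params, w$gamma, include)
  up <- adam_step(model$params, grads, opt, cfg$lr, include)
  model$params <- up$params
  out <- list(model = model, opt = up$state, loss_beta = loss_beta,
              ypp = ypp_cl)
  if (gy_prime_out) {
    gyp <- array(bw$gsrc, d) # through the sampled source
    gin <- sg$gx # through the regressor input (channel 1 = Y')
    out$gy_prime <- gyp + array(gin[, , , 1], d)
  }
  out
}

dice_loss_raw_soft <- function(p, truth) {
  y <- as.numeric(unclass(truth))
  p <- as.numeric(p)
  1 - (2 * sum(p * y) + DICE_EPS) / (sum(p) + sum(y) + DICE_EPS)
}

## Stage III step: joint update of all blocks under the full objective.
step_stage3 <- function(model, opt, s, prior, cfg) {
  w <- cfg$weights
  fw <- vnet_forward_full(model, unclass(s$volume), training = TRUE,
                          keep_cache = TRUE)
  model <- fw$model
  core <- stn_step_core(model, opt, s, fw$prob, prior, cfg,
                        include = param_names(model, "stn."),
                        gy_prime_out = TRUE)
  ## core already applied the stn/L2 update; now add the vnet part fed by
  ## both loss terms
  model <- core$model
  opt <- core$opt
  loss <- w$alpha * dice_loss(probability_volume(fw$prob), s$mask, "soft") +
    core$loss_beta + w$gamma * l2_penalty(model, average = TRUE)
  gprob <- w$alpha * soft_dice_grad(fw$prob, s$mask) + core$gy_prime
  grads <- vnet_backward(model, fw$cache, gprob)
  include <- param_names(model, "vnet.")
  grads <- add_l2_grads(grads, model$params, w$gamma, include)
  up <- adam_step(model$params, grads, opt, cfg$lr, include)
  model$params <- up$params
  list(model = model, opt = up$state, loss = loss)
}

## ---- stages -------------------------------------------------------------

run_epochs <- function(model, data, cfg, stage, epochs, step_fn,
                       priors = NULL, store = NULL, elem = NULL,
                       val_metric = validation_dsc) {
  opt <- adam_init(model$params)
  best <- list(dsc = -Inf, params = model$params, bn = model$bn)
  history <- data.frame()
  for (ep in seq_len(epochs)) {
    losses <- numeric(0)
    for (i in sample(length(data$train))) {
      s0 <- data$train[[i]]
      s <- maybe_augment(s0, cfg)
      prior <- if (!is.null(store)) store$priors[[s0$id]]
               else if (!is.null(priors)) priors[[s0$id]] else NULL
      res <- if (is.null(prior)) step_fn(model, opt, s, cfg)
             else step_fn(model, opt, s, prior, cfg)
      model <- res$model
      opt <- res$opt
      check_finite_loss(res$loss %||% res$loss_beta, stage, ep, s0$id)
      losses <- c(losses, res$loss %||% res$loss_beta)
    }
    vdsc <- val_metric(model, data$val)
    if (!is.null(store))
      store <- update_priors(store, model, data$train, vdsc, elem)
    if (vdsc > best$dsc)
      best <- list(dsc = vdsc, params = model$params, bn = model$bn)
    history <- rbind(history,
                     data.frame(stage = stage, epoch = ep,
                                train_loss = mean(losses), val_dsc = vdsc,
                                best_dsc = if (!is.null(store))
                                  store$best_dsc else NA_real_))
  }
  model$params <- best$params
  model$bn <- best$bn
  list(model = model, history = history, best_dsc = best$dsc,
       store = store)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Stage I: train the V-Net with the transformation module frozen
#'
#' Only `vnet.*` parameter blocks receive updates; any `stn.*` blocks
#' are bitwise unchanged. The objective is
#' `alpha * L_dice(Y', Y) + gamma * L2`; per-epoch validation DSC is
#' logged and the weights with the highest validation DSC are retained.
#'
#' @param model a model holding at least the V-Net blocks.
#' @param data list with `train` and `val` sample lists (each sample:
#'   `id`, `volume`, `mask`).
#' @param cfg a [training_config()]; `cfg$stage_epochs[1]` epochs run.
#' @return list with `model` (best checkpoint) and `history`
#'   (per-epoch log).
#' @export
train_stage1 <- function(model, data, cfg = training_config()) {
  res <- with_seed(cfg$seed,
    run_epochs(model, data, cfg, stage = 1L, cfg$stage_epochs[1],
               step_stage1))
  res[c("model", "history", "best_dsc")]
}

#' Stage II: train the transformation module with the V-Net frozen
#'
#' Shape priors are generated once from the frozen V-Net's outputs at
#' stage entry and never regenerated within the stage; only `stn.*`
#' blocks are updated, under `beta * L_dice(Y'', Y) + gamma * L2`.
#'
#' @inheritParams train_stage1
#' @param elem structuring element for the priors.
#' @return list with `model`, `history`, and `store` (the fixed
#'   [prior_store()], whose `best_dsc` is the validation DSC of the
#'   frozen V-Net at stage entry).
#' @export
train_stage2 <- function(model, data, cfg = training_config(),
                         elem = structuring_element(cfg$prior_element)) {
  entry_dsc <- validation_dsc(model, data$val)
  em <- set_mode(model, "evaluation")
  gen_priors <- function(samples) {
    pr <- lapply(samples, function(s) {
      p <- vnet_forward_full(em, unclass(s$volume), training = FALSE)$prob
      suppressWarnings(generate_prior(probability_volume(p), elem))
    })
    names(pr) <- vapply(samples, function(s) s$id, character(1))
    pr
  }
  priors <- gen_priors(data$train)
  val_priors <- gen_priors(data$val)
  ## checkpoint selection within the stage must track what the stage
  ## trains: the hard Dice of the aligned output on validation subjects
  ## (the segmenter's own validation DSC is constant while it is frozen)
  val_aligned <- function(mod, val_set) {
    emod <- set_mode(mod, "evaluation")
    mean(vapply(val_set, function(s) {
      yp <- vnet_forward_full(emod, unclass(s$volume),
                              training = FALSE)$prob
      phi <- regress_affine(probability_volume(yp),
                            val_priors[[s$id]], emod)
      ypp <- apply_transform(probability_volume(yp), phi)
      bin <- suppressWarnings(otsu_binarize(ypp))
      dice_coefficient(bin, s$mask)
    }, numeric(1)))
  }
  res <- with_seed(cfg$seed + 1L,
    run_epochs(model, data, cfg, stage = 2L, cfg$stage_epochs[2],
               step_stage2, priors = priors, val_metric = val_aligned))
  list(model = res$model, history = res$history,
       store = prior_store(priors, min(max(entry_dsc, 0), 1)))
}

#' Stage III: joint training with dynamically updated priors
#'
#' All parameter blocks are updated under the full compound objective;
#' after every epoch [update_priors()] regenerates the priors whenever
#' the validation DSC improves on the best seen, so `best_dsc` is
#' monotone nondecreasing. The final model is the highest-validation-DSC
#' checkpoint.
#'
#' @inheritParams train_stage2
#' @param store the [prior_store()] from stage II.
#' @return list with `model`, `history`, `store`.
#' @export
train_stage3 <- function(model, data, store, cfg = training_config(),
                         elem = structuring_element(cfg$prior_element)) {
  res <- with_seed(cfg$seed + 2L,
    run_epochs(model, data, cfg, stage = 3L, cfg$stage_epochs[3],
               step_stage3, store = store, elem = elem))
  res[c("model", "history", "store", "best_dsc")]
}
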