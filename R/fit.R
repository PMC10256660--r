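#' Combine a V-Net and a transformation module into one model
#'
#' @param seg_spec a [segmenter_spec()].
#' @param reg_spec a [regressor_spec()].
#' @param seed integer seed for the initialization of both sub-networks.
#' @return A model holding both `vnet.*` and `stn.*` parameter blocks.
#' @export
st_vnet_model <- function(seg_spec, reg_spec, seed = 1L) {
  vn <- build_vnet(seg_spec, seed)
  st <- build_regressor(reg_spec, seg_spec$input_shape, seed + 1L)
  vn$stn_spec <- st$stn_spec
  vn$stn_input_shape <- st$stn_input_shape
  vn$stn_out_scale <- st$stn_out_scale
  vn$params <- c(vn$params, st$params)
  vn$bn <- c(vn$bn, st$bn)
  vn
}

#' Fit a shape-prior-constrained segmentation network
#'
#' Trains the full three-stage schedule on a cohort of volume/mask
#' pairs: stage I trains the V-Net alone, stage II trains the
#' transformation module against shape priors generated from the frozen
#' V-Net, and stage III fine-tunes everything jointly while the priors
#' are regenerated whenever the validation DSC improves. Held-out test
#' subjects (never seen during training) are evaluated with both the
#' stage-I V-Net and the final model, so the incremental value of the
#' shape-prior constraint is measured on the same split.
#'
#' @param cohort list of samples (`id`, `stratum`, `volume`, `mask`),
#'   e.g. from [generate_cohort()].
#' @param seg_spec a [segmenter_spec()]; defaults to the tiny profile
#'   sized to the first sample's grid.
#' @param reg_spec a [regressor_spec()]; defaults to the tiny widths.
#' @param cfg a [training_config()].
#' @param k folds for the stratified split; fold 1 is the internal
#'   validation set, the rest train.
#' @param test_frac fraction of subjects held out as the external test
#'   set.
#' @return An object of class `st_vnet` with components `model` (final
#'   checkpoint), `stage1_model` (V-Net-only baseline checkpoint),
#'   `history` (per-epoch log across stages), `split`, `store` (final
#'   priors), and `test_metrics` (per-subject [evaluate_masks()] results
#'   for both checkpoints).
#' @seealso [predict.st_vnet()], [summary.st_vnet()]
#' @export
st_vnet <- function(cohort,
                    seg_spec = segmenter_spec_tiny(dim(cohort[[1]]$volume)),
                    reg_spec = regressor_spec(c(8L, 16L, 32L, 64L)),
                    cfg = training_config(), k = 10L, test_frac = 0.10) {
  ids <- vapply(cohort, function(s) s$id, character(1))
  strata <- vapply(cohort, function(s) s$stratum %||% "all", character(1))
  split <- stratified_split(ids, strata, k = k, test_frac = test_frac,
                            seed = cfg$seed)
  by_id <- stats::setNames(cohort, ids)
  data <- list(train = by_id[unlist(split$folds[-1])],
               val = by_id[split$folds[[1]]])
  test_set <- by_id[split$test_ids]
  model <- st_vnet_model(seg_spec, reg_spec, seed = cfg$seed)
  s1 <- train_stage1(model, data, cfg)
  s2 <- train_stage2(s1$model, data, cfg)
  s3 <- train_stage3(s2$model, data, s2$store, cfg)
  history <- rbind(s1$history, s2$history, s3$history)
  test_metrics <- rbind(
    eval_on_set(s1$model, test_set, "vnet_stage1"),
    eval_on_set(s3$model, test_set, "st_vnet"))
  structure(list(model = s3$model, stage1_model = s1$model,
                 stage2_model = s2$model, history = history,
                 split = split, store = s3$store, cfg = cfg,
                 seg_spec = seg_spec, reg_spec = reg_spec,
                 test_metrics = test_metrics),
            class = "st_vnet")
}

eval_on_set <- function(model, samples, label) {
  if (!length(samples)) return(data.frame())
  rows <- lapply(samples, function(s) {
    pred <- predict_volume(model, s$volume)
    snsp <- suppressWarnings(sensitivity_specificity(pred$mask, s$mask))
    ## surface distances are undefined against an empty prediction
    sd <- tryCatch(surface_distances(pred$mask, s$mask,
                                     vol_spacing(s$mask)),
                   error = function(e) c(hd_mm = NA_real_,
                                         asd_mm = NA_real_))
    data.frame(model = label, id = s$id,
               stratum = s$stratum %||% "all",
               dsc = dice_coefficient(pred$mask, s$mask),
               sensitivity = unname(snsp[1]),
               specificity = unname(snsp[2]),
               hd_mm = unname(sd[1]), asd_mm = unname(sd[2]))
  })
  do.call(rbind, c(rows, make.row.names = FALSE))
}

## single-volume prediction: direct forward when the depth matches the
## spec, sliding window otherwise
predict_volume <- function(model, v) {
  em <- set_mode(model, "evaluation")
  depth <- em$spec$input_shape[3]
  prob <- if (dim(v)[3] == depth) {
    probability_volume(vnet_forward_full(em, unclass(v),
                                         training = FALSE)$prob,
                       spacing = vol_spacing(v), origin = vol_origin(v))
  } else sliding_window_predict(em, v)
  list(prob = prob, mask = suppressWarnings(otsu_binarize(prob)))
}

#' @export
print.st_vnet <- function(x, ...) {
  cat("Shape-prior-constrained V-Net (three-stage fit)\n")
  cat("  parameters: ", count_params(x$model), "\n", sep = "")
  cat("  epochs (stage I/II/III): ",
      paste(x$cfg$stage_epochs, collapse = "/"), "\n", sep = "")
  cat("  best validation DSC: ",
      signif(max(x$history$val_dsc), 4), "\n", sep = "")
  if (nrow(x$test_metrics)) {
    agg <- stats::aggregate(dsc ~ model, x$test_metrics, mean)
    for (i in seq_len(nrow(agg)))
      cat("  held-out mean DSC [", agg$model[i], "]: ",
          signif(agg$dsc[i], 4), "\n", sep = "")
  }
  invisible(x)
}

#' Summary of a fitted segmentation model
#'
#' @param object an `st_vnet` fit.
#' @param ... unused.
#' @return data frame of held-out test metrics aggregated per
#'   checkpoint (means over subjects), invisibly printed.
#' @export
summary.st_vnet <- function(object, ...) {
  tm <- object$test_metrics
  if (!nrow(tm)) {
    cat("no held-out test subjects\n")
    return(invisible(NULL))
  }
  agg <- stats::aggregate(cbind(dsc, sensitivity, specificity, hd_mm,
                                asd_mm) ~ model, tm, mean)
  cat("Held-out test performance (means over",
      length(unique(tm$id)), "subjects):\n")
  print(agg, digits = 4, row.names = FALSE)
  invisible(agg)
}

#' Predict a segmentation for a new volume
#'
#' Runs the final checkpoint in evaluation mode; volumes deeper than the
#' network's window are predicted by depth-wise sliding window with mean
#' fusion, then Otsu-binarized.
#'
#' @param object an `st_vnet` fit.
#' @param newdata an [intensity_volume()].
#' @param type `"mask"` (default) or `"prob"`.
#' @param ... unused.
#' @return A [binary_mask()] or [probability_volume()].
#' @export
predict.st_vnet <- function(object, newdata, type = c("mask", "prob"),
                            ...) {
  type <- match.arg(type)
  res <- predict_volume(object$model, newdata)
  if (type == "mask") res$mask else res$prob
}

#' Training curves of a fitted model
#'
#' Plots the per-epoch training loss and validation DSC, with stage
#' boundaries marked.
#'
#' @param x an `st_vnet` fit.
#' @param ... passed to [graphics::plot()].
#' @export
plot.st_vnet <- function(x, ...) {
  h <- x$history
  ep <- seq_len(nrow(h))
  old <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old))
  graphics::plot(ep, h$train_loss, type = "l", xlab = "epoch",
                 ylab = "training loss", main = "compound loss", ...)
  graphics::abline(v = cumsum(table(h$stage))[-3] + 0.5, lty = 3)
  graphics::plot(ep, h$val_dsc, type = "l", xlab = "epoch",
                 ylab = "validation DSC", main = "validation DSC", ...)
  graphics::abline(v = cumsum(table(h$stage))[-3] + 0.5, lty = 3)
  invisible(x)
}

#' Save / load a model checkpoint
#'
#' Checkpoints carry a format version tag, both architecture specs and
#' the initialization seed alongside the weights, so a saved model can
#' be rebuilt and verified.
#'
#' @param model a model object (or `st_vnet` fit, whose final model is
#'   saved).
#' @param path file path (`.rds`).
#' @return `path` (save) or the model (load).
#' @export
save_checkpoint <- function(model, path) {
  if (inherits(model, "st_vnet")) model <- model$model
  saveRDS(list(format = "stvnet-checkpoint-1", spec = model$spec,
               stn_spec = model$stn_spec,
               stn_input_shape = model$stn_input_shape,
               stn_out_scale = model$stn_out_scale,
               seed = model$seed, params = model$params, bn = model$bn),
          path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  if (!identical(ck$format, "stvnet-checkpoint-1"))
    stop("not a recognized checkpoint: ", path)
  structure(list(spec = ck$spec, stn_spec = ck$stn_spec,
                 stn_input_shape = ck$stn_input_shape, params = ck$params,
                 bn = ck$bn, stn_out_scale = ck$stn_out_scale,
                 mode = "evaluation", seed = ck$seed),
            class = "stvnet_model")
}
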