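#' Otsu binarization of a probability map
#'
#' Builds a 256-bin histogram of the probabilities over [0, 1] and picks
#' the class split maximizing the between-class variance; voxels at or
#' above the split value become foreground. A constant map carries no
#' separable classes and yields an all-background mask with a warning.
#'
#' @param p a [probability_volume()] (or array with values in [0, 1]).
#' @return A [binary_mask()]; the chosen threshold is attached as
#'   attribute `threshold`.
#' @export
otsu_binarize <- function(p) {
  x <- as.numeric(unclass(p))
  if (min(x) < 0 || max(x) > 1) stop("values must lie in [0, 1]")
  bins <- pmin(floor(x * 256), 255)
  h <- tabulate(bins + 1L, nbins = 256L)
  t_star <- otsu_split(h)
  if (is.na(t_star)) {
    warning("probability map has a single occupied class; ",
            "returning all-background mask")
    mask <- array(0, dim(p)[1:3])
    thr <- NA_real_
  } else {
    mask <- array(as.numeric(bins > t_star), dim(p)[1:3])
    thr <- (t_star + 1) / 256
  }
  out <- binary_mask(mask, spacing = vol_spacing(p), origin = vol_origin(p))
  attr(out, "threshold") <- thr
  out
}

## Between-class-variance maximizing split over 256 histogram bins;
## returns the 0-based index of the last class-0 bin, or NA when only a
## single bin is occupied.
otsu_split <- function(h) {
  h <- as.numeric(h) # counts can overflow integer arithmetic below
  n <- sum(h)
  if (sum(h > 0) < 2) return(NA_integer_)
  k <- seq_len(256) - 1
  w0 <- cumsum(h)[1:255]
  w1 <- n - w0
  mu0 <- cumsum(h * k)[1:255]
  mu_total <- sum(h * k)
  valid <- w0 > 0 & w1 > 0
  bcv <- rep(-Inf, 255)
  bcv[valid] <- (mu_total * w0[valid] / n - mu0[valid])^2 /
    (w0[valid] / n * w1[valid] / n) / n^2
  which.max(bcv) - 1L
}

#' Plan depth-wise sliding windows
#'
#' Enumerates window start offsets `0, step, ...` covering a volume of
#' `L` slices with windows of `depth` slices; with `step = 1` there are
#' `L - depth + 1` windows (e.g. 19 windows for a 50-slice volume at
#' depth 32).
#'
#' @param L slice count of the volume.
#' @param depth window depth in slices (default 32).
#' @param step offset increment (default 1).
#' @return A `window_plan`: list with 0-based `starts`, `depth`, `step`.
#' @export
plan_windows <- function(L, depth = 32L, step = 1L) {
  L <- as.integer(L); depth <- as.integer(depth); step <- as.integer(step)
  if (L < depth)
    stop("volume has ", L, " slices but the window depth is ", depth,
         "; zero-pad the volume or choose a smaller depth")
  starts <- seq.int(0L, L - depth, by = step)
  if (starts[length(starts)] != L - depth)
    starts <- c(starts, L - depth) # always cover the last slices
  structure(list(starts = starts, depth = depth, step = step),
            class = "window_plan")
}

#' Whole-volume prediction by depth-wise sliding window
#'
#' Runs the segmenter on every planned window along the slice axis and
#' fuses the overlapping predictions per voxel: arithmetic mean by
#' default (`fusion = "mean"`), or voxelwise maximum (`fusion = "max"`).
#'
#' @param model a model in evaluation or training mode (evaluation
#'   recommended for deterministic output), or a function mapping a
#'   window array to a probability array of the same shape (useful for
#'   stub predictors in tests).
#' @param v an [intensity_volume()] whose in-plane dims equal the spec's
#'   and whose slice count is at least the window depth.
#' @param fusion `"mean"` or `"max"`.
#' @param step window offset increment.
#' @param depth window depth; defaults to the model spec's slice depth
#'   (required when `model` is a function).
#' @return A [probability_volume()] with the input's shape.
#' @export
sliding_window_predict <- function(model, v, fusion = c("mean", "max"),
                                   step = 1L, depth = NULL) {
  fusion <- match.arg(fusion)
  d <- dim(v)
  if (is.function(model)) {
    if (is.null(depth)) stop("depth is required for a function predictor")
    forward <- model
  } else {
    spec <- model$spec
    if (!all(d[1:2] == spec$input_shape[1:2]))
      stop("in-plane dims (", d[1], ", ", d[2],
           ") do not match the segmenter spec (",
           spec$input_shape[1], ", ", spec$input_shape[2], ")")
    if (is.null(depth)) depth <- spec$input_shape[3]
    forward <- function(win)
      vnet_forward_full(model, win,
                        training = identical(model$mode, "training"))$prob
  }
  plan <- plan_windows(d[3], depth, step)
  acc <- array(0, d)
  cnt <- array(0, d)
  x <- unclass(v)
  for (s in plan$starts) {
    win <- x[, , (s + 1):(s + depth), drop = FALSE]
    pr <- forward(win)
    sl <- (s + 1):(s + depth)
    if (fusion == "mean") {
      acc[, , sl] <- acc[, , sl] + pr
      cnt[, , sl] <- cnt[, , sl] + 1
    } else {
      acc[, , sl] <- pmax(acc[, , sl], pr)
    }
  }
  out <- if (fusion == "mean") acc / pmax(cnt, 1) else acc
  probability_volume(out, spacing = vol_spacing(v), origin = vol_origin(v))
}
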