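#' Loss weights of the compound objective
#'
#' The training objective is
#' `alpha * L_DSC(Y', Y) + beta * L_DSC(Y'', Y) + gamma * ||W||^2`,
#' where `Y'` is the segmenter output, `Y''` the deformed output after
#' the shape-prior alignment, and the last term the L2 penalty over the
#' convolution and fully connected kernels. Defaults are the study
#' settings alpha = 1, beta = 0.1, gamma = 0.2.
#'
#' @param alpha,beta,gamma nonnegative scalars.
#' @return A `loss_weights` object.
#' @export
loss_weights <- function(alpha = 1, beta = 0.1, gamma = 0.2) {
  if (alpha < 0 || beta < 0 || gamma < 0)
    stop("loss weights must be nonnegative")
  structure(list(alpha = alpha, beta = beta, gamma = gamma),
            class = "loss_weights")
}

check_same_shape <- function(a, b) {
  if (!all(dim(a)[1:3] == dim(b)[1:3]))
    stop("shape mismatch: (", paste(dim(a)[1:3], collapse = ", "),
         ") vs (", paste(dim(b)[1:3], collapse = ", "), ")")
}

#' Dice similarity coefficient of two binary masks
#'
#' `2 |A n B| / (|A| + |B|)`. Two empty masks agree on "nothing" and
#' score 1.
#'
#' @param pred,truth [binary_mask()] objects (or 0/1 arrays) of equal
#'   shape.
#' @return score in [0, 1].
#' @export
dice_coefficient <- function(pred, truth) {
  check_same_shape(pred, truth)
  a <- as.numeric(unclass(pred))
  b <- as.numeric(unclass(truth))
  denom <- sum(a) + sum(b)
  if (denom == 0) return(1)
  2 * sum(a * b) / denom
}

DICE_EPS <- 1e-6

#' Dice loss (1 - DSC), hard or soft
#'
#' `mode = "hard"` binarizes the probability map with Otsu's method
#' before computing the overlap, exactly as the reported metric is
#' defined; this is used for evaluation. `mode = "soft"` replaces the
#' voxel counts with sums of probabilities (with a small smoothing term
#' in numerator and denominator), which keeps the loss differentiable
#' and is what gradient-based training minimizes.
#'
#' @param prob a [probability_volume()].
#' @param truth a [binary_mask()] of the same shape.
#' @param mode `"soft"` (training) or `"hard"` (reporting).
#' @return scalar loss.
#' @export
dice_loss <- function(prob, truth, mode = c("soft", "hard")) {
  mode <- match.arg(mode)
  check_same_shape(prob, truth)
  y <- as.numeric(unclass(truth))
  if (mode == "hard") {
    g <- as.numeric(unclass(otsu_binarize(prob)))
    denom <- sum(g) + sum(y)
    if (denom == 0) return(0)
    return(1 - 2 * sum(g * y) / denom)
  }
  p <- as.numeric(unclass(prob))
  1 - (2 * sum(p * y) + DICE_EPS) / (sum(p) + sum(y) + DICE_EPS)
}

## gradient of the soft dice loss w.r.t. the probability map
soft_dice_grad <- function(prob, truth) {
  p <- as.numeric(unclass(prob))
  y <- as.numeric(unclass(truth))
  num <- 2 * sum(p * y) + DICE_EPS
  den <- sum(p) + sum(y) + DICE_EPS
  g <- -(2 * y * den - num) / den^2
  array(g, dim(prob)[1:3])
}

#' L2 penalty over model kernels
#'
#' Sum of squared entries over the convolution, transpose-convolution
#' and fully connected kernels of both sub-networks; biases and
#' batch-norm scale/shift are excluded.
#'
#' @param model a model object.
#' @param average divide by the number of penalized entries. The raw
#'   sum is the printed form of the objective; the training code uses
#'   the per-weight average so that the penalty's scale is independent
#'   of the network size (a raw sum over millions of weights would
#'   dwarf the Dice terms at the stated weight `gamma = 0.2`).
#' @return scalar penalty.
#' @export
l2_penalty <- function(model, average = FALSE) {
  nm <- l2_block_names(model)
  s <- sum(vapply(nm, function(n) sum(model$params[[n]]^2), numeric(1)))
  if (average)
    s <- s / sum(vapply(nm, function(n) length(model$params[[n]]),
                        numeric(1)))
  s
}

l2_block_names <- function(model) {
  nm <- names(model$params)
  nm[grepl("\\.w$", nm)]
}

#' Compound training objective
#'
#' `alpha * L_DSC(Y', Y) + beta * L_DSC(Y'', Y) + gamma * l2_penalty`.
#' Terms are also returned separately (attribute `terms`) for logging.
#'
#' @param y_prime segmenter output ([probability_volume()]).
#' @param y_dprime deformed output ([probability_volume()]).
#' @param truth ground-truth [binary_mask()].
#' @param model model whose kernels enter the L2 term.
#' @param w a [loss_weights()].
#' @param mode Dice mode passed to [dice_loss()].
#' @return scalar loss with attribute `terms = c(dsc, dsc_aligned, l2)`.
#' @export
compound_loss <- function(y_prime, y_dprime, truth, model,
                          w = loss_weights(), mode = c("soft", "hard")) {
  mode <- match.arg(mode)
  t1 <- dice_loss(y_prime, truth, mode)
  t2 <- dice_loss(y_dprime, truth, mode)
  t3 <- l2_penalty(model)
  structure(w$alpha * t1 + w$beta * t2 + w$gamma * t3,
            terms = c(dsc = t1, dsc_aligned = t2, l2 = t3))
}
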