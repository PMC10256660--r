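#' Voxelwise sensitivity and specificity
#'
#' Sensitivity is the proportion of actual positives correctly
#' identified, `TP / (TP + FN)`; specificity the proportion of actual
#' negatives, `TN / (TN + FP)`. A side with no actual positives
#' (respectively negatives) yields `NaN` with a warning.
#'
#' @param pred,truth [binary_mask()] objects of equal shape.
#' @return named numeric `c(sensitivity, specificity)`.
#' @export
sensitivity_specificity <- function(pred, truth) {
  check_same_shape(pred, truth)
  p <- as.numeric(unclass(pred))
  y <- as.numeric(unclass(truth))
  tp <- sum(p * y)
  fn <- sum((1 - p) * y)
  tn <- sum((1 - p) * (1 - y))
  fp <- sum(p * (1 - y))
  sn <- if (tp + fn == 0) {
    warning("truth has no positive voxels; sensitivity undefined")
    NaN
  } else tp / (tp + fn)
  sp <- if (tn + fp == 0) {
    warning("truth has no negative voxels; specificity undefined")
    NaN
  } else tn / (tn + fp)
  c(sensitivity = sn, specificity = sp)
}

#' Surface voxels of a mask
#'
#' Foreground voxels with at least one face-adjacent (6-connected)
#' background neighbour; voxels on the grid boundary count as surface
#' (outside the grid is background).
#'
#' @param mask a [binary_mask()] or 0/1 array.
#' @return logical array of the mask's shape.
#' @export
surface_voxels <- function(mask) {
  m <- unclass(mask) > 0
  d <- dim(m)
  interior <- array(TRUE, d)
  shift_and <- function(acc, ax, by) {
    idx <- vector("list", 3)
    for (a in 1:3) idx[[a]] <- seq_len(d[a])
    pad <- array(FALSE, d)
    src <- idx; dst <- idx
    if (by > 0) { dst[[ax]] <- seq_len(d[ax] - by) + by
                  src[[ax]] <- seq_len(d[ax] - by) }
    else { dst[[ax]] <- seq_len(d[ax] + by)
           src[[ax]] <- seq_len(d[ax] + by) - by }
    pad[dst[[1]], dst[[2]], dst[[3]]] <- m[src[[1]], src[[2]], src[[3]]]
    acc & pad
  }
  for (ax in 1:3) {
    interior <- shift_and(interior, ax, 1L)
    interior <- shift_and(interior, ax, -1L)
  }
  m & !(m & interior)
}

#' Directed Hausdorff and average surface distance in mm
#'
#' Surfaces are extracted as 6-connectivity boundary voxels and scaled by
#' the voxel spacing. The directed Hausdorff distance is the maximum,
#' over prediction-surface points, of the distance to the nearest
#' truth-surface point; the directed average surface distance is the mean
#' of those distances. `symmetric = TRUE` returns the symmetric variants
#' (max of the two directed maxima; mean over the pooled point sets of
#' the distance to the other surface).
#'
#' @param pred,truth nonempty [binary_mask()] objects of equal shape.
#' @param spacing voxel spacing in mm (defaults to the masks' spacing).
#' @param symmetric return symmetric instead of directed values.
#' @return named numeric `c(hd_mm, asd_mm)`.
#' @export
surface_distances <- function(pred, truth, spacing = NULL,
                              symmetric = FALSE) {
  check_same_shape(pred, truth)
  if (sum(unclass(pred)) == 0) stop("prediction mask is empty")
  if (sum(unclass(truth)) == 0) stop("truth mask is empty")
  if (is.null(spacing)) spacing <- vol_spacing(pred)
  ps <- surface_points_mm(pred, spacing)
  ts <- surface_points_mm(truth, spacing)
  d_pt <- cpp_min_dists(ps, ts)
  if (!symmetric)
    return(c(hd_mm = max(d_pt), asd_mm = mean(d_pt)))
  d_tp <- cpp_min_dists(ts, ps)
  c(hd_mm = max(max(d_pt), max(d_tp)),
    asd_mm = mean(c(d_pt, d_tp)))
}

surface_points_mm <- function(mask, spacing) {
  s <- which(surface_voxels(mask), arr.ind = TRUE)
  ## 0-based voxel indices scaled to mm
  cbind((s[, 1] - 1) * spacing[1], (s[, 2] - 1) * spacing[2],
        (s[, 3] - 1) * spacing[3])
}

#' Full evaluation report for one prediction/truth pair
#'
#' @param pred,truth [binary_mask()] objects of equal shape.
#' @param spacing voxel spacing in mm.
#' @return A `metrics_report`: list with `dsc`, `sensitivity`,
#'   `specificity`, `hd_mm`, `asd_mm` (directed) and `hd_sym_mm`,
#'   `asd_sym_mm` (symmetric).
#' @export
evaluate_masks <- function(pred, truth, spacing = NULL) {
  snsp <- sensitivity_specificity(pred, truth)
  sd_dir <- surface_distances(pred, truth, spacing)
  sd_sym <- surface_distances(pred, truth, spacing, symmetric = TRUE)
  structure(list(dsc = dice_coefficient(pred, truth),
                 sensitivity = unname(snsp[1]),
                 specificity = unname(snsp[2]),
                 hd_mm = unname(sd_dir[1]), asd_mm = unname(sd_dir[2]),
                 hd_sym_mm = unname(sd_sym[1]),
                 asd_sym_mm = unname(sd_sym[2])),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("DSC %.4f  SN %.4f  SP %.4f  HD %.3f mm  ASD %.3f mm\n",
              x$dsc, x$sensitivity, x$specificity, x$hd_mm, x$asd_mm))
  cat(sprintf("  symmetric: HD %.3f mm  ASD %.3f mm\n", x$hd_sym_mm,
              x$asd_sym_mm))
  invisible(x)
}
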