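#' Structuring elements for shape-prior dilation
#'
#' The default prior generator dilates the binarized prediction with a
#' 5x5x5 all-ones cube, which enlarges the mask isotropically and
#' smooths its surface. A literal 5x5x5 diagonal line of voxels is
#' available as `"diag5"` for comparison; it grows the mask only along
#' the main diagonal.
#'
#' @param kind `"cube5"`, `"diag5"`, or `"custom"` with `support`.
#' @param support for `kind = "custom"`: a 3D 0/1 array with odd side
#'   lengths (origin at the centre).
#' @return A `structuring_element` object.
#' @export
structuring_element <- function(kind = c("cube5", "diag5", "custom"),
                                support = NULL) {
  kind <- match.arg(kind)
  if (kind == "cube5") support <- array(1L, c(5, 5, 5))
  if (kind == "diag5") {
    support <- array(0L, c(5, 5, 5))
    for (i in 1:5) support[i, i, i] <- 1L
  }
  if (is.null(support)) stop("custom elements need a support array")
  d <- dim(support)
  if (length(d) != 3 || any(d %% 2 == 0))
    stop("structuring element must be 3D with odd side lengths")
  if (sum(support != 0) == 0) stop("structuring element must be nonempty")
  structure(list(kind = kind, support = array(as.integer(support != 0), d)),
            class = "structuring_element")
}

#' Morphological dilation of a binary mask
#'
#' Set union of translates of the mask by the element's support offsets
#' (element origin at its centre, clipped to the grid).
#'
#' @param mask a [binary_mask()] or 0/1 array.
#' @param elem a [structuring_element()].
#' @return mask of the same class/shape.
#' @export
dilate_mask <- function(mask, elem = structuring_element("cube5")) {
  stopifnot(inherits(elem, "structuring_element"))
  m <- unclass(mask)
  out <- cpp_dilate3d(as.integer(m != 0), dim(m)[1:3], elem$support,
                      dim(elem$support))
  out <- array(as.numeric(out), dim(m)[1:3])
  if (is_binary_mask(mask))
    binary_mask(out, spacing = vol_spacing(mask), origin = vol_origin(mask))
  else out
}

#' Generate a shape prior from a network prediction
#'
#' Binarizes the probability map with Otsu's method, then dilates with
#' the structuring element. Because the element contains its origin, the
#' prior is always a voxelwise superset of the binarized prediction. An
#' empty binarized prediction produces an empty prior with a warning
#' (the prior then carries no constraint).
#'
#' @param pred a [probability_volume()].
#' @param elem a [structuring_element()].
#' @return A [binary_mask()] prior.
#' @export
generate_prior <- function(pred, elem = structuring_element("cube5")) {
  bin <- suppressWarnings(otsu_binarize(pred))
  if (sum(bin) == 0) {
    warning("binarized prediction is empty; prior carries no constraint")
    return(bin)
  }
  dilate_mask(bin, elem)
}

#' Store of per-sample shape priors with the best validation DSC
#'
#' @param priors named list of [binary_mask()] priors, keyed by sample
#'   id.
#' @param best_dsc best validation DSC seen so far (in [0, 1]).
#' @return A `prior_store` object.
#' @export
prior_store <- function(priors = list(), best_dsc = 0) {
  stopifnot(best_dsc >= 0, best_dsc <= 1)
  structure(list(priors = priors, best_dsc = best_dsc),
            class = "prior_store")
}

#' Dynamic prior update rule of the joint training stage
#'
#' If the current validation DSC improves on the stored best, every
#' training-sample prior is regenerated from the current segmenter
#' output (forward pass in evaluation mode followed by
#' [generate_prior()]) and `best_dsc` is raised; otherwise the store is
#' returned unchanged. `best_dsc` is therefore monotone nondecreasing
#' over a run.
#'
#' @param store a [prior_store()].
#' @param model the current model.
#' @param train_set list of samples, each with `$id` and `$volume`.
#' @param current_dsc validation DSC of the current epoch.
#' @param elem structuring element for [generate_prior()].
#' @return The (possibly updated) [prior_store()].
#' @export
update_priors <- function(store, model, train_set, current_dsc,
                          elem = structuring_element("cube5")) {
  stopifnot(inherits(store, "prior_store"),
            current_dsc >= 0, current_dsc <= 1)
  if (current_dsc <= store$best_dsc) return(store)
  eval_model <- set_mode(model, "evaluation")
  priors <- lapply(train_set, function(s) {
    pr <- vnet_forward_full(eval_model, unclass(s$volume),
                            training = FALSE)$prob
    suppressWarnings(generate_prior(probability_volume(pr), elem))
  })
  names(priors) <- vapply(train_set, function(s) as.character(s$id),
                          character(1))
  prior_store(priors, current_dsc)
}
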