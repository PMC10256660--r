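#' Intensity volumes and binary masks
#'
#' The package represents 3D scalar images as plain R arrays wrapped in a
#' light S3 class carrying physical voxel spacing (mm) and an origin (mm).
#' The grid indexing convention is fixed throughout: axis order
#' (row, column, slice) and 0-based voxel indices; all coordinates are
#' voxel indices unless a name carries the `_mm` suffix.
#'
#' @param data numeric 3D array (M x N x L).
#' @param spacing numeric length-3, voxel spacing in mm, all > 0.
#' @param origin numeric length-3, position of voxel (0,0,0) in mm.
#' @return An `intensity_volume` object: a 3D array with `spacing` and
#'   `origin` attributes.
#' @examples
#' v <- intensity_volume(array(rnorm(8 * 8 * 4), c(8, 8, 4)),
#'                       spacing = c(0.9, 0.9, 3))
#' dim(v)
#' @export
intensity_volume <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  data <- as_array3d(data)
  stopifnot(length(spacing) == 3, length(origin) == 3)
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing components must be finite and > 0")
  structure(data, spacing = spacing, origin = origin,
            class = "intensity_volume")
}

#' @param x object to coerce/test.
#' @rdname intensity_volume
#' @export
is_intensity_volume <- function(x) inherits(x, "intensity_volume")

#' Binary segmentation mask
#'
#' A 3D \{0,1\} grid with the same geometry conventions as
#' [intensity_volume()]. Values are validated to be exactly 0 or 1.
#'
#' @inheritParams intensity_volume
#' @return A `binary_mask` object.
#' @export
binary_mask <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  data <- as_array3d(data)
  u <- unique(as.vector(data))
  if (!all(u %in% c(0, 1)))
    stop("binary_mask values must be exactly 0 or 1")
  storage.mode(data) <- "double"
  spacing <- as.numeric(spacing)
  if (any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing components must be finite and > 0")
  structure(data, spacing = spacing, origin = as.numeric(origin),
            class = "binary_mask")
}

#' @rdname binary_mask
#' @export
is_binary_mask <- function(x) inherits(x, "binary_mask")

#' Per-voxel foreground probability map
#'
#' Values must lie in [0, 1]; geometry conventions as
#' [intensity_volume()].
#'
#' @inheritParams intensity_volume
#' @return A `probability_volume` object.
#' @export
probability_volume <- function(data, spacing = c(1, 1, 1),
                               origin = c(0, 0, 0)) {
  data <- as_array3d(data)
  rng <- range(data)
  if (rng[1] < 0 || rng[2] > 1)
    stop("probability values must lie in [0, 1]; got range [",
         signif(rng[1], 6), ", ", signif(rng[2], 6), "]")
  structure(data, spacing = as.numeric(spacing),
            origin = as.numeric(origin), class = "probability_volume")
}

#' @rdname probability_volume
#' @export
is_probability_volume <- function(x) inherits(x, "probability_volume")

as_array3d <- function(data) {
  data <- unclass(data)
  if (is.null(dim(data)) || length(dim(data)) != 3)
    stop("expected a 3D array, got dimensionality ",
         length(dim(data)))
  if (any(dim(data) < 1)) stop("all three dimensions must be >= 1")
  attributes(data) <- list(dim = dim(data))
  data
}

#' @export
print.intensity_volume <- function(x, ...) {
  cat("<intensity_volume> ", paste(dim(x), collapse = " x "),
      " voxels, spacing (", paste(signif(vol_spacing(x), 4), collapse = ", "),
      ") mm\n", sep = "")
  cat("  intensity range [", signif(min(x), 4), ", ", signif(max(x), 4),
      "]\n", sep = "")
  invisible(x)
}

#' @export
print.binary_mask <- function(x, ...) {
  cat("<binary_mask> ", paste(dim(x), collapse = " x "),
      " voxels, |foreground| = ", sum(x), "\n", sep = "")
  invisible(x)
}

#' @export
print.probability_volume <- function(x, ...) {
  cat("<probability_volume> ", paste(dim(x), collapse = " x "),
      " voxels, range [", signif(min(x), 4), ", ", signif(max(x), 4),
      "]\n", sep = "")
  invisible(x)
}

#' Voxel spacing and origin accessors
#'
#' @param x a volume/mask object created by this package.
#' @return numeric length-3 vector (mm).
#' @export
vol_spacing <- function(x) {
  s <- attr(x, "spacing")
  if (is.null(s)) c(1, 1, 1) else s
}

#' @rdname vol_spacing
#' @export
vol_origin <- function(x) {
  o <- attr(x, "origin")
  if (is.null(o)) c(0, 0, 0) else o
}

## keep class + geometry while replacing data
rewrap <- function(template, data) {
  structure(as_array3d(data), spacing = vol_spacing(template),
            origin = vol_origin(template), class = class(template))
}

#' Read a volume from a NIfTI file
#'
#' Reads a 3D scalar image with its header spacing and origin. Intensities
#' are returned as stored (after the format's own slope/intercept scaling,
#' which the reader applies); no further rescaling is done.
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @return An [intensity_volume()].
#' @seealso [write_volume()], [read_mask()]
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("cannot read volume: no such file: ", path)
  ext_ok <- grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)
  if (!ext_ok)
    stop("unsupported volume format for ", path,
         " (NIfTI .nii/.nii.gz is supported)")
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop("cannot read volume ", path, ": ",
                                           conditionMessage(e), call. = FALSE))
  d <- dim(img)
  if (length(d) != 3)
    stop("expected a 3D image in ", path, ", got ", length(d), "D")
  hdr <- RNifti::niftiHeader(img)
  spacing <- as.numeric(hdr$pixdim[2:4])
  origin <- as.numeric(RNifti::origin(img))
  if (length(origin) != 3 || any(!is.finite(origin))) origin <- c(0, 0, 0)
  intensity_volume(array(as.numeric(img), d), spacing = spacing,
                   origin = origin)
}

#' Write a volume or mask to NIfTI
#'
#' Masks are written with an integer datatype; intensity and probability
#' volumes as 32-bit float.
#'
#' @param v volume or mask object.
#' @param path output `.nii` / `.nii.gz` path.
#' @return `path`, invisibly.
#' @export
write_volume <- function(v, path) {
  dt <- if (is_binary_mask(v)) "uint8" else "float"
  arr <- array(as.numeric(v), dim(v))
  hdr <- RNifti::niftiHeader(RNifti::asNifti(arr, datatype = dt))
  hdr$pixdim[2:4] <- vol_spacing(v)
  RNifti::writeNifti(RNifti::asNifti(arr, reference = hdr,
                                     datatype = dt), path)
  invisible(path)
}

#' @rdname read_volume
#' @export
read_mask <- function(path) {
  v <- read_volume(path)
  binary_mask(array(as.numeric(v > 0.5), dim(v)), spacing = vol_spacing(v),
              origin = vol_origin(v))
}

#' Crop window specification
#'
#' A rectangular in-plane region of interest applied to every slice, in
#' voxel offsets (0-based).
#'
#' @param row_offset,col_offset 0-based offsets of the window corner.
#' @param height,width window extent in voxels (default 192 x 192, the
#'   in-plane size the segmentation network consumes).
#' @return A `crop_spec` object.
#' @export
crop_spec <- function(row_offset = 0L, col_offset = 0L,
                      height = 192L, width = 192L) {
  s <- list(row_offset = as.integer(row_offset),
            col_offset = as.integer(col_offset),
            height = as.integer(height), width = as.integer(width))
  if (s$height < 1 || s$width < 1) stop("crop extents must be >= 1")
  if (s$row_offset < 0 || s$col_offset < 0) stop("crop offsets must be >= 0")
  structure(s, class = "crop_spec")
}

#' Default middle-right crop window
#'
#' Convenience helper mirroring the study's manual placement: the window
#' sits in the right half of the slice, vertically centred.
#'
#' @param dims volume dims (M, N, L).
#' @param height,width window extent.
#' @return A [crop_spec()].
#' @export
default_crop_window <- function(dims, height = 192L, width = 192L) {
  row_offset <- max(0L, as.integer(floor((dims[1] - height) / 2)))
  col_offset <- max(0L, as.integer(dims[2] - width -
                                     floor((dims[2] / 2 - width) / 2)))
  if (col_offset + width > dims[2])
    col_offset <- max(0L, as.integer(dims[2] - width))
  crop_spec(row_offset, col_offset, height, width)
}

#' Crop the region of interest from a volume or mask
#'
#' Applying the same spec to a paired mask yields voxel-aligned outputs.
#'
#' @param v volume or mask.
#' @param spec a [crop_spec()].
#' @return Object of the same class, `height x width x L`.
#' @export
crop_roi <- function(v, spec) {
  stopifnot(inherits(spec, "crop_spec"))
  d <- dim(v)
  r1 <- spec$row_offset + spec$height
  c1 <- spec$col_offset + spec$width
  if (r1 > d[1] || c1 > d[2])
    stop("crop window [rows ", spec$row_offset, "..", r1 - 1, ", cols ",
         spec$col_offset, "..", c1 - 1, "] exceeds grid ",
         d[1], " x ", d[2])
  out <- unclass(v)[(spec$row_offset + 1):r1, (spec$col_offset + 1):c1, ,
                    drop = FALSE]
  sp <- vol_spacing(v)
  org <- vol_origin(v) + c(spec$row_offset, spec$col_offset, 0) * sp
  structure(as_array3d(out), spacing = sp, origin = org, class = class(v))
}
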