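#' Convert slice thickness by Fourier interpolation and decimation
#'
#' Reproduces the acquisition-side preprocessing used to convert
#' 2-mm-thick CT slices to 3-mm-thick slices: each consecutive group of
#' `group` slices (tiling, non-overlapping) is Fourier-interpolated along
#' the slice axis by a factor of `upsample` (zero-padded centred spectrum,
#' energy-preserving scaling, Nyquist-bin splitting for even lengths) and
#' the interpolated slices are then decimated by averaging runs of
#' `decimate` consecutive slices. With the defaults, three 2-mm slices
#' become six 1-mm slices and then two 3-mm slices, so the output has
#' `2 * L / 3` slices at 3 mm spacing.
#'
#' @param v an [intensity_volume()]; its slice count must be a multiple of
#'   `group`.
#' @param group slices per interpolation group (default 3).
#' @param upsample Fourier upsampling factor within a group (default 2).
#' @param decimate how many interpolated slices are averaged into one
#'   output slice (default 3).
#' @return An [intensity_volume()] with `L * upsample / decimate / 1`
#'   slices per the grouping arithmetic and slice spacing scaled by
#'   `decimate / upsample`.
#' @export
fourier_slice_resample <- function(v, group = 3L, upsample = 2L,
                                   decimate = 3L) {
  d <- dim(v)
  L <- d[3]
  if (L %% group != 0)
    stop("slice count ", L, " is not a multiple of the group size ", group)
  if ((group * upsample) %% decimate != 0)
    stop("group * upsample must be divisible by decimate")
  if (any(!is.finite(v))) stop("intensities must be finite")
  out_per_group <- group * upsample / decimate
  n_groups <- L / group
  Lout <- n_groups * out_per_group
  out <- array(0, c(d[1], d[2], Lout))
  x <- unclass(v)
  for (g in seq_len(n_groups)) {
    sl <- x[, , ((g - 1) * group + 1):(g * group), drop = FALSE]
    up <- fourier_upsample_axis3(sl, upsample)
    for (o in seq_len(out_per_group)) {
      idx <- ((o - 1) * decimate + 1):(o * decimate)
      acc <- up[, , idx[1]]
      for (t in idx[-1]) acc <- acc + up[, , t]
      out[, , (g - 1) * out_per_group + o] <- acc / decimate
    }
  }
  sp <- vol_spacing(v)
  intensity_volume(out, spacing = c(sp[1], sp[2], sp[3] * decimate / upsample),
                   origin = vol_origin(v))
}

## Zero-pad the centred spectrum along the 3rd axis: n -> n * factor
## samples. Even input lengths split the Nyquist bin symmetrically; output
## is scaled by `factor` so constants (the DC component) are preserved.
fourier_upsample_axis3 <- function(x, factor) {
  d <- dim(x)
  n <- d[3]
  m <- n * factor
  nvox <- d[1] * d[2]
  xm <- matrix(x, nrow = nvox, ncol = n)
  ## FFT each voxel's slice profile: mvfft works column-wise
  X <- t(stats::mvfft(t(xm)))
  Xp <- matrix(0 + 0i, nrow = nvox, ncol = m)
  half <- floor(n / 2)
  ## non-negative frequencies 0..half (for even n, bin `half` is Nyquist)
  pos <- seq_len(half + 1)
  Xp[, pos] <- X[, pos]
  if (n > 1) {
    if (n %% 2 == 0) {
      ## split the Nyquist bin between +half and -half
      Xp[, half + 1] <- X[, half + 1] / 2
      Xp[, m - half + 1] <- X[, half + 1] / 2
      if (half > 1)
        Xp[, (m - half + 2):m] <- X[, (half + 2):n]
    } else {
      Xp[, (m - half + 1):m] <- X[, (half + 2):n]
    }
  }
  y <- t(stats::mvfft(t(Xp), inverse = TRUE)) / n
  array(Re(y), c(d[1], d[2], m))
}
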