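#' Synthetic femur-like phantom specification
#'
#' The phantom emulates the structure of proximal-femur QCT volumes at
#' the level the segmentation pipeline needs: a femur-shaped foreground
#' (spherical head joined by an oblique cylindrical neck to a vertical
#' shaft), a brighter cortical shell of configurable thickness, a
#' soft-tissue background, additive Gaussian noise, and anisotropic
#' voxel spacing (slice spacing much larger than pixel size). The
#' `contrast` parameter scales the bone/soft-tissue intensity gap and
#' emulates the lower image contrast of low-bone-density subjects.
#'
#' @param grid voxel dims (M, N, L); default the tiny training grid
#'   `c(64, 64, 32)`.
#' @param spacing voxel spacing in mm; default `c(0.9, 0.9, 3)`.
#' @param head_radius femoral-head sphere radius in mm.
#' @param shaft_radius shaft cylinder radius in mm.
#' @param neck_angle angle of the neck axis against the shaft axis, in
#'   degrees.
#' @param cortical_thickness thickness of the bright shell in mm.
#' @param contrast scalar in (0, 1]; bone-vs-soft-tissue intensity
#'   separation.
#' @param noise_sigma standard deviation of additive Gaussian noise in
#'   intensity units (intensities are on a [0, 1]-ish scale).
#' @param seed integer seed making the phantom fully deterministic.
#' @return A `phantom_spec` object.
#' @export
phantom_spec <- function(grid = c(64L, 64L, 32L), spacing = c(0.9, 0.9, 3),
                         head_radius = 14, shaft_radius = 8,
                         neck_angle = 45, cortical_thickness = 2,
                         contrast = 1, noise_sigma = 0.02, seed = 1L) {
  if (head_radius <= 0 || shaft_radius <= 0)
    stop("degenerate geometry: radii must be > 0")
  if (contrast <= 0 || contrast > 1) stop("contrast must be in (0, 1]")
  if (noise_sigma < 0) stop("noise_sigma must be >= 0")
  structure(list(grid = as.integer(grid), spacing = as.numeric(spacing),
                 head_radius = head_radius, shaft_radius = shaft_radius,
                 neck_angle = neck_angle,
                 cortical_thickness = cortical_thickness,
                 contrast = contrast, noise_sigma = noise_sigma,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

## Distances (mm) from every voxel centre to the three geometric
## primitives; shared by the mask, the shell and the component helper.
phantom_distances <- function(spec) {
  d <- spec$grid; sp <- spec$spacing
  ext <- d * sp
  xs <- (seq_len(d[1]) - 1) * sp[1]
  ys <- (seq_len(d[2]) - 1) * sp[2]
  zs <- (seq_len(d[3]) - 1) * sp[3]
  X <- array(rep(xs, times = d[2] * d[3]), d)
  Y <- array(rep(rep(ys, each = d[1]), times = d[3]), d)
  Z <- array(rep(zs, each = d[1] * d[2]), d)
  ## shaft: vertical cylinder from mid-depth to the bottom of the grid
  p0 <- c(0.6 * ext[1], 0.6 * ext[2], 0.5 * ext[3])
  p1 <- c(p0[1], p0[2], ext[3])
  ## neck: oblique cylinder leaving the shaft top towards the head
  th <- spec$neck_angle * pi / 180
  dir <- c(-sin(th) / sqrt(2), -sin(th) / sqrt(2), -cos(th))
  neck_len <- 1.2 * spec$head_radius
  hc <- p0 + neck_len * dir
  seg_dist <- function(a, b) {
    u <- b - a
    len2 <- sum(u^2)
    t <- ((X - a[1]) * u[1] + (Y - a[2]) * u[2] + (Z - a[3]) * u[3]) / len2
    t <- pmin(pmax(t, 0), 1)
    sqrt((X - a[1] - t * u[1])^2 + (Y - a[2] - t * u[2])^2 +
           (Z - a[3] - t * u[3])^2)
  }
  list(head = sqrt((X - hc[1])^2 + (Y - hc[2])^2 + (Z - hc[3])^2),
       neck = seg_dist(p0, hc), shaft = seg_dist(p0, p1))
}

#' Component masks of the phantom geometry
#'
#' @param spec a [phantom_spec()].
#' @return list of 0/1 arrays `head`, `neck`, `shaft` (noise-free,
#'   clipped to the grid).
#' @export
phantom_geometry <- function(spec) {
  dist <- phantom_distances(spec)
  neck_radius <- 0.75 * spec$shaft_radius
  list(head = (dist$head <= spec$head_radius) + 0,
       neck = (dist$neck <= neck_radius) + 0,
       shaft = (dist$shaft <= spec$shaft_radius) + 0)
}

#' Generate one phantom volume/mask pair
#'
#' The mask is the union of the three primitives; the intensity volume
#' is a soft-tissue baseline (0.25) plus a contrast-scaled bone value
#' inside the mask (trabecular 0.25 + 0.5 contrast) with a brighter
#' cortical shell (0.25 + 0.75 contrast) within `cortical_thickness` of
#' the mask boundary, plus seeded Gaussian noise. Deterministic per
#' seed.
#'
#' @param spec a [phantom_spec()].
#' @return list with `volume` ([intensity_volume()]) and `mask`
#'   ([binary_mask()]).
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  dist <- phantom_distances(spec)
  neck_radius <- 0.75 * spec$shaft_radius
  t <- spec$cortical_thickness
  mask <- (dist$head <= spec$head_radius) |
    (dist$neck <= neck_radius) | (dist$shaft <= spec$shaft_radius)
  core <- (dist$head <= spec$head_radius - t) |
    (dist$neck <= neck_radius - t) | (dist$shaft <= spec$shaft_radius - t)
  shell <- mask & !core
  img <- array(0.25, spec$grid)
  img[core] <- 0.25 + 0.5 * spec$contrast
  img[shell] <- 0.25 + 0.75 * spec$contrast
  if (spec$noise_sigma > 0)
    img <- img + with_seed(spec$seed,
                           array(stats::rnorm(length(img),
                                              sd = spec$noise_sigma),
                                 spec$grid))
  list(volume = intensity_volume(img, spacing = spec$spacing),
       mask = binary_mask(array(as.numeric(mask), spec$grid),
                          spacing = spec$spacing))
}

#' Generate a stratified synthetic cohort
#'
#' Samples per-phantom geometry jitter (radii and neck angle within
#' +/-10%) and assigns strata: high-contrast "male-like" subjects
#' (contrast 0.9-1.0) and low-contrast "female-like" subjects (contrast
#' 0.5-0.65), mirroring the direction of the reported sex difference in
#' bone density and image contrast. Stratum counts follow
#' `strata_fractions` by largest remainder. When `vary_slices` is TRUE,
#' per-subject slice counts are drawn uniformly from `slice_range`
#' (exercising sliding-window inference); otherwise the base grid depth
#' is kept (fixed-shape training).
#'
#' @param n number of subjects (>= 2).
#' @param strata_fractions length-2 fractions for (male-like,
#'   female-like).
#' @param base_spec a [phantom_spec()] providing grid/spacing and base
#'   geometry.
#' @param seed integer seed; the cohort is reproducible.
#' @param vary_slices draw per-subject slice counts from `slice_range`.
#' @param slice_range inclusive range of slice counts, default
#'   `c(37, 95)`.
#' @return list of samples: each has `id`, `stratum`, `volume`, `mask`.
#' @export
generate_cohort <- function(n, strata_fractions = c(0.5, 0.5),
                            base_spec = phantom_spec(), seed = 1L,
                            vary_slices = FALSE, slice_range = c(37L, 95L)) {
  stopifnot(n >= 2, length(strata_fractions) == 2)
  fr <- strata_fractions / sum(strata_fractions)
  n_male <- largest_remainder(fr, n)[1]
  strata <- c(rep("male-like", n_male), rep("female-like", n - n_male))
  with_seed(seed, {
    samples <- vector("list", n)
    for (i in seq_len(n)) {
      sp <- base_spec
      jit <- function(x) x * stats::runif(1, 0.9, 1.1)
      sp$head_radius <- jit(base_spec$head_radius)
      sp$shaft_radius <- jit(base_spec$shaft_radius)
      sp$neck_angle <- jit(base_spec$neck_angle)
      sp$contrast <- if (strata[i] == "male-like")
        stats::runif(1, 0.9, 1.0) else stats::runif(1, 0.5, 0.65)
      if (vary_slices)
        sp$grid[3] <- sample(seq.int(slice_range[1], slice_range[2]), 1)
      sp$seed <- sample.int(.Machine$integer.max, 1)
      ph <- generate_phantom(sp)
      samples[[i]] <- list(id = sprintf("subj%03d", i),
                           stratum = strata[i], volume = ph$volume,
                           mask = ph$mask)
    }
    samples
  })
}

## integer allocation of n over fractions, largest remainder
largest_remainder <- function(fr, n) {
  raw <- fr * n
  base <- floor(raw)
  short <- n - sum(base)
  if (short > 0) {
    ord <- order(raw - base, decreasing = TRUE)
    base[ord[seq_len(short)]] <- base[ord[seq_len(short)]] + 1
  }
  as.integer(base)
}
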