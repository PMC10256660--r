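test_that("phantoms are deterministic per seed and validate their
           geometry", {
  sp <- phantom_spec(seed = 9)
  a <- generate_phantom(sp)
  b <- generate_phantom(sp)
  expect_identical(unclass(a$volume), unclass(b$volume))
  expect_identical(unclass(a$mask), unclass(b$mask))
  c <- generate_phantom(phantom_spec(seed = 10))
  expect_false(identical(unclass(a$volume), unclass(c$volume)))
  expect_error(phantom_spec(head_radius = 0), "degenerate")
  expect_error(phantom_spec(contrast = 0), "contrast")
  expect_error(phantom_spec(noise_sigma = -1), "noise")
})

test_that("noise-free full-contrast phantoms are perfectly separable", {
  ph <- generate_phantom(phantom_spec(noise_sigma = 0, contrast = 1))
  img <- unclass(ph$volume)
  m <- unclass(ph$mask) == 1
  expect_gt(min(img[m]), max(img[!m]))
})

test_that("the head-sphere voxel count matches the analytic volume", {
  sp <- phantom_spec(grid = c(48, 48, 48), spacing = c(1, 1, 1),
                     head_radius = 12, noise_sigma = 0)
  geo <- phantom_geometry(sp)
  expect_equal(sum(geo$head), 4 / 3 * pi * 12^3, tolerance = 0.05)
})

test_that("masks are a single 6-connected component", {
  for (seed in 1:3) {
    ph <- generate_phantom(phantom_spec(seed = seed))
    lab <- stvnet:::cpp_label6(as.integer(unclass(ph$mask) != 0),
                               dim(ph$mask))
    expect_equal(max(lab), 1)
  }
})

test_that("lowering contrast narrows the noiseless intensity gap", {
  gaps <- vapply(c(1, 0.7, 0.4, 0.2), function(ct) {
    ph <- generate_phantom(phantom_spec(noise_sigma = 0, contrast = ct))
    img <- unclass(ph$volume); m <- unclass(ph$mask) == 1
    mean(img[m]) - mean(img[!m])
  }, numeric(1))
  expect_true(all(diff(gaps) < 0))
})

test_that("cohorts honour stratum fractions, reproduce per seed, and can
           vary slice counts", {
  co <- generate_cohort(10, c(0.5, 0.5),
                        base_spec = phantom_spec(grid = c(16, 16, 16)),
                        seed = 3)
  expect_equal(sum(vapply(co, `[[`, "", "stratum") == "male-like"), 5)
  co2 <- generate_cohort(10, c(0.5, 0.5),
                         base_spec = phantom_spec(grid = c(16, 16, 16)),
                         seed = 3)
  expect_identical(unclass(co[[4]]$volume), unclass(co2[[4]]$volume))
  ## the study cohort proportions: 216 women + 181 men of 397
  n_male <- stvnet:::largest_remainder(c(181 / 397, 216 / 397), 397)
  expect_identical(n_male, c(181L, 216L))
  vs <- generate_cohort(4, base_spec = phantom_spec(grid = c(8, 8, 48)),
                        seed = 5, vary_slices = TRUE,
                        slice_range = c(37, 95))
  Ls <- vapply(vs, function(s) dim(s$volume)[3], integer(1))
  expect_true(all(Ls >= 37 & Ls <= 95))
  expect_gt(length(unique(Ls)), 1)
})

test_that("male-like strata carry higher contrast than female-like", {
  co <- generate_cohort(8, c(0.5, 0.5),
                        base_spec = phantom_spec(grid = c(24, 24, 16),
                                                 noise_sigma = 0),
                        seed = 11)
  gap <- function(s) {
    img <- unclass(s$volume); m <- unclass(s$mask) == 1
    mean(img[m]) - mean(img[!m])
  }
  g_m <- vapply(co[vapply(co, `[[`, "", "stratum") == "male-like"],
                gap, numeric(1))
  g_f <- vapply(co[vapply(co, `[[`, "", "stratum") == "female-like"],
                gap, numeric(1))
  expect_gt(min(g_m), max(g_f))
})
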