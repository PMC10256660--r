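test_that("window planning: worked example, exact fit, and the padding
           error", {
  expect_length(plan_windows(50, 32, 1)$starts, 19)
  p <- plan_windows(32, 32)
  expect_identical(p$starts, 0L)
  expect_error(plan_windows(31, 32), "zero-pad")
})

test_that("window count is L - depth + 1 for unit steps", {
  set.seed(50)
  for (L in sample(32:200, 12))
    expect_length(plan_windows(L, 32, 1)$starts, L - 32 + 1)
})

test_that("a single exact-fit window equals one forward pass", {
  m <- set_mode(build_vnet(segmenter_spec_tiny(c(16, 16, 8)), seed = 1),
                "evaluation")
  set.seed(51)
  v <- intensity_volume(array(runif(16 * 16 * 8), c(16, 16, 8)))
  fused <- sliding_window_predict(m, v)
  direct <- vnet_forward(m, v)
  expect_equal(unclass(fused), unclass(direct))
})

test_that("fusion of a constant stub is constant; overlap averaging
           matches the coverage-count oracle", {
  set.seed(52)
  v <- intensity_volume(array(runif(4 * 4 * 40), c(4, 4, 40)))
  stub_const <- function(win) array(0.37, dim(win))
  out <- sliding_window_predict(stub_const, v, depth = 32)
  expect_true(all(abs(unclass(out) - 0.37) < 1e-12))
  ## stub returning its (scaled) window start offset as a constant
  stub_offset <- local({
    i <- 0
    function(win) {
      i <<- i + 1
      array((i - 1) / 100, dim(win)) # start offset s = i - 1 for step 1
    }
  })
  v34 <- intensity_volume(array(0, c(4, 4, 34)))
  out34 <- sliding_window_predict(stub_offset, v34, depth = 32)
  ## coverage-count oracle: slice z is covered by starts
  ## max(0, z-32) .. min(2, z-1) (1-based z), fused by the mean
  for (z in c(1, 2, 15, 33, 34)) {
    starts <- seq.int(max(0, z - 32), min(2, z - 1))
    expect_equal(out34[1, 1, z], mean(starts / 100), tolerance = 1e-12,
                 info = paste("slice", z))
  }
  ## probabilities stay within [0,1] under mean fusion
  stub_rand <- function(win) array(runif(length(win)), dim(win))
  outr <- sliding_window_predict(stub_rand, v34, depth = 32)
  expect_true(min(outr) >= 0 && max(outr) <= 1)
})

test_that("slice-reversed inputs give slice-reversed outputs under a
           slice-symmetric stub", {
  set.seed(53)
  v <- array(runif(4 * 4 * 40), c(4, 4, 40))
  stub <- function(win) { # symmetric per-window map: depends on voxel value
    1 / (1 + exp(-win))
  }
  out <- sliding_window_predict(stub, intensity_volume(v), depth = 32)
  out_rev <- sliding_window_predict(stub,
                                    intensity_volume(v[, , 40:1]),
                                    depth = 32)
  expect_equal(unclass(out_rev), unclass(out)[, , 40:1],
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("max fusion bounds mean fusion from above", {
  set.seed(54)
  m <- set_mode(build_vnet(segmenter_spec_tiny(c(16, 16, 8)), seed = 2),
                "evaluation")
  v <- intensity_volume(array(runif(16 * 16 * 12), c(16, 16, 12)))
  fm <- sliding_window_predict(m, v, fusion = "mean")
  fx <- sliding_window_predict(m, v, fusion = "max")
  expect_true(all(unclass(fx) - unclass(fm) >= -1e-12))
})

test_that("Otsu binarization separates bimodal maps and matches the
           exhaustive search on random maps", {
  half <- array(c(rep(0.1, 32), rep(0.9, 32)), c(4, 4, 4))
  b <- otsu_binarize(probability_volume(half))
  thr <- attr(b, "threshold")
  expect_gt(thr, 0.1); expect_lt(thr, 0.9)
  expect_equal(unclass(b), (half > 0.5) + 0, ignore_attr = TRUE)
  set.seed(55)
  for (rep in 1:5) {
    vals <- runif(600)^sample(c(0.5, 1, 2), 1)
    p <- probability_volume(array(vals[1:512], c(8, 8, 8)))
    got <- otsu_binarize(p)
    t_star <- oracle_otsu_split(as.numeric(unclass(p)))
    expect_equal(attr(got, "threshold"), (t_star + 1) / 256)
  }
  expect_warning(z <- otsu_binarize(probability_volume(
    array(0, c(4, 4, 4)))), "single occupied class")
  expect_equal(sum(z), 0)
})
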