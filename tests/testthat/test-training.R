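test_that("stratified splits preserve proportions exactly and
           reproducibly", {
  ids <- sprintf("s%03d", 1:100)
  strata <- rep(c("male-like", "female-like"), c(60, 40))
  sp <- stratified_split(ids, strata, k = 9, test_frac = 0.1, seed = 2)
  test_strata <- sp$strata[sp$test_ids]
  expect_equal(sum(test_strata == "male-like"), 6)
  expect_equal(sum(test_strata == "female-like"), 4)
  ## partition: disjoint folds covering everything outside the test set
  all_ids <- c(sp$test_ids, unlist(sp$folds))
  expect_setequal(all_ids, ids)
  expect_equal(anyDuplicated(all_ids), 0)
  ## per-fold proportions within one sample of 60:40
  for (f in sp$folds) {
    fs <- sp$strata[f]
    expect_lte(abs(sum(fs == "male-like") / length(fs) - 0.6),
               1 / length(fs) + 1e-9)
  }
  sp2 <- stratified_split(ids, strata, k = 9, test_frac = 0.1, seed = 2)
  expect_identical(sp, sp2)
  expect_false(identical(
    sp, stratified_split(ids, strata, k = 9, test_frac = 0.1, seed = 3)))
})

test_that("a 397-subject cohort with 216:181 strata yields a ~40-subject
           proportional test set", {
  ids <- sprintf("q%03d", 1:397)
  strata <- rep(c("w", "m"), c(216, 181))
  sp <- stratified_split(ids, strata, k = 10, test_frac = 0.1, seed = 1)
  ts <- sp$strata[sp$test_ids]
  expect_length(sp$test_ids, 40)
  expect_equal(sum(ts == "w"), 22) # largest remainder of 21.6 : 18.1
  expect_equal(sum(ts == "m"), 18)
})

test_that("too many folds for a stratum is an error", {
  expect_error(stratified_split(letters[1:10], rep(c("a", "b"), 5),
                                k = 10, test_frac = 0.1, seed = 1),
               "folds were requested")
})

test_that("augmentation with zero probabilities is the identity", {
  set.seed(60)
  co <- tiny_cohort(1, grid = c(16L, 16L, 16L))
  cfg0 <- augment_config(p_rotate = 0, p_mirror = 0, p_brightness = 0,
                         p_gamma = 0, p_noise = 0)
  out <- augment(co[[1]]$volume, co[[1]]$mask, cfg0)
  expect_identical(unclass(out$volume), unclass(co[[1]]$volume))
  expect_identical(unclass(out$mask), unclass(co[[1]]$mask))
})

test_that("mirror flips are involutions", {
  set.seed(61)
  x <- array(rnorm(6 * 7 * 8), c(6, 7, 8))
  for (ax in 1:3)
    expect_identical(stvnet:::flip_axis(stvnet:::flip_axis(x, ax), ax), x)
})

test_that("rotation keeps the mask binary and roughly volume-preserving
           for a convex blob", {
  set.seed(62)
  blob <- random_blob_mask(c(16, 16, 16), r_frac = 0.28)
  v <- intensity_volume(unclass(blob) * 0.5 + 0.25)
  cfg <- augment_config(p_rotate = 1, p_mirror = 0, p_brightness = 0,
                        p_gamma = 0, p_noise = 0)
  for (rep in 1:5) {
    out <- augment(v, blob, cfg)
    m <- unclass(out$mask)
    expect_true(all(m %in% c(0, 1)))
    expect_lt(abs(sum(m) - sum(blob)) / sum(blob), 0.15)
  }
})

test_that("brightness, gamma and noise touch the volume but never the
           mask", {
  set.seed(63)
  co <- tiny_cohort(1, grid = c(16L, 16L, 16L))
  cfg <- augment_config(p_rotate = 0, p_mirror = 0, p_brightness = 1,
                        p_gamma = 1, p_noise = 1)
  out <- augment(co[[1]]$volume, co[[1]]$mask, cfg)
  expect_identical(unclass(out$mask), unclass(co[[1]]$mask))
  expect_false(identical(unclass(out$volume), unclass(co[[1]]$volume)))
})

test_that("two fits with identical seeds produce identical logs", {
  co <- tiny_cohort(8, grid = c(16L, 16L, 16L), seed = 64)
  cfg <- training_config(stage_epochs = c(1, 1, 1), seed = 5)
  run <- function() {
    st_vnet(co, seg_spec = segmenter_spec_tiny(c(16, 16, 16),
                                               base_width = 2),
            reg_spec = regressor_spec(c(2, 2, 2, 2)),
            cfg = cfg, k = 3, test_frac = 0.25)
  }
  f1 <- run()
  f2 <- run()
  expect_identical(f1$history, f2$history)
  expect_identical(f1$model$params, f2$model$params)
})

test_that("the fitted object exposes print/summary/predict/plot", {
  co <- tiny_cohort(8, grid = c(16L, 16L, 16L), seed = 65)
  cfg <- training_config(stage_epochs = c(1, 1, 1), seed = 5)
  fit <- st_vnet(co, seg_spec = segmenter_spec_tiny(c(16, 16, 16),
                                                    base_width = 2),
                 reg_spec = regressor_spec(c(2, 2, 2, 2)),
                 cfg = cfg, k = 3, test_frac = 0.25)
  expect_s3_class(fit, "st_vnet")
  expect_output(print(fit), "three-stage")
  expect_output(s <- summary(fit), "Held-out")
  expect_true(all(c("vnet_stage1", "st_vnet") %in% s$model))
  pr <- predict(fit, co[[1]]$volume, type = "prob")
  expect_s3_class(pr, "probability_volume")
  mk <- predict(fit, co[[1]]$volume)
  expect_s3_class(mk, "binary_mask")
  ## deeper volume goes through the sliding window
  deep <- tiny_cohort(1, grid = c(16L, 16L, 24L), seed = 66)[[1]]$volume
  mk2 <- suppressWarnings(predict(fit, deep))
  expect_identical(dim(mk2), dim(deep))
  tmp <- tempfile(fileext = ".png")
  grDevices::png(tmp); plot(fit); grDevices::dev.off()
  expect_true(file.exists(tmp)); unlink(tmp)
})
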