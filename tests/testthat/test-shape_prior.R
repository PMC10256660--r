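test_that("structuring elements validate and the literal diagonal is
           available", {
  cube <- structuring_element("cube5")
  expect_equal(sum(cube$support), 125)
  diag5 <- structuring_element("diag5")
  expect_equal(sum(diag5$support), 5)
  expect_error(structuring_element("custom",
                                   support = array(1, c(4, 5, 5))), "odd")
  expect_error(structuring_element("custom",
                                   support = array(0, c(3, 3, 3))),
               "nonempty")
})

test_that("an interior voxel dilated by the 5^3 cube becomes a 125-voxel
           cube; an empty map stays empty", {
  p <- array(0, c(11, 11, 11)); p[6, 6, 6] <- 1
  prior <- generate_prior(probability_volume(p))
  expect_equal(sum(prior), 125)
  expect_true(all(unclass(prior)[4:8, 4:8, 4:8] == 1))
  expect_warning(e <- generate_prior(probability_volume(
    array(0, c(8, 8, 8)))), "empty")
  expect_equal(sum(e), 0)
})

test_that("dilation equals the union-of-translates oracle and always
           contains its input", {
  set.seed(40)
  elems <- list(structuring_element("cube5"),
                structuring_element("diag5"),
                structuring_element("custom",
                                    support = array(
                                      as.integer(runif(27) < 0.5 |
                                        seq_len(27) == 14), c(3, 3, 3))))
  for (el in elems) {
    m <- unclass(random_mask(c(16, 16, 16), p = 0.05))
    got <- dilate_mask(m, el)
    expect_equal(got, oracle_dilate(m, el$support))
    if (el$support[(dim(el$support)[1] + 1) / 2,
                   (dim(el$support)[2] + 1) / 2,
                   (dim(el$support)[3] + 1) / 2] == 1)
      expect_true(all(got >= m)) # superset when the element has its origin
  }
})

test_that("prior volume is monotone in the element size and repeated
           dilation grows until the boundary", {
  m <- array(0, c(15, 15, 15)); m[8, 8, 8] <- 1
  cube3 <- structuring_element("custom", support = array(1, c(3, 3, 3)))
  cube5 <- structuring_element("cube5")
  expect_lt(sum(dilate_mask(m, cube3)), sum(dilate_mask(m, cube5)))
  once <- dilate_mask(m, cube5)
  twice <- dilate_mask(once, cube5)
  expect_gt(sum(twice), sum(once))
  expect_true(all(twice >= once))
})

test_that("update_priors regenerates only on improvement and best_dsc is
           monotone", {
  cohort <- tiny_cohort(3, seed = 41)
  model <- set_mode(build_vnet(segmenter_spec_tiny(c(32, 32, 16)),
                               seed = 1), "evaluation")
  store0 <- suppressWarnings(
    update_priors(prior_store(), model, cohort, current_dsc = 0.4))
  expect_equal(store0$best_dsc, 0.4)
  expect_length(store0$priors, 3)
  ## no-improvement branch returns the store object unchanged
  same <- update_priors(store0, model, cohort, current_dsc = 0.4)
  expect_identical(same, store0)
  worse <- update_priors(store0, model, cohort, current_dsc = 0.1)
  expect_identical(worse, store0)
  ## improvement regenerates and raises best_dsc
  store1 <- suppressWarnings(
    update_priors(store0, model, cohort, current_dsc = 0.7))
  expect_equal(store1$best_dsc, 0.7)
  ## induction: a sequence of epochs never lowers best_dsc
  best <- numeric(0)
  st <- prior_store()
  for (d in c(0.2, 0.5, 0.3, 0.6, 0.6, 0.9)) {
    st <- suppressWarnings(update_priors(st, model, cohort, d))
    best <- c(best, st$best_dsc)
  }
  expect_true(all(diff(best) >= 0))
})
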