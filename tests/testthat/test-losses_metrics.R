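test_that("Dice coefficient: perfect, disjoint, half overlap, empties,
           symmetry", {
  m0 <- array(0, c(4, 4, 4))
  a <- m0; a[1:2, 1, 1] <- 1
  b <- m0; b[2:3, 1, 1] <- 1
  dj <- m0; dj[4, 4, 4] <- 1
  expect_equal(dice_coefficient(a, a), 1)
  expect_equal(dice_coefficient(a, dj), 0)
  expect_equal(dice_coefficient(a, b), 0.5) # overlap 1 of 2+2
  expect_equal(dice_coefficient(m0, m0), 1) # both empty: agree on nothing
  set.seed(30)
  x <- random_mask(c(6, 6, 6))
  y <- random_mask(c(6, 6, 6))
  expect_equal(dice_coefficient(x, y), dice_coefficient(y, x))
  expect_true(dice_coefficient(x, y) >= 0 && dice_coefficient(x, y) <= 1)
  expect_error(dice_coefficient(x, random_mask(c(5, 6, 6))), "mismatch")
})

test_that("dice_loss: exact prediction, total disagreement, and the
           hard mode equals 1 - dice(otsu(prob), truth)", {
  set.seed(31)
  y <- random_mask(c(8, 8, 8), p = 0.4)
  exact <- probability_volume(unclass(y))
  expect_lt(dice_loss(exact, y, "soft"), 1e-5)
  expect_lt(dice_loss(exact, y, "hard"), 1e-12)
  flipped <- probability_volume(1 - unclass(y))
  expect_gt(dice_loss(flipped, y, "hard"), 1 - 1e-12)
  p <- probability_volume(array(runif(512), c(8, 8, 8)))
  expect_equal(dice_loss(p, y, "hard"),
               1 - dice_coefficient(otsu_binarize(p), y))
})

test_that("soft dice approaches hard dice as probabilities polarize", {
  set.seed(32)
  y <- random_mask(c(8, 8, 8), p = 0.4)
  base <- array(runif(512), c(8, 8, 8))
  for (sharp in c(1, 4, 16, 64)) {
    p <- 1 / (1 + exp(-sharp * (unclass(y) - 0.5) * 4 -
                        (base - 0.5) / sharp))
    p <- probability_volume(array(p, c(8, 8, 8)))
    if (sharp == 64)
      expect_equal(dice_loss(p, y, "soft"), dice_loss(p, y, "hard"),
                   tolerance = 1e-3)
  }
})

test_that("l2_penalty sums squared kernel entries, excluding biases and
           batch-norm parameters", {
  fake <- list(params = list("a.conv.w" = c(3, 4), "a.conv.b" = c(100),
                             "a.bn.gamma" = c(5), "a.bn.beta" = c(7)))
  expect_equal(l2_penalty(fake), 25)
  expect_equal(l2_penalty(fake, average = TRUE), 12.5)
  fake0 <- list(params = list("k.w" = numeric(3)))
  expect_equal(l2_penalty(fake0), 0)
  ## enumeration oracle over a real tiny model
  m <- build_vnet(segmenter_spec_tiny(c(8, 8, 8)), seed = 2)
  manual <- 0
  for (nm in names(m$params))
    if (endsWith(nm, ".w"))
      for (v in as.numeric(m$params[[nm]])) manual <- manual + v * v
  expect_equal(l2_penalty(m), manual)
})

test_that("compound loss reduces to its parts and matches the
           term-by-term weighted sum", {
  set.seed(33)
  y <- random_mask(c(8, 8, 8), p = 0.4)
  yp <- probability_volume(array(runif(512), c(8, 8, 8)))
  ypp <- probability_volume(array(runif(512), c(8, 8, 8)))
  m <- build_vnet(segmenter_spec_tiny(c(8, 8, 8)), seed = 1)
  perfect <- probability_volume(unclass(y))
  expect_equal(as.numeric(compound_loss(perfect, perfect, y, m,
                                        loss_weights(0, 0, 0), "hard")), 0)
  ## alpha-only degenerates to the plain Dice loss
  expect_equal(as.numeric(compound_loss(yp, ypp, y, m,
                                        loss_weights(1, 0, 0), "soft")),
               dice_loss(yp, y, "soft"))
  ## study weights: hand-computed weighted sum of the three terms
  w <- loss_weights(1, 0.1, 0.2)
  expect_equal(as.numeric(compound_loss(yp, ypp, y, m, w, "soft")),
               1 * dice_loss(yp, y, "soft") +
                 0.1 * dice_loss(ypp, y, "soft") + 0.2 * l2_penalty(m))
  ## additivity/homogeneity in the weights
  l1 <- as.numeric(compound_loss(yp, ypp, y, m, loss_weights(2, 0, 0)))
  l2 <- as.numeric(compound_loss(yp, ypp, y, m, loss_weights(0, 3, 0)))
  l3 <- as.numeric(compound_loss(yp, ypp, y, m, loss_weights(0, 0, 4)))
  expect_equal(as.numeric(compound_loss(yp, ypp, y, m,
                                        loss_weights(2, 3, 4))),
               l1 + l2 + l3, tolerance = 1e-12)
})

test_that("sensitivity/specificity: perfect, all-positive, degenerate
           and random cases", {
  y <- array(0, c(4, 4, 4)); y[1:2, , ] <- 1
  expect_equal(unname(sensitivity_specificity(y, y)), c(1, 1))
  ones <- array(1, c(4, 4, 4))
  expect_equal(unname(sensitivity_specificity(ones, y)), c(1, 0))
  expect_warning(r <- sensitivity_specificity(y, array(0, c(4, 4, 4))),
                 "sensitivity")
  expect_true(is.nan(r[["sensitivity"]]))
  set.seed(34)
  for (rep in 1:3) {
    p <- unclass(random_mask(c(10, 10, 10)))
    t <- unclass(random_mask(c(10, 10, 10)))
    cm <- oracle_confusion(p, t)
    expect_equal(unname(sensitivity_specificity(p, t)),
                 c(cm["tp"] / (cm["tp"] + cm["fn"]),
                   cm["tn"] / (cm["tn"] + cm["fp"])),
                 ignore_attr = TRUE)
  }
})

test_that("surface distances: identical masks, single-voxel pairs with
           anisotropic spacing, and the all-pairs oracle", {
  set.seed(35)
  m <- random_blob_mask(c(10, 10, 10))
  expect_equal(unname(surface_distances(m, m, c(1, 1, 1))), c(0, 0))
  ## two single-voxel "surfaces" 3 slices apart at 3 mm slices
  a <- array(0, c(5, 5, 7)); a[3, 3, 2] <- 1
  b <- array(0, c(5, 5, 7)); b[3, 3, 5] <- 1
  expect_equal(unname(surface_distances(a, b, c(1, 1, 3))), c(9, 9))
  expect_error(surface_distances(array(0, c(5, 5, 7)), b), "empty")
  for (rep in 1:3) {
    p <- unclass(random_blob_mask(c(12, 12, 12), r_frac = 0.3))
    q <- unclass(random_blob_mask(c(12, 12, 12), r_frac = 0.25))
    o <- oracle_surface_dists(p, q, c(0.9, 0.9, 3))
    got <- surface_distances(p, q, c(0.9, 0.9, 3))
    expect_equal(unname(got), unname(o))
    ## directed max >= directed mean, always
    expect_gte(got[["hd_mm"]], got[["asd_mm"]])
  }
})

test_that("evaluate_masks bundles directed and symmetric variants", {
  set.seed(36)
  p <- random_blob_mask(c(12, 12, 12), r_frac = 0.3,
                        spacing = c(0.9, 0.9, 3))
  t <- random_blob_mask(c(12, 12, 12), r_frac = 0.28,
                        spacing = c(0.9, 0.9, 3))
  r <- evaluate_masks(p, t)
  expect_s3_class(r, "metrics_report")
  expect_gte(r$hd_sym_mm, r$hd_mm - 1e-12)
  expect_true(all(is.finite(unlist(r))))
})
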