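test_that("a fresh regressor emits the identity transform,
           deterministically", {
  d <- c(32, 32, 16)
  m <- set_mode(build_regressor(regressor_spec(c(8, 16, 32, 64)), d,
                                seed = 1), "evaluation")
  set.seed(20)
  yp <- probability_volume(array(runif(prod(d)), d))
  pr <- random_mask(d)
  phi <- regress_affine(yp, pr, m)
  expect_equal(phi$phi, cbind(diag(3), 0), ignore_attr = TRUE)
  expect_length(affine_to_vector(phi), 12)
  phi2 <- regress_affine(yp, pr, m)
  expect_identical(phi$phi, phi2$phi)
  expect_error(regress_affine(yp, random_mask(c(16, 16, 16)), m),
               "shapes differ")
})

test_that("affine_grid implements source = phi (target, 1)", {
  shape <- c(4, 5, 6)
  g_id <- affine_grid(identity_affine(), shape)
  tgt <- attr(g_id, "target")
  expect_equal(unclass(g_id)[, 1:3], tgt, ignore_attr = TRUE)
  ## pure translation in x
  g_tx <- affine_grid(affine_transform(cbind(diag(3), c(1, 0, 0))), shape)
  expect_equal(g_tx[, 1], tgt[, 1] + 1)
  expect_equal(g_tx[, 2:3], tgt[, 2:3], ignore_attr = TRUE)
  ## scaling row: phi11 = 2 maps target x = 3 to source x = 6
  phi_s <- affine_transform(rbind(c(2, 0, 0, 0), c(0, 1, 0, 0),
                                  c(0, 0, 1, 0)))
  g_s <- affine_grid(phi_s, shape)
  row <- which(tgt[, 1] == 3 & tgt[, 2] == 0 & tgt[, 3] == 0)
  expect_equal(unname(g_s[row, ]), c(6, 0, 0))
})

test_that("trilinear sampling: identity is exact and half-integer
           coordinates average neighbours", {
  set.seed(21)
  vol <- array(runif(5 * 5 * 5), c(5, 5, 5))
  g <- affine_grid(identity_affine(), c(5, 5, 5))
  expect_equal(unclass(trilinear_sample(vol, g)), vol)
  g2 <- affine_grid(affine_transform(cbind(diag(3), c(0.5, 0, 0))),
                    c(5, 5, 5))
  out <- trilinear_sample(vol, g2)
  expect_equal(out[1, 2, 3], (vol[1, 2, 3] + vol[2, 2, 3]) / 2)
  expect_equal(out[3, 1, 4], (vol[3, 1, 4] + vol[4, 1, 4]) / 2)
})

test_that("the fast sampler equals the literal triple-sum on random
           affine grids", {
  set.seed(22)
  for (rep in 1:5) {
    d <- rep(sample(6:8, 1), 3)
    vol <- array(runif(prod(d)), d)
    phi <- affine_transform(cbind(diag(3) + matrix(rnorm(9, 0, 0.1), 3),
                                  rnorm(3, 0, 1)))
    g <- affine_grid(phi, d)
    fast <- as.vector(unclass(trilinear_sample(vol, g)))
    expect_lt(max(abs(fast - oracle_trilinear(vol, unclass(g)[, 1:3]))),
              1e-9)
  }
})

test_that("sampling is linear in the source volume and preserves [0,1]", {
  set.seed(23)
  d <- c(6, 6, 6)
  u <- array(runif(216), d)
  v <- array(runif(216), d)
  phi <- affine_transform(cbind(diag(3) + matrix(rnorm(9, 0, 0.05), 3),
                                rnorm(3, 0, 0.5)))
  g <- affine_grid(phi, d)
  lhs <- trilinear_sample(2.5 * u - 1.2 * v, g)
  rhs <- 2.5 * unclass(trilinear_sample(u, g)) -
    1.2 * unclass(trilinear_sample(v, g))
  expect_equal(unclass(lhs), rhs, tolerance = 1e-9)
  p <- probability_volume(u)
  out <- trilinear_sample(p, g)
  expect_true(min(out) >= 0 && max(out) <= 1)
})

test_that("sample_jacobians: identity weights, zero-weight far voxels,
           and finite-difference agreement", {
  set.seed(24)
  d <- c(5, 5, 5)
  vol <- array(runif(125), d)
  ## identity: full weight on the matching voxel
  gi <- affine_grid(identity_affine(), d)
  ji <- sample_jacobians(vol, gi)
  expect_true(all(abs(rowSums(ji$weights) - 1) < 1e-12))
  w_on_self <- ji$weights[cbind(seq_len(125),
                                max.col(ji$weights, "first"))]
  expect_true(all(abs(w_on_self - 1) < 1e-12))
  ## hat kernel support: at most the 8 enclosing nodes carry weight
  phi <- affine_transform(cbind(diag(3), c(0.37, -0.21, 0.43)))
  g <- affine_grid(phi, d)
  j <- sample_jacobians(vol, g)
  expect_true(all(j$weights >= 0 & j$weights <= 1))
  ## coordinate partials vs central finite differences
  co <- unclass(g)[, 1:3]
  h <- 1e-4
  rows <- sample(nrow(co), 20)
  for (r in rows) {
    for (ax in 1:3) {
      cp <- co[r, , drop = FALSE]; cp[ax] <- cp[ax] + h
      cm <- co[r, , drop = FALSE]; cm[ax] <- cm[ax] - h
      fd <- (stvnet:::cpp_trilinear_fwd(vol, d, cp) -
               stvnet:::cpp_trilinear_fwd(vol, d, cm)) / (2 * h)
      expect_equal(j$dcoords[r, ax], fd, tolerance = 1e-4,
                   ignore_attr = TRUE)
    }
  }
})

test_that("apply_transform: identity, integer shifts and inverse
           round-trips behave as index arithmetic predicts", {
  set.seed(25)
  d <- c(12, 12, 12)
  blob <- random_blob_mask(d, r_frac = 0.22)
  yp <- probability_volume(unclass(blob))
  expect_equal(unclass(apply_transform(yp, identity_affine())),
               unclass(yp))
  ## translation: target (x,y,z) samples source (x+2,y,z), i.e. the
  ## content moves two voxels towards lower x, zero-filled at the edge
  phi <- affine_transform(cbind(diag(3), c(2, 0, 0)))
  shifted <- apply_transform(yp, phi)
  expect_equal(unclass(shifted)[1:10, , ], unclass(yp)[3:12, , ])
  expect_true(all(unclass(shifted)[11:12, , ] == 0))
  ## smooth interior-supported blob survives a there-and-back
  ## non-integer warp within interpolation tolerance
  ctr <- (d - 1) / 2
  xs <- seq_len(d[1]) - 1
  d2 <- outer(outer((xs - ctr[1])^2, (xs - ctr[2])^2, "+"),
              (xs - ctr[3])^2, "+")
  smooth <- exp(-d2 / (2 * 2.5^2))
  A <- diag(3) * 1.05
  t0 <- c(0.4, -0.3, 0.2)
  fwd <- affine_transform(cbind(A, t0))
  inv <- affine_transform(cbind(solve(A), -solve(A) %*% t0))
  back <- apply_transform(apply_transform(probability_volume(smooth),
                                          fwd), inv)
  expect_lt(max(abs(unclass(back) - smooth)), 0.15)
})

test_that("the compound loss is differentiable end-to-end through the
           transformation module", {
  set.seed(26)
  d <- c(8, 8, 8)
  m <- build_regressor(regressor_spec(c(2, 3, 4, 5)), d, seed = 11)
  ## move off the identity so no sampling coordinate sits on a kernel
  ## node (the interpolant is non-smooth there by construction)
  for (nm in names(m$params))
    m$params[[nm]] <- m$params[[nm]] +
      rnorm(length(m$params[[nm]]), sd = 0.02)
  yp <- array(runif(prod(d)), d)
  prior <- array(as.numeric(runif(prod(d)) > 0.6), d)
  truth <- array(as.numeric(runif(prod(d)) > 0.5), d)
  lossf <- function(mm) {
    sf <- stvnet:::stn_forward_full(mm, yp, prior, training = TRUE)
    g <- affine_grid(affine_transform(sf$phi_vec), d)
    ypp <- array(stvnet:::cpp_trilinear_fwd(yp, d,
                                            stvnet:::unclass_grid(g)), d)
    stvnet:::dice_loss_raw_soft(ypp, truth)
  }
  sf <- stvnet:::stn_forward_full(m, yp, prior, training = TRUE,
                                  keep_cache = TRUE)
  g <- affine_grid(affine_transform(sf$phi_vec), d)
  co <- stvnet:::unclass_grid(g)
  ypp <- array(stvnet:::cpp_trilinear_fwd(yp, d, co), d)
  bw <- stvnet:::cpp_trilinear_bwd(yp, d, co,
                                   stvnet:::soft_dice_grad(ypp, truth))
  gphi <- as.vector(t(crossprod(bw$gcoords, cbind(attr(g, "target"), 1))))
  sg <- stvnet:::stn_backward(m, sf$cache, gphi)
  h <- 1e-6
  set.seed(27)
  for (nm in names(m$params)) {
    for (t in sample(length(m$params[[nm]]),
                     min(3, length(m$params[[nm]])))) {
      m2 <- m; m2$params[[nm]][t] <- m$params[[nm]][t] + h
      m3 <- m; m3$params[[nm]][t] <- m$params[[nm]][t] - h
      fd <- (lossf(m2) - lossf(m3)) / (2 * h)
      ga <- sg$grads[[nm]][t]
      expect_lt(abs(ga - fd) / max(abs(ga), abs(fd), 1e-6), 1e-3)
    }
  }
})
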