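## Independent reference implementations used as oracles. These are kept
## deliberately literal (triple sums, all-pairs scans, exhaustive
## searches) and share no code with the package internals they check.

## Eq.-style literal hat-kernel triple sum over every source voxel
oracle_trilinear <- function(vol, coords) {
  d <- dim(vol)
  out <- numeric(nrow(coords))
  ms <- seq_len(d[1]) - 1
  ns <- seq_len(d[2]) - 1
  ls <- seq_len(d[3]) - 1
  for (i in seq_len(nrow(coords))) {
    wx <- pmax(0, 1 - abs(coords[i, 1] - ms))
    wy <- pmax(0, 1 - abs(coords[i, 2] - ns))
    wz <- pmax(0, 1 - abs(coords[i, 3] - ls))
    out[i] <- sum(vol * (wx %o% wy %o% wz))
  }
  out
}

## dilation as an explicit union of mask translates
oracle_dilate <- function(mask, elem) {
  d <- dim(mask)
  ed <- dim(elem)
  ctr <- (ed + 1) / 2
  out <- array(0, d)
  for (a in seq_len(ed[1])) for (b in seq_len(ed[2]))
    for (cc in seq_len(ed[3])) {
      if (elem[a, b, cc] == 0) next
      off <- c(a, b, cc) - ctr
      for (i in seq_len(d[1])) for (j in seq_len(d[2]))
        for (k in seq_len(d[3])) {
          if (mask[i, j, k] == 0) next
          t <- c(i, j, k) + off
          if (all(t >= 1) && all(t <= d)) out[t[1], t[2], t[3]] <- 1
        }
    }
  out
}

## voxel-enumeration confusion matrix
oracle_confusion <- function(pred, truth) {
  tp <- fp <- tn <- fn <- 0
  for (i in seq_along(pred)) {
    if (pred[i] == 1 && truth[i] == 1) tp <- tp + 1
    if (pred[i] == 1 && truth[i] == 0) fp <- fp + 1
    if (pred[i] == 0 && truth[i] == 0) tn <- tn + 1
    if (pred[i] == 0 && truth[i] == 1) fn <- fn + 1
  }
  c(tp = tp, fp = fp, tn = tn, fn = fn)
}

## surface voxels by literal 6-neighbour scan (outside grid = background)
oracle_surface <- function(mask) {
  d <- dim(mask)
  out <- array(FALSE, d)
  nb <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
              c(0, 0, 1), c(0, 0, -1))
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    if (mask[i, j, k] == 0) next
    for (q in 1:6) {
      t <- c(i, j, k) + nb[q, ]
      if (any(t < 1) || any(t > d) || mask[t[1], t[2], t[3]] == 0) {
        out[i, j, k] <- TRUE
        break
      }
    }
  }
  out
}

## directed HD/ASD by all-pairs nearest neighbour on the two surfaces
oracle_surface_dists <- function(pred, truth, spacing) {
  ps <- which(oracle_surface(pred), arr.ind = TRUE)
  ts <- which(oracle_surface(truth), arr.ind = TRUE)
  pm <- sweep(ps - 1, 2, spacing, "*")
  tm <- sweep(ts - 1, 2, spacing, "*")
  dmin <- apply(pm, 1, function(p)
    sqrt(min(colSums((t(tm) - p)^2))))
  c(hd = max(dmin), asd = mean(dmin))
}

## exhaustive 256-bin between-class-variance search
oracle_otsu_split <- function(vals) {
  bins <- pmin(floor(vals * 256), 255)
  h <- tabulate(bins + 1L, nbins = 256L)
  n <- sum(h)
  best <- -Inf
  best_t <- NA_integer_
  for (t in 0:254) {
    idx0 <- 1:(t + 1)
    w0 <- sum(h[idx0]) / n
    w1 <- 1 - w0
    if (w0 == 0 || w1 == 0) next
    mu0 <- sum(h[idx0] * (idx0 - 1)) / sum(h[idx0])
    idx1 <- (t + 2):256
    mu1 <- sum(h[idx1] * (idx1 - 1)) / sum(h[idx1])
    bcv <- w0 * w1 * (mu0 - mu1)^2
    if (bcv > best) { best <- bcv; best_t <- t }
  }
  best_t
}

## centred zero-padding DFT interpolation of a length-3 profile to 6
## samples followed by explicit triple averaging (one slice group)
oracle_group_resample <- function(profile3) {
  n <- 3; m <- 6
  j <- 0:(n - 1)
  F <- exp(-2i * pi * outer(j, j) / n)
  X <- as.vector(F %*% profile3)      # freqs 0, 1, 2(= -1)
  Xp <- complex(m)
  Xp[1] <- X[1]                        # DC
  Xp[2] <- X[2]                        # +1
  Xp[m] <- X[3]                        # -1
  jj <- 0:(m - 1)
  Fi <- exp(2i * pi * outer(jj, jj) / m)
  y <- Re(as.vector(Fi %*% Xp)) / n    # scale preserves constants
  c(mean(y[1:3]), mean(y[4:6]))
}

## small helpers shared across tests
random_mask <- function(dims, p = 0.3, spacing = c(1, 1, 1)) {
  binary_mask(array(as.numeric(stats::runif(prod(dims)) < p), dims),
              spacing = spacing)
}

random_blob_mask <- function(dims, r_frac = 0.3, spacing = c(1, 1, 1)) {
  ctr <- (dims - 1) / 2 + stats::runif(3, -1, 1)
  r <- r_frac * min(dims)
  xs <- seq_len(dims[1]) - 1
  ys <- seq_len(dims[2]) - 1
  zs <- seq_len(dims[3]) - 1
  d2 <- outer(outer((xs - ctr[1])^2, (ys - ctr[2])^2, "+"),
              (zs - ctr[3])^2, "+")
  binary_mask(array(as.numeric(d2 <= r^2), dims), spacing = spacing)
}

tiny_cohort <- function(n, grid = c(32L, 32L, 16L), seed = 7L) {
  generate_cohort(max(n, 2), base_spec = phantom_spec(grid = grid,
                                                      head_radius = 8,
                                                      shaft_radius = 5),
                  seed = seed)[seq_len(n)]
}
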