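# brute-force masked Pearson over all cyclic shifts: the independent oracle
# for the FFT path
brute_cc_shifts <- function(P, S) {
  nt <- nrow(P$data)
  vapply(0:(nt - 1), function(k) {
    idx <- ((seq_len(nt) - 1 + k) %% nt) + 1
    Sk <- S$data[idx, , drop = FALSE]
    Mk <- S$valid[idx, , drop = FALSE]
    j <- P$valid & Mk
    if (sum(j) < 2) return(NA_real_)
    a <- P$data[j]; b <- Sk[j]
    if (stats::var(a) == 0 || stats::var(b) == 0) return(NA_real_)
    stats::cor(a, b)
  }, 0)
}

mkpolar <- function(data, valid) {
  structure(list(data = data, valid = valid, r = seq_len(ncol(data)),
                 theta = 2 * pi * (seq_len(nrow(data)) - 1) / nrow(data)),
            class = "polar_image")
}

test_that("pearson_cc matches hand-computed values and affine invariance", {
  x <- c(1, 2, 3, 4)
  expect_equal(pearson_cc(x, c(2, 4, 6, 8)), 1)
  expect_equal(pearson_cc(x, c(4, 3, 2, 1)), -1)
  expect_equal(pearson_cc(x, c(1, 3, 2, 4)), 0.8)
  expect_equal(pearson_cc(x, 3 * x + 7), 1)
  expect_equal(pearson_cc(x, -x), -1)
  expect_true(is.na(pearson_cc(x, rep(2, 4))))          # zero variance
  expect_true(is.na(pearson_cc(x, x, valid = c(TRUE, FALSE, FALSE, FALSE))))
  set.seed(1)
  a <- rnorm(50); b <- rnorm(50); v <- runif(50) > 0.3
  expect_equal(pearson_cc(a, b, v), cor(a[v], b[v]))
})

test_that("FFT shift profile equals the brute-force loop to 1e-10", {
  set.seed(21)
  nt <- 32; nr <- 6
  for (trial in 1:100) {
    # alternate between irregular and angularly invariant (radial) masks
    mk <- if (trial %% 2) matrix(runif(nt * nr) > 0.25, nt, nr)
    else matrix(rep(runif(nr) > 0.25, each = nt), nt, nr)
    P <- mkpolar(matrix(rnorm(nt * nr, sd = 3), nt, nr),
                 matrix(runif(nt * nr) > 0.25, nt, nr))
    S <- mkpolar(matrix(rnorm(nt * nr, sd = 3), nt, nr), mk)
    got <- ccmax_over_gamma(P, S)$cc
    want <- brute_cc_shifts(P, S)
    expect_identical(is.na(got), is.na(want))
    expect_lt(max(abs(got - want), na.rm = TRUE), 1e-10)
  }
})

test_that("shift of a polar image is recovered exactly", {
  set.seed(2)
  nt <- 64; nr <- 9
  P <- mkpolar(matrix(rnorm(nt * nr), nt, nr), matrix(TRUE, nt, nr))
  for (k in c(0, 1, 17, 63)) {
    S <- mkpolar(P$data[((seq_len(nt) - 1 - k) %% nt) + 1, , drop = FALSE],
                 matrix(TRUE, nt, nr))
    r <- ccmax_over_gamma(P, S)
    expect_equal(r$cc_max, 1, tolerance = 1e-12)
    expect_equal(r$gamma, 2 * pi * k / nt)
  }
})

test_that("polar transform: rotation is a cyclic shift; structure maps to rows", {
  n <- 33; nt <- 8
  ctr <- (n + 1) / 2
  x <- matrix(seq_len(n) - ctr, n, n)
  y <- t(x)
  r <- sqrt(x^2 + y^2); th <- atan2(y, x)
  set.seed(14)
  img <- matrix(rnorm(n * n), n, n)
  # a quarter-turn of the pixel grid is an exact permutation, and nt = 8
  # makes it exactly two angular bins: the polar image must shift cyclically
  img_rot <- t(img)[n:1, ]
  p1 <- to_polar(img, NULL, n_r = 10, n_theta = nt)
  p2 <- to_polar(img_rot, NULL, n_r = 10, n_theta = nt)
  k <- nt / 4
  shifted <- p2$data[((seq_len(nt) - 1 + k) %% nt) + 1, ]
  expect_equal(p1$data, shifted, tolerance = 1e-12)
  # constant image stays constant
  pc <- to_polar(matrix(5, n, n), NULL, n_r = 8, n_theta = 16)
  expect_true(all(abs(pc$data[pc$valid] - 5) < 1e-12))
  # bright ring maps to a single bright radial band
  ring <- exp(-(r - 9)^2)
  pr <- to_polar(ring, NULL, n_r = 15, n_theta = 16)
  prof <- colMeans(pr$data)
  expect_equal(which.max(prof), which.min(abs(pr$r - 9)))
  expect_error(to_polar(img, NULL, n_r = 40, n_theta = 8), "half-width")
})

test_that("slice_volume matches a plain-loop trilinear oracle and isotropy", {
  set.seed(12)
  n <- 24; dq <- 0.01
  vol <- intensity_volume(array(rnorm(n^3)^2, c(n, n, n)), dq)
  g <- tiny_geometry(10)
  ew <- ewald_map(g)
  o <- sample_random(1)[[1]]
  sl <- slice_volume(vol, o, ew)
  # independent scalar-loop trilinear interpolation at valid pixels
  ctr <- n / 2 + 1
  vpx <- which(sl$valid, arr.ind = TRUE)
  set.seed(1)
  sel_px <- vpx[sample(nrow(vpx), 6), ]
  for (ipx in seq_len(6)) {
    px <- sel_px[ipx, ]
    qv <- c(ew$qx[px[1], px[2]], ew$qy[px[1], px[2]], ew$qz[px[1], px[2]])
    pt <- as.vector(o$R %*% qv) / dq + ctr
    i0 <- floor(pt); f <- pt - i0
    val <- 0
    for (dz in 0:1) for (dy in 0:1) for (dx in 0:1) {
      w <- prod(ifelse(c(dx, dy, dz) == 1, f, 1 - f))
      val <- val + w * vol$data[i0[1] + dx, i0[2] + dy, i0[3] + dz]
    }
    expect_equal(sl$data[px[1], px[2]], val, tolerance = 1e-12)
  }
  # volume constant on spheres gives a radially symmetric slice
  ax <- q_axis(n, dq)
  rr <- sqrt(outer(outer(ax^2, ax^2, "+"), ax^2, "+"))
  # smooth on the voxel scale so interpolation error is subordinate
  iso <- intensity_volume(exp(-rr^2 / (2 * (8 * dq)^2)), dq)
  s1 <- slice_volume(iso, orientation(0, 0, 0), ew)
  s2 <- slice_volume(iso, sample_random(1)[[1]], ew)
  j <- s1$valid & s2$valid   # cube-boundary validity is orientation-dependent
  expect_lt(max(abs(s1$data[j] - s2$data[j])) / max(s1$data), 1e-2)
  # pixels beyond the volume are invalid, not an error
  tiny_vol <- intensity_volume(array(1, c(4, 4, 4)), dq = 1e-4)
  s3 <- slice_volume(tiny_vol, orientation(0, 0, 0), ew)
  expect_true(any(!s3$valid))
})

test_that("CC table equals exhaustive slice-by-slice correlation", {
  set.seed(31)
  g <- tiny_geometry(12, beamstop = 2)
  nt <- 16
  pspec <- polar_spec(g, n_theta = nt)
  grid <- sample_grid(0.7)
  vols <- list(
    intensity_volume(array(runif(20^3), c(20, 20, 20)), 0.012),
    intensity_volume(array(runif(20^3)^2, c(20, 20, 20)), 0.012))
  pats <- array(rpois(12 * 12 * 3, 20), c(12, 12, 3))
  mask <- ewald_map(g)$mask
  ps <- pattern_set(pats, mask, geometry = g)
  tab <- compute_cc_table(ps, vols, grid, n_theta = nt)
  # oracle: recompute each slice at each full (alpha, beta, gamma_k) triple
  # independently (no shift trick, no FFT) and take the plain masked Pearson
  for (i in 1:3) {
    pol <- to_polar(pats[, , i], mask, pspec)
    for (m in 1:2) {
      best <- -Inf; best_o <- NULL
      for (gidx in seq_len(nrow(grid$dirs))) {
        for (k in 0:(nt - 1)) {
          gam <- 2 * pi * k / nt
          sl <- spimix:::.slice_polar(vols[[m]], grid$dirs[gidx, 1],
                                      grid$dirs[gidx, 2], pspec, gamma = gam)
          cc <- pearson_cc(pol$data, sl$data, pol$valid & sl$valid)
          if (!is.na(cc) && cc > best) {
            best <- cc
            best_o <- c(grid$dirs[gidx, 1], grid$dirs[gidx, 2], gam)
          }
        }
      }
      expect_equal(tab$cc[i, m], best, tolerance = 1e-10)
      expect_equal(c(tab$alpha[i, m], tab$beta[i, m], tab$gamma[i, m]),
                   unname(best_o), tolerance = 1e-12)
    }
  }
  # CC_max invariant under positive rescaling of a template
  vols2 <- vols; vols2[[1]]$data <- vols2[[1]]$data * 37.5
  tab2 <- compute_cc_table(ps, vols2, grid, n_theta = nt)
  expect_equal(tab2$cc, tab$cc, tolerance = 1e-9)
})

test_that("noiseless self-match recovers identity-level CC and orientation", {
  fx_g <- detector_geometry(1, 0.06, c(32, 32), 600, beamstop_px = 4)
  m <- tiny_model(20, seed = 8, spread = 5)
  vg <- volume_grid(fx_g, 2)
  tv <- model_to_intensity(m, vg$n, vg$dq)
  ew <- ewald_map(fx_g)
  beam <- beam_model(1e15, 0.1, 0)
  set.seed(9)
  os <- sample_random(3)
  pats <- array(0, c(32, 32, 3))
  for (i in 1:3) {
    pats[, , i] <- expected_pattern(m, os[[i]], ew, beam$fluence)
  }
  ps <- pattern_set(pats, ew$mask, geometry = fx_g)
  # noiseless pattern vs slice of its own truth volume at the truth
  sl <- slice_volume(tv, os[[1]], ew)
  expect_gt(pearson_cc(pats[, , 1], sl$data, sl$valid & ew$mask), 0.999)
  # matching over a grid recovers the orientation to within the spacing
  tab <- compute_cc_table(ps, list(tv), sample_grid(10 * pi / 180),
                          n_theta = 64)
  for (i in 1:3) {
    expect_gt(tab$cc[i, 1], 0.97)
    err <- rotation_distance(table_orientation(tab, i, 1)$R, os[[i]]$R)
    expect_lt(err, 10 * pi / 180)
  }
})

test_that("half-sphere direction sampling cannot orient lower-hemisphere views", {
  # slices from antipodal directions are mirror images, not in-plane
  # rotations, so a beta > pi/2 orientation has no match on a half grid
  fx_g <- detector_geometry(1, 0.06, c(32, 32), 600, beamstop_px = 4)
  m <- tiny_model(20, seed = 8, spread = 5)
  vg <- volume_grid(fx_g, 2)
  tv <- model_to_intensity(m, vg$n, vg$dq)
  ew <- ewald_map(fx_g)
  o <- orientation(0.7, 2.4, 1.3)          # beta well into the lower half
  lam <- expected_pattern(m, o, ew, 1e15)
  ps <- pattern_set(array(lam, c(32, 32, 1)), ew$mask, geometry = fx_g)
  half <- compute_cc_table(ps, list(tv), sample_grid(10 * pi / 180, half = TRUE),
                           n_theta = 64)
  full <- compute_cc_table(ps, list(tv), sample_grid(10 * pi / 180),
                           n_theta = 64)
  err_half <- rotation_distance(table_orientation(half, 1, 1)$R, o$R)
  err_full <- rotation_distance(table_orientation(full, 1, 1)$R, o$R)
  expect_lt(err_full, 10 * pi / 180)
  expect_gt(err_half, 30 * pi / 180)
  expect_gt(full$cc[1, 1], half$cc[1, 1])
})
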