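test_that("rasterized density integrates to the electron count", {
  m <- atomic_model("C", matrix(0, 1, 3))
  d <- model_to_density(m, voxel = 0.4, n = 32)
  expect_equal(sum(d$data) * 0.4^3, 6, tolerance = 0.01)
  # two identical atoms far apart give equal peaks
  m2 <- atomic_model(c("C", "C"), rbind(c(-4, 0, 0), c(4, 0, 0)))
  d2 <- model_to_density(m2, voxel = 0.5, n = 40)
  half <- dim(d2$data)[1] / 2
  expect_equal(max(d2$data[1:half, , ]), max(d2$data[(half + 1):(2 * half), , ]),
               tolerance = 1e-9)
  # oversized model rejected
  expect_error(model_to_density(m2, voxel = 0.5, n = 8), "does not fit")
})

test_that("density matches a direct per-voxel Gaussian sum", {
  m <- tiny_model(5, seed = 9, spread = 2)
  voxel <- 0.8; n <- 24; sigma <- 1
  d <- model_to_density(m, voxel, n, sigma)
  ax <- (seq_len(n) - (n / 2 + 1)) * voxel
  xyz <- model_xyz(m)
  w <- electron_count(m$element)
  oracle <- array(0, c(n, n, n))
  norm <- (2 * pi * sigma^2)^(-3 / 2)
  for (a in seq_len(5)) {
    gx <- exp(-(ax - xyz[a, 1])^2 / (2 * sigma^2))
    gy <- exp(-(ax - xyz[a, 2])^2 / (2 * sigma^2))
    gz <- exp(-(ax - xyz[a, 3])^2 / (2 * sigma^2))
    oracle <- oracle + w[a] * norm * (gx %o% gy %o% gz)
  }
  # implementation truncates each atom at 5 sigma; the full sum differs by
  # at most the tail mass
  expect_lt(max(abs(d$data - oracle)) / max(oracle), 5e-6)
})

test_that("structure factors obey zero-frequency, Hermitian and DFT oracles", {
  m <- tiny_model(7, seed = 2)
  expect_equal(Re(structure_factors(m, matrix(0, 1, 3))), total_electrons(m))
  q <- matrix(rnorm(30, sd = 0.05), 10, 3)
  expect_lt(max(Mod(structure_factors(m, -q) -
                      Conj(structure_factors(m, q)))), 1e-10)
  # gridded-density route vs naive O(N M) Fourier sum
  set.seed(6)
  dn <- structure(list(data = array(rnorm(8^3), c(8, 8, 8)),
                       voxel = 1, sigma = 1), class = "density_map")
  qs <- matrix(rnorm(60, sd = 0.1), 20, 3)
  got <- structure_factors(dn, qs)
  ax <- (1:8) - 5
  oracle <- vapply(1:20, function(k) {
    s <- 0 + 0i
    for (i in 1:8) for (j in 1:8) for (l in 1:8) {
      s <- s + dn$data[i, j, l] *
        exp(2i * pi * sum(qs[k, ] * c(ax[i], ax[j], ax[l])))
    }
    s
  }, 0 + 0i)
  expect_lt(max(Mod(got - oracle)) / max(Mod(oracle)), 1e-6)
  # beyond the grid band limit the density route refuses
  expect_error(structure_factors(dn, matrix(c(0.7, 0, 0), 1, 3)),
               "band limit")
})

test_that("expected patterns follow I = J re^2 Omega |F|^2", {
  g <- tiny_geometry(16, beamstop = 2)
  ew <- ewald_map(g)
  m <- tiny_model(6)
  o <- orientation(0.5, 1.0, 0.2)
  J <- 1e30
  lam <- expected_pattern(m, o, ew, J)
  # beam-stop pixels zeroed
  expect_true(all(lam[!ew$mask] == 0))
  # linear in fluence
  expect_equal(expected_pattern(m, o, ew, 2 * J), 2 * lam, tolerance = 1e-12)
  # spot check one pixel against a direct evaluation
  px <- c(3, 11)
  qv <- c(ew$qx[px[1], px[2]], ew$qy[px[1], px[2]], ew$qz[px[1], px[2]])
  Fq <- structure_factors(m, matrix(qv %*% t(euler_to_matrix(0.5, 1.0, 0.2)), 1, 3))
  re <- 2.8179403e-15
  expect_equal(lam[px[1], px[2]],
               J * re^2 * ew$omega[px[1], px[2]] * Mod(Fq)^2,
               tolerance = 1e-10)
  # zero-electron model gives an all-zero pattern
  m0 <- m; m0$occupancy <- 0
  expect_true(all(expected_pattern(m0, o, ew, J) == 0))
  # Friedel: noiseless pattern symmetric under point reflection in the
  # small-angle (flat-detector) limit, so use a long camera length
  gf <- detector_geometry(1, 0.5, c(16, 16), 1200, beamstop_px = 2)
  ewf <- ewald_map(gf)
  lamf <- expected_pattern(m, o, ewf, J)
  n <- nrow(lamf)
  flipped <- lamf[n:1, n:1]
  ok <- ewf$mask & ewf$mask[n:1, n:1]
  expect_gt(cor(lamf[ok], flipped[ok]), 0.999)
})

test_that("Poisson noise has the right mean and is reproducible", {
  g <- tiny_geometry(8)
  ew <- ewald_map(g)
  m <- tiny_model(4)
  beam <- beam_model(1e12, 0.1, jitter_sd = 0)
  o <- orientation(1, 1, 1)
  lam <- expected_pattern(m, o, ew, beam$fluence)
  set.seed(10)
  acc <- matrix(0, 8, 8)
  nrep <- 3000
  for (i in seq_len(nrep)) {
    acc <- acc + simulate_pattern(m, o, ew, beam, fluence = beam$fluence)$counts
  }
  mu <- acc / nrep
  se <- sqrt(pmax(lam, 1e-12) / nrep)
  expect_true(all(abs(mu - lam) <= 5 * se + 1e-9))
  # determinism: identical seeds give identical draws
  set.seed(42); p1 <- simulate_pattern(m, o, ew, beam)
  set.seed(42); p2 <- simulate_pattern(m, o, ew, beam)
  expect_identical(p1$counts, p2$counts)
  expect_identical(p1$fluence, p2$fluence)
  # noiseless pattern equals the expected map exactly
  expect_equal(simulate_pattern(m, o, ew, beam, noise = FALSE,
                                fluence = beam$fluence)$counts, lam)
})

test_that("fluence jitter is relative, positive and resampled", {
  beam <- beam_model(1e12, 0.1, jitter_sd = 0.1)
  set.seed(3)
  f <- sample_fluence(beam, 20000)
  expect_true(all(f > 0))
  expect_equal(mean(f) / beam$fluence, 1, tolerance = 0.01)
  expect_equal(sd(f) / beam$fluence, 0.1, tolerance = 0.05)
  # pathological jitter still yields positive draws
  wild <- beam_model(1e12, 0.1, jitter_sd = 0.8)
  set.seed(3)
  expect_true(all(sample_fluence(wild, 2000) > 0))
})

test_that("mixtures have the requested composition and reproduce under a seed", {
  g <- tiny_geometry(8)
  beam <- beam_model(1e14, 0.1)
  models <- list(tiny_model(3, 1), tiny_model(4, 2), tiny_model(5, 3))
  ps <- simulate_mixture(models, c(3, 2, 1), g, beam, seed = 77)
  expect_identical(n_patterns(ps), 6L)
  expect_identical(as.integer(table(ps$meta$label)), c(3L, 2L, 1L))
  ps2 <- simulate_mixture(models, c(3, 2, 1), g, beam, seed = 77)
  expect_identical(ps$patterns, ps2$patterns)
  expect_identical(ps$meta, ps2$meta)
  ps3 <- simulate_mixture(models, c(3, 2, 1), g, beam, seed = 78)
  expect_false(identical(ps$patterns, ps3$patterns))
  expect_error(simulate_mixture(models, c(3, 0, 1), g, beam, seed = 1),
               "positive")
})
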