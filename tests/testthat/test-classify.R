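mk_table <- function(cc) {
  structure(list(cc = cc,
                 alpha = matrix(0.1, nrow(cc), ncol(cc)),
                 beta = matrix(0.2, nrow(cc), ncol(cc)),
                 gamma = matrix(0.3, nrow(cc), ncol(cc))),
            class = "cc_table")
}

test_that("threshold classification follows the top-two margin rule", {
  tab <- mk_table(rbind(c(0.90, 0.85, 0.40),   # margin 0.05 -> class 1
                        c(0.90, 0.89, 0.10),   # margin 0.01 -> unclassified
                        c(0.50, 0.70, 0.68)))  # margin 0.02 (not >) -> uncl.
  a <- assign_classes(tab, 0.02)
  expect_identical(a$class, c(1L, NA_integer_, NA_integer_))
  expect_equal(a$margin, c(0.05, 0.01, 0.02))
  # orientation only committed for classified patterns
  expect_identical(is.na(a$alpha), is.na(a$class))
  # threshold 0 classifies everything with finite CCs
  a0 <- assign_classes(tab, 0)
  expect_false(any(is.na(a0$class)))
  expect_identical(a0$class, c(1L, 1L, 2L))
  # all-NA row stays unclassified even at threshold 0
  tabNA <- mk_table(rbind(c(NA_real_, NA_real_)))
  expect_true(is.na(assign_classes(tabNA, 0)$class))
  # single-class table classifies every pattern to class 1
  tab1 <- mk_table(matrix(c(0.2, 0.9), 2, 1))
  expect_identical(assign_classes(tab1, 0.02)$class, c(1L, 1L))
})

test_that("classification equals a per-row sort oracle on random tables", {
  set.seed(17)
  cc <- matrix(runif(300), 100, 3)
  thr <- 0.02
  a <- assign_classes(mk_table(cc), thr)
  for (i in 1:100) {
    s <- sort(cc[i, ], decreasing = TRUE)
    want <- if (s[1] - s[2] > thr) which.max(cc[i, ]) else NA_integer_
    expect_identical(a$class[i], as.integer(want))
  }
})

test_that("merging deposits on the Ewald shell and classes are independent", {
  g <- tiny_geometry(12, beamstop = 2)
  set.seed(3)
  pats <- array(rpois(12 * 12 * 4, 10) + 1, c(12, 12, 4))
  ps <- pattern_set(pats, ewald_map(g)$mask, geometry = g)
  asg <- data.frame(class = c(1L, 1L, 2L, 2L),
                    alpha = c(0, 1, 2, 0.5), beta = c(0, 1, 0.4, 2),
                    gamma = c(0, 0.3, 1, 2), cc = 1, margin = 1)
  vols <- merge_patterns(ps, asg, n = 40, dq = 0.01)
  # single pattern at identity: nonzero voxels only within the trilinear
  # support of the Ewald surface
  v1 <- merge_patterns(ps[["patterns"]][, , 1, drop = FALSE] |>
                         pattern_set(ps$mask, geometry = g),
                       data.frame(class = 1L, alpha = 0, beta = 0, gamma = 0,
                                  cc = 1, margin = 1),
                       n = 40, dq = 0.01)[[1]]
  ew <- ewald_map(g)
  touched <- which(v1$coverage, arr.ind = TRUE)
  expect_gt(nrow(touched), 50)
  qpts <- (touched - 21) * 0.01
  # every covered voxel lies within one voxel diagonal of the Ewald sphere
  d_sphere <- abs(sqrt(qpts[, 1]^2 + qpts[, 2]^2 +
                         (qpts[, 3] + 1)^2) - 1)
  expect_lt(max(d_sphere), 2 * 0.01 * sqrt(3))
  # swapping class-2 patterns does not change class 1's volume
  asg_swap <- asg
  asg_swap[3:4, c("alpha", "beta", "gamma")] <-
    asg[4:3, c("alpha", "beta", "gamma")]
  vols2 <- merge_patterns(ps, asg_swap, n = 40, dq = 0.01)
  expect_identical(vols[[1]]$data, vols2[[1]]$data)
  expect_false(identical(vols[[2]]$data, vols2[[2]]$data))
  # a class with no patterns comes back NULL (caller carries old template)
  asg3 <- asg; asg3$class <- c(1L, 1L, 1L, NA)
  vols3 <- merge_patterns(ps, asg3, n_classes = 2, n = 40, dq = 0.01)
  expect_null(vols3[[2]])
})

test_that("merge -> slice closure: slicing the merge reproduces a pattern", {
  g <- detector_geometry(1, 0.06, c(32, 32), 600, beamstop_px = 4)
  m <- tiny_model(20, seed = 8, spread = 5)
  ew <- ewald_map(g)
  beam <- beam_model(1e15, 0.1, 0)
  set.seed(19)
  os <- sample_random(40)
  pats <- array(0, c(32, 32, 40))
  for (i in seq_along(os)) {
    pats[, , i] <- expected_pattern(m, os[[i]], ew, beam$fluence)
  }
  ps <- pattern_set(pats, ew$mask, geometry = g)
  asg <- data.frame(class = 1L,
                    alpha = vapply(os, `[[`, 0, "alpha"),
                    beta = vapply(os, `[[`, 0, "beta"),
                    gamma = vapply(os, `[[`, 0, "gamma"),
                    cc = 1, margin = 1)
  vg <- volume_grid(g, 2)
  mv <- merge_patterns(ps, asg, n = vg$n, dq = vg$dq)[[1]]
  sl <- slice_volume(mv, os[[1]], ew)
  j <- sl$valid & ew$mask
  expect_gt(pearson_cc(pats[, , 1], sl$data, j), 0.9)
})

test_that("degenerate runs abort with a diagnostic", {
  g <- tiny_geometry(12, beamstop = 2)
  set.seed(30)
  pats <- array(rpois(12 * 12 * 4, 10), c(12, 12, 4))
  ps <- pattern_set(pats, ewald_map(g)$mask, geometry = g)
  cfg <- run_config(shape = c(12, 12), distance = 0.06, pixel_um = 1200,
                    beamstop_px = 2, counts = c(2, 2), threshold = 0.9999,
                    max_iter = 2, delta_deg = 40, n_theta = 16)
  vg <- volume_grid(g, 2)
  set.seed(1)
  tmpl <- list(intensity_volume(array(runif(vg$n^3), rep(vg$n, 3)), vg$dq),
               intensity_volume(array(runif(vg$n^3), rep(vg$n, 3)), vg$dq))
  expect_error(
    classify_reconstruct(ps, tmpl, cfg, downsample = FALSE),
    "unclassified")
})

test_that("a mislabeled warm start is corrected within three iterations", {
  fx <- toy_base()
  beam0 <- beam_model(fx$cfg$photons_per_pulse, fx$cfg$focus_um, 0)
  ps <- simulate_mixture(unname(fx$models), c(30, 20, 10), fx$geom, beam0,
                         seed = 12, noise = FALSE)
  psd <- downsample_pattern(ps)
  # warm start: true orientations, but 6 deliberately wrong labels
  asg0 <- data.frame(class = psd$meta$label, alpha = psd$meta$alpha,
                     beta = psd$meta$beta, gamma = psd$meta$gamma,
                     cc = 1, margin = 1)
  set.seed(3)
  wrong <- sample(60, 6)
  asg0$class[wrong] <- (asg0$class[wrong] %% 3L) + 1L
  cfg <- fx$cfg; cfg$max_iter <- 3L
  run <- classify_reconstruct(psd, templates = NULL, cfg,
                              initial_assignment = asg0, downsample = FALSE)
  final <- run$assignment
  # all deliberately mislabeled patterns are corrected (or abstain), and
  # most are actively reassigned to their true class
  expect_true(all(is.na(final$class[wrong]) |
                    final$class[wrong] == psd$meta$label[wrong]))
  expect_gte(sum(final$class[wrong] == psd$meta$label[wrong], na.rm = TRUE), 4)
  # the warm-start damage does not spread: residual misclassifications are
  # limited to the handful of intrinsically confusable monomer/dimer views
  mis <- sum(!is.na(final$class) & final$class != psd$meta$label)
  expect_lte(mis, 5)
})
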