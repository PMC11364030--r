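#' Forward simulation of single-particle diffraction
#'
#' The forward model treats every atom as an isotropic Gaussian of
#' `electron_count(element)` electrons and width `sigma` (A).  Its Fourier
#' transform is analytic,
#' \deqn{F(q) = e^{-2\pi^2\sigma^2 |q|^2} \sum_a Z_a o_a e^{2\pi i q\cdot r_a},}
#' so structure factors can be evaluated exactly at the non-uniform
#' reciprocal points of the curved Ewald sphere, with no gridding or
#' interpolation error.  The expected photon count in a detector pixel is
#' \deqn{\langle k \rangle = J\, r_e^2\, \Omega\, |F(Rq)|^2,}
#' with `J` the incident photon fluence (photons per unit area), `r_e` the
#' classical electron radius, `Omega` the pixel solid angle and `R` the
#' particle orientation; recorded counts are Poisson draws.  The beam is
#' treated as unpolarized (no polarization factor).
#'
#' @name simulate
NULL

# classical electron radius in meters
.r_e <- 2.8179403e-15

#' Default width of the Gaussian atom, in Angstrom
#' @export
default_atom_sigma <- 1.0

#' Rasterize a model to a real-space electron density map
#'
#' Each atom contributes `Z * occupancy` electrons as a normalized isotropic
#' Gaussian of width `sigma`, evaluated (separably) out to 5 sigma.  The
#' grid is centered on the coordinate origin; center the model first (see
#' [center_model()]).
#'
#' @param model An [atomic_model()].
#' @param voxel Voxel size in Angstrom.
#' @param n Grid size per side (voxels).
#' @param sigma Gaussian atom width in Angstrom.
#' @return Object of class `"density_map"`: list with `data` (n^3 array,
#'   electrons / A^3), `voxel`, and `sigma`.
#' @export
model_to_density <- function(model, voxel, n, sigma = default_atom_sigma) {
  xyz <- model_xyz(model)
  w <- electron_count(model$element) * model$occupancy
  ax <- (seq_len(n) - (floor(n / 2) + 1)) * voxel
  half_extent <- max(abs(ax))
  if (max(abs(xyz)) + 3 * sigma > half_extent + voxel / 2) {
    stop("model (plus 3 sigma padding) does not fit in the box; ",
         "increase n or center the model")
  }
  rad <- 5 * sigma
  norm <- (2 * pi * sigma^2)^(-3 / 2)
  rho <- array(0, c(n, n, n))
  g1 <- function(centers, coord) exp(-(coord - centers)^2 / (2 * sigma^2))
  for (a in seq_len(nrow(xyz))) {
    ix <- which(abs(ax - xyz[a, 1]) <= rad)
    iy <- which(abs(ax - xyz[a, 2]) <= rad)
    iz <- which(abs(ax - xyz[a, 3]) <= rad)
    gx <- g1(xyz[a, 1], ax[ix]); gy <- g1(xyz[a, 2], ax[iy])
    gz <- g1(xyz[a, 3], ax[iz])
    rho[ix, iy, iz] <- rho[ix, iy, iz] +
      (w[a] * norm) * (gx %o% gy %o% gz)
  }
  structure(list(data = rho, voxel = voxel, sigma = sigma),
            class = "density_map")
}

#' @export
print.density_map <- function(x, ...) {
  n <- dim(x$data)[1]
  cat(sprintf("density map: %d^3 voxels, %.2f A voxel, %.1f electrons\n",
              n, x$voxel, sum(x$data) * x$voxel^3))
  invisible(x)
}

#' Structure factors at arbitrary reciprocal points
#'
#' For an [atomic_model()] the analytic Gaussian-atom transform is used
#' (exact at any q).  For a [model_to_density()] grid the direct Fourier sum
#' over voxels is evaluated (O(voxels x points); intended for validation on
#' small grids).
#'
#' @param object An [atomic_model()] or `"density_map"`.
#' @param qpts Numeric matrix (m x 3) of reciprocal points in 1/Angstrom.
#' @param ... Passed on to methods.
#' @return Complex vector of length m.
#' @export
structure_factors <- function(object, qpts, ...) {
  UseMethod("structure_factors")
}

#' @rdname structure_factors
#' @param sigma Gaussian atom width in Angstrom.
#' @param chunk Number of q-points per block (memory control).
#' @export
structure_factors.atomic_model <- function(object, qpts,
                                           sigma = default_atom_sigma,
                                           chunk = 65536L, ...) {
  qpts <- matrix(qpts, ncol = 3)
  xyz <- model_xyz(object)
  w <- electron_count(object$element) * object$occupancy
  env <- exp(-2 * pi^2 * sigma^2 * rowSums(qpts^2))
  out <- complex(nrow(qpts))
  for (i0 in seq(1, nrow(qpts), by = chunk)) {
    ii <- i0:min(i0 + chunk - 1, nrow(qpts))
    ph <- qpts[ii, , drop = FALSE] %*% t(xyz)
    out[ii] <- exp(2i * pi * ph) %*% w
  }
  out * env
}

#' @rdname structure_factors
#' @export
structure_factors.density_map <- function(object, qpts, ...) {
  qpts <- matrix(qpts, ncol = 3)
  if (any(abs(qpts) > 1 / (2 * object$voxel))) {
    stop("q-point beyond the band limit 1/(2 voxel) of the density grid")
  }
  n <- dim(object$data)[1]
  ax <- (seq_len(n) - (floor(n / 2) + 1)) * object$voxel
  grid <- as.matrix(expand.grid(x = ax, y = ax, z = ax))
  rho <- as.vector(object$data)
  ph <- qpts %*% t(grid)             # m x n^3
  drop(exp(2i * pi * ph) %*% rho) * object$voxel^3
}

#' Beam model
#'
#' @param photons_per_pulse Mean photons per pulse.
#' @param focus_um Beam focus diameter in micrometers; the fluence is
#'   photons per pulse divided by the focal-spot area.
#' @param jitter_sd Relative (Gaussian) pulse-to-pulse fluence jitter;
#'   non-positive draws are resampled.
#' @return Object of class `"beam_model"` with the derived mean fluence
#'   `fluence` in photons / m^2.
#' @export
beam_model <- function(photons_per_pulse, focus_um, jitter_sd = 0.10) {
  stopifnot(photons_per_pulse > 0, focus_um > 0, jitter_sd >= 0)
  area <- pi * (focus_um * 1e-6 / 2)^2
  structure(list(photons_per_pulse = photons_per_pulse,
                 focus_um = focus_um, jitter_sd = jitter_sd,
                 fluence = photons_per_pulse / area),
            class = "beam_model")
}

#' @export
print.beam_model <- function(x, ...) {
  cat(sprintf(
    "beam: %.3g photons/pulse, %.2g um focus -> J = %.3g ph/m^2 (+/- %.0f%%)\n",
    x$photons_per_pulse, x$focus_um, x$fluence, 100 * x$jitter_sd))
  invisible(x)
}

#' Sample per-pulse fluences with relative Gaussian jitter
#' @param beam A [beam_model()].
#' @param n Number of pulses.
#' @return Numeric vector of fluences (photons / m^2), all positive.
#' @export
sample_fluence <- function(beam, n) {
  f <- beam$fluence * (1 + stats::rnorm(n, 0, beam$jitter_sd))
  bad <- which(f <= 0)
  while (length(bad) > 0) {
    f[bad] <- beam$fluence * (1 + stats::rnorm(length(bad), 0, beam$jitter_sd))
    bad <- bad[f[bad] <= 0]
  }
  f
}

#' Noiseless expected-count map for one orientation
#'
#' @param model An [atomic_model()] (centered).
#' @param orient An [orientation()] or 3x3 rotation matrix.
#' @param ewald An [ewald_map()].
#' @param fluence Photon fluence in photons / m^2 for this pulse.
#' @param sigma Gaussian atom width.
#' @return Matrix of expected photon counts (beam-stop pixels set to 0).
#' @export
expected_pattern <- function(model, orient, ewald, fluence,
                             sigma = default_atom_sigma) {
  R <- if (inherits(orient, "orientation")) orient$R else orient
  q <- .ewald_qmat(ewald)
  # F(R q) = sum_a w_a exp(2 pi i q . (R^T r_a)): rotate the atoms instead
  rot <- transform_model(model, R = t(R))
  F <- structure_factors(rot, q, sigma = sigma)
  I <- fluence * .r_e^2 * as.vector(ewald$omega) * Mod(F)^2
  I[!as.vector(ewald$mask)] <- 0
  matrix(I, nrow(ewald$qx), ncol(ewald$qx))
}

#' Simulate one diffraction pattern
#'
#' Expected counts per [expected_pattern()]; recorded counts are Poisson
#' draws unless `noise = FALSE`.
#'
#' @inheritParams expected_pattern
#' @param beam A [beam_model()]; a single fluence is drawn from it unless
#'   `fluence` is given explicitly.
#' @param noise Add Poisson noise?
#' @param fluence Optional fixed fluence (overrides the jittered draw).
#' @return List with `counts` (matrix), `mask`, `fluence`.
#' @export
simulate_pattern <- function(model, orient, ewald, beam,
                             sigma = default_atom_sigma, noise = TRUE,
                             fluence = NULL) {
  if (is.null(fluence)) fluence <- sample_fluence(beam, 1)
  lam <- expected_pattern(model, orient, ewald, fluence, sigma)
  if (max(lam) > 2^31 - 1) stop("expected counts overflow integer range")
  counts <- if (noise) {
    matrix(stats::rpois(length(lam), as.vector(lam)), nrow(lam), ncol(lam))
  } else lam
  list(counts = counts, mask = ewald$mask, fluence = fluence)
}

#' Pattern sets
#'
#' A stack of photon-count images sharing one detector mask, with hidden
#' per-pattern truth metadata (species label, orientation, applied fluence)
#' used only by the evaluation module.
#'
#' @param patterns Numeric array `h x w x n`.
#' @param mask Logical `h x w` matrix (TRUE = usable pixel).
#' @param meta Data frame with `n` rows; columns `label` (integer species,
#'   or NA), `alpha`, `beta`, `gamma` (true orientation), `fluence`.
#' @param geometry The generating [detector_geometry()] (optional).
#' @return Object of class `"pattern_set"`.
#' @export
pattern_set <- function(patterns, mask, meta = NULL, geometry = NULL) {
  d <- dim(patterns)
  stopifnot(length(d) == 3, d[3] >= 1, d[1] == nrow(mask),
            d[2] == ncol(mask), all(patterns >= 0))
  if (is.null(meta)) {
    meta <- data.frame(label = rep(NA_integer_, d[3]), alpha = NA_real_,
                       beta = NA_real_, gamma = NA_real_, fluence = NA_real_)
  }
  stopifnot(nrow(meta) == d[3])
  structure(list(patterns = patterns, mask = mask, meta = meta,
                 geometry = geometry),
            class = "pattern_set")
}

#' @export
print.pattern_set <- function(x, ...) {
  d <- dim(x$patterns)
  lab <- table(factor(x$meta$label))
  cat(sprintf("pattern set: %d patterns of %dx%d px (%d masked px)\n",
              d[3], d[1], d[2], sum(!x$mask)))
  if (length(lab)) {
    cat("  true labels:",
        paste(sprintf("%s:%d", names(lab), lab), collapse = " "), "\n")
  }
  cat(sprintf("  mean photons/pattern: %.0f\n", mean(apply(x$patterns, 3, sum))))
  invisible(x)
}

#' Number of patterns in a set
#' @param x A [pattern_set()].
#' @return Integer.
#' @export
n_patterns <- function(x) dim(x$patterns)[3]

#' Simulate a mixed-species pattern set
#'
#' Draws Haar-uniform orientations and jittered fluences, simulates
#' `counts[k]` Poisson patterns from each model, and shuffles the stack.
#' True labels and orientations are stored only in the metadata.  All
#' randomness derives from `seed` through fixed sub-streams (orientations,
#' fluence, photon noise, shuffling), so a given seed reproduces the set
#' bit-for-bit.
#'
#' @param models List of centered [atomic_model()] objects, one per species.
#' @param counts Integer vector, patterns per species (all > 0).
#' @param geometry A [detector_geometry()].
#' @param beam A [beam_model()].
#' @param seed Integer seed.
#' @param sigma Gaussian atom width.
#' @param noise Add Poisson noise?
#' @return A [pattern_set()].
#' @export
simulate_mixture <- function(models, counts, geometry, beam, seed,
                             sigma = default_atom_sigma, noise = TRUE) {
  stopifnot(length(models) == length(counts))
  if (any(counts <= 0)) stop("all species pattern counts must be positive")
  n <- sum(counts)
  ew <- ewald_map(geometry)
  seeds <- seed + 1:4
  set.seed(seeds[1]); orients <- sample_random(n)
  set.seed(seeds[2]); flu <- sample_fluence(beam, n)
  labels <- rep(seq_along(models), counts)
  set.seed(seeds[3])
  pats <- array(0, c(geometry$shape[1], geometry$shape[2], n))
  for (i in seq_len(n)) {
    p <- simulate_pattern(models[[labels[i]]], orients[[i]], ew, beam,
                          sigma = sigma, noise = noise, fluence = flu[i])
    pats[, , i] <- p$counts
  }
  set.seed(seeds[4]); ord <- sample.int(n)
  meta <- data.frame(
    label = labels[ord],
    alpha = vapply(orients, `[[`, 0, "alpha")[ord],
    beta = vapply(orients, `[[`, 0, "beta")[ord],
    gamma = vapply(orients, `[[`, 0, "gamma")[ord],
    fluence = flu[ord])
  pattern_set(pats[, , ord, drop = FALSE], ew$mask, meta, geometry)
}

#' Analytic 3D intensity of a model on a cubic grid
#'
#' Evaluates `|F(q)|^2` from the Gaussian-atom transform on the inscribed
#' ball of the grid (voxels outside the ball are zero and marked uncovered).
#' This is the ground-truth intensity a perfect reconstruction should
#' reproduce, and doubles as the "analytic" template builder.
#'
#' @param model A centered [atomic_model()].
#' @param n Grid side (voxels).
#' @param dq Voxel step (1/Angstrom).
#' @param sigma Gaussian atom width.
#' @return An [intensity_volume()] (Friedel-symmetric by construction).
#' @export
model_to_intensity <- function(model, n, dq, sigma = default_atom_sigma) {
  ax <- q_axis(n, dq)
  qmax <- (n / 2) * dq
  r2 <- outer(outer(ax^2, ax^2, "+"), ax^2, "+")
  inside <- which(r2 <= qmax^2)
  idx <- arrayInd(inside, c(n, n, n))
  qpts <- cbind(ax[idx[, 1]], ax[idx[, 2]], ax[idx[, 3]])
  F <- structure_factors(model, qpts, sigma = sigma)
  data <- array(0, c(n, n, n))
  data[inside] <- Mod(F)^2
  cov <- array(FALSE, c(n, n, n)); cov[inside] <- TRUE
  friedel_symmetrize(intensity_volume(data, dq, coverage = cov))
}
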