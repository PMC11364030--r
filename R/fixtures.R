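#' Deterministic toy inputs
#'
#' Pseudo-atom blob assemblies at three oligomeric states, mirroring a
#' monomer/dimer/tetramer mixture at a scale every pipeline stage can
#' process in seconds: the monomer is a fixed random cloud of 50 carbon
#' pseudo-atoms in a 9 Angstrom-radius ball, the dimer is two rigid
#' (rotated, displaced) monomer copies, and the tetramer two rigid dimer
#' copies.  A fixed seed gives identical models on every call.
#'
#' @param kind `"monomer"`, `"dimer"` or `"tetramer"`.
#' @param seed Integer seed for the monomer cloud.
#' @return A centered [atomic_model()].
#' @export
#' @examples
#' toy_species("dimer")
toy_species <- function(kind = c("monomer", "dimer", "tetramer"), seed = 101) {
  kind <- match.arg(kind)
  set.seed(seed)
  n0 <- 50; r0 <- 9
  u <- matrix(stats::rnorm(3 * n0), n0, 3)
  u <- u / sqrt(rowSums(u^2))
  rad <- r0 * stats::runif(n0)^(1 / 3)
  mono <- atomic_model(rep("C", n0), u * rad)
  assemble <- function(unit, shift, rot) {
    a <- unit
    b <- transform_model(unit, R = rot, t = shift)
    b$resno <- b$resno + max(a$resno)
    out <- rbind(as.data.frame(a), as.data.frame(b))
    class(out) <- c("atomic_model", "data.frame")
    out
  }
  model <- switch(kind,
    monomer = mono,
    dimer = assemble(mono, c(20, 0, 0), euler_to_matrix(0.4, 1.1, 2.2)),
    tetramer = {
      dim1 <- assemble(mono, c(20, 0, 0), euler_to_matrix(0.4, 1.1, 2.2))
      assemble(dim1, c(0, 20, 0), euler_to_matrix(2.8, 0.6, 1.0))
    })
  center_model(model)
}

#' Perturb a model by a smooth displacement field
#'
#' Emulates the discrepancy between a predicted and an experimental
#' structure: each coordinate component receives a sum of four random
#' long-wavelength cosine modes (wavelengths of order the particle size, so
#' the distortion is spatially correlated rather than white noise), and the
#' field is rescaled so the realized coordinate RMSD equals `rmsd_target`
#' exactly.
#'
#' @param model An [atomic_model()].
#' @param rmsd_target Target coordinate RMSD in Angstrom (>= 0).
#' @param seed Integer seed for the mode directions and phases.
#' @return The perturbed model (same atoms, displaced coordinates).
#' @export
perturb_model <- function(model, rmsd_target, seed = 1) {
  stopifnot(rmsd_target >= 0)
  if (rmsd_target == 0) return(model)
  set.seed(seed)
  xyz <- model_xyz(model)
  scale_len <- 2 * max(radius_of_gyration(model), 1)
  disp <- matrix(0, nrow(xyz), 3)
  for (mode in 1:4) {
    k <- matrix(stats::rnorm(3), 1, 3) / scale_len
    phase <- stats::runif(3, 0, 2 * pi)
    amp <- matrix(stats::rnorm(3), 1, 3)
    arg <- xyz %*% t(k) * 2 * pi
    disp <- disp + cbind(amp[1] * cos(arg + phase[1]),
                         amp[2] * cos(arg + phase[2]),
                         amp[3] * cos(arg + phase[3]))
  }
  realized <- sqrt(mean(rowSums(disp^2)))
  disp <- disp * (rmsd_target / realized)
  out <- model
  out$x <- out$x + disp[, 1]
  out$y <- out$y + disp[, 2]
  out$z <- out$z + disp[, 3]
  out
}

#' Toy run configuration
#'
#' The study conditions for the desk-scale end-to-end test: a 64x64
#' detector at 1 Angstrom wavelength whose edge resolution (about 6.3 A) is
#' a few times the blob feature size, the same 10x10-pixel beam stop, 10%
#' fluence jitter and 0.02 CC threshold as the full-scale conditions, a
#' 4:2:1 species mixture of 600 patterns, and a 10-degree orientation grid
#' with 64 in-plane bins.  The photon budget (2e17 photons per pulse into a
#' 0.1 um focus) is chosen so the central-speckle photon counts of the
#' small toy scatterers match those of full-size proteins under the
#' full-scale beam, keeping the per-pattern noise regime comparable.
#' The reconstruction grid uses two voxels per detector pixel step
#' (`oversample = 2`), resolving the finest speckles of the largest
#' species with ~5 voxels; correlations against slices of sparsely
#' covered merged volumes are guarded by the minimum-overlap rule of
#' [compute_cc_table()].
#'
#' @param seed Integer seed.
#' @return A [run_config()].
#' @export
toy_config <- function(seed = 1) {
  run_config(wavelength = 1, distance = 0.06, shape = c(64, 64),
             pixel_um = 300, beamstop_px = 10,
             photons_per_pulse = 2e17, focus_um = 0.1, jitter_sd = 0.10,
             counts = c(343, 171, 86), threshold = 0.02, max_iter = 10,
             stop_tol = 0.001, delta_deg = 10, n_theta = 64,
             oversample = 2, atom_sigma = 1.0, seed = seed)
}

#' The three toy species as a list
#' @param seed Monomer cloud seed.
#' @return Named list of [atomic_model()]: monomer, dimer, tetramer.
#' @export
toy_models <- function(seed = 101) {
  list(monomer = toy_species("monomer", seed),
       dimer = toy_species("dimer", seed),
       tetramer = toy_species("tetramer", seed))
}
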