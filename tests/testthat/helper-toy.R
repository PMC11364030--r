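# Shared toy fixtures, built once per test run on first use.

.toy_env <- new.env(parent = emptyenv())

# Small detector used by cheap unit tests (16x16, no beam stop unless asked)
tiny_geometry <- function(shape = 16, beamstop = 0) {
  detector_geometry(wavelength = 1, distance = 0.06, shape = shape,
                    pixel_um = 1200, beamstop_px = beamstop)
}

tiny_model <- function(n = 6, seed = 3, spread = 4) {
  set.seed(seed)
  center_model(atomic_model(rep("C", n), matrix(rnorm(3 * n, sd = spread), n, 3)))
}

# Cheap shared pieces of the toy study (configuration, models, geometry)
toy_base <- function() {
  if (!is.null(.toy_env$base)) return(.toy_env$base)
  cfg <- toy_config(seed = 1)
  .toy_env$base <- list(cfg = cfg, models = toy_models(),
                        geom = config_geometry(cfg), beam = config_beam(cfg))
  .toy_env$base
}

# Full toy study fixture: 600-pattern 3-species mixture, perturbed
# templates, ground-truth volumes.  Expensive (minutes); cached.
toy_fixture <- function() {
  if (!is.null(.toy_env$fix)) return(.toy_env$fix)
  base <- toy_base()
  cfg <- base$cfg; models <- base$models
  geom <- base$geom; beam <- base$beam
  ps <- simulate_mixture(unname(models), cfg$counts, geom, beam,
                         seed = cfg$seed)
  vgf <- volume_grid(geom, cfg$oversample)
  rmsds <- c(1, 2, 3)
  tmpl <- lapply(1:3, function(k) build_template(
    perturb_model(models[[k]], rmsds[k], seed = 200 + k),
    vgf$n, vgf$dq, sigma = cfg$atom_sigma))
  gd <- downsample_geometry(geom)
  vgd <- list(n = vgf$n %/% 2, dq = vgf$dq * 2)
  truth_ds <- lapply(models, function(m) model_to_intensity(m, vgd$n, vgd$dq))
  .toy_env$fix <- list(cfg = cfg, models = models, geom = geom, beam = beam,
                       patterns = ps, templates = tmpl, truth_ds = truth_ds,
                       vgf = vgf, vgd = vgd, rmsds = rmsds)
  .toy_env$fix
}

# Full classification run on the toy fixture (the criterion-4 study), cached.
toy_run <- function() {
  if (!is.null(.toy_env$run)) return(.toy_env$run)
  fx <- toy_fixture()
  .toy_env$run <- classify_reconstruct(fx$patterns, fx$templates, fx$cfg)
  .toy_env$run
}
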