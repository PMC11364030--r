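#' File formats
#'
#' Readers/writers for the package's on-disk artifacts:
#' * 3D intensity volumes as MRC2014 maps (mode 2, float32).  The header's
#'   cell fields hold the reciprocal extent: `cella = n * dq` with the value
#'   in 1/Angstrom stored directly in the cell-length field and the voxel
#'   step recovered as `cella / mx` on read.
#' * Pattern sets as a single self-describing binary container (`.spipat`):
#'   an 8-byte magic (`SPIPAT01`), a JSON header, then the shared mask, the
#'   pattern stack and the per-pattern metadata as raw little-endian arrays.
#'   Layout mirrors the datasets `patterns` (n x h x w), `mask` (h x w) and
#'   `meta/{label,alpha,beta,gamma,fluence}`.
#' * Run configurations as YAML, field-for-field the [run_config()] object.
#'
#' @name io_formats
NULL

#' Write an intensity volume as an MRC2014 map
#'
#' @param volume An [intensity_volume()].  The coverage mask, if any, is not
#'   stored in the map (missing voxels are written as their value, 0).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path) {
  n <- dim(volume$data)[1]
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  v <- as.vector(volume$data)
  wi(c(n, n, n))                    # nx ny nz
  wi(2)                             # mode 2 = float32
  wi(c(0, 0, 0))                    # nxstart
  wi(c(n, n, n))                    # mx my mz
  wf(rep(n * volume$dq, 3))         # cella: reciprocal extent, 1/A
  wf(c(90, 90, 90))                 # cellb
  wi(c(1, 2, 3))                    # mapc mapr maps
  wf(c(min(v), max(v), mean(v)))    # dmin dmax dmean
  wi(1)                             # ispg
  wi(0)                             # nsymbt
  wi(c(0, 0))                       # extra words 25-26
  writeChar("MRC ", con, 4, eos = NULL); wi(20140)  # exttyp + nversion
  wi(rep(0, 21))                    # extra words 29-49
  wf(c(0, 0, 0))                    # origin
  writeChar("MAP ", con, 4, eos = NULL)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)  # little-endian stamp
  wf(stats::sd(v))                  # rms
  wi(1)                             # nlabl
  lab <- sprintf("%-80s", "spimix intensity volume; cell = n*dq in 1/Angstrom")
  writeChar(substr(lab, 1, 80), con, 80, eos = NULL)
  writeChar(strrep(" ", 80 * 9), con, 80 * 9, eos = NULL)
  writeBin(as.numeric(v), con, size = 4, endian = "little")
  invisible(path)
}

#' Read an MRC2014 intensity volume
#'
#' @param path Path to a map written by [write_volume()] (or any cubic
#'   mode-2 MRC map whose cell encodes the reciprocal extent).
#' @return An [intensity_volume()].
#' @export
read_volume <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  ri <- function(k) readBin(con, "integer", k, size = 4, endian = "little")
  rf <- function(k) readBin(con, "numeric", k, size = 4, endian = "little")
  nxyz <- ri(3)
  mode <- ri(1)
  if (mode != 2) stop("unsupported MRC mode: ", mode)
  ri(3)                             # nstart
  mxyz <- ri(3)
  cella <- rf(3)
  if (length(unique(nxyz)) != 1) stop("volume grid is not cubic")
  if (any(cella <= 0)) stop("missing voxel spacing in header")
  seek(con, 1024)
  v <- rf(prod(nxyz))
  intensity_volume(array(v, nxyz), dq = cella[1] / mxyz[1])
}

.spipat_magic <- "SPIPAT01"

#' Save a pattern set
#'
#' Single-file binary container, lossless for integer counts (stored int32)
#' and float64 otherwise; see [io_formats].
#'
#' @param patterns A [pattern_set()].
#' @param path Output path (conventionally `.spipat`).
#' @return `path`, invisibly.
#' @export
save_patterns <- function(patterns, path) {
  stopifnot(inherits(patterns, "pattern_set"))
  d <- dim(patterns$patterns)
  if (d[3] < 1) stop("refusing to save an empty pattern set")
  v <- as.vector(patterns$patterns)
  integer_counts <- all(v == round(v)) && max(v) <= 2^31 - 1
  g <- patterns$geometry
  header <- jsonlite::toJSON(list(
    h = d[1], w = d[2], n = d[3],
    dtype = if (integer_counts) "int32" else "float64",
    geometry = if (is.null(g)) NULL else
      list(wavelength = g$wavelength, distance = g$distance,
           shape = g$shape, pixel_um = g$pixel_um,
           beamstop_px = g$beamstop_px)),
    auto_unbox = TRUE, digits = NA)
  hraw <- charToRaw(as.character(header))
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(.spipat_magic, con, 8, eos = NULL)
  writeBin(length(hraw), con, size = 4, endian = "little")
  writeBin(hraw, con)
  writeBin(as.integer(patterns$mask), con, size = 1)
  if (integer_counts) writeBin(as.integer(v), con, size = 4, endian = "little")
  else writeBin(as.numeric(v), con, size = 8, endian = "little")
  meta <- patterns$meta
  lab <- meta$label; lab[is.na(lab)] <- -1L
  writeBin(as.integer(lab), con, size = 4, endian = "little")
  for (f in c("alpha", "beta", "gamma", "fluence")) {
    writeBin(as.numeric(meta[[f]]), con, size = 8, endian = "little")
  }
  invisible(path)
}

#' Load a pattern set
#'
#' @param path Path written by [save_patterns()].
#' @return A [pattern_set()].
#' @export
load_patterns <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readChar(con, 8, useBytes = TRUE)
  if (!identical(magic, .spipat_magic)) stop("not a spimix pattern file: ", path)
  hlen <- readBin(con, "integer", 1, size = 4, endian = "little")
  hdr <- jsonlite::fromJSON(rawToChar(readBin(con, "raw", hlen)))
  h <- hdr$h; w <- hdr$w; n <- hdr$n
  mask <- matrix(readBin(con, "integer", h * w, size = 1) > 0, h, w)
  v <- if (identical(hdr$dtype, "int32")) {
    readBin(con, "integer", h * w * n, size = 4, endian = "little")
  } else {
    readBin(con, "numeric", h * w * n, size = 8, endian = "little")
  }
  lab <- readBin(con, "integer", n, size = 4, endian = "little")
  lab[lab < 0] <- NA_integer_
  meta <- data.frame(label = lab)
  for (f in c("alpha", "beta", "gamma", "fluence")) {
    meta[[f]] <- readBin(con, "numeric", n, size = 8, endian = "little")
  }
  geometry <- NULL
  if (!is.null(hdr$geometry)) {
    geometry <- detector_geometry(hdr$geometry$wavelength,
                                  hdr$geometry$distance, hdr$geometry$shape,
                                  hdr$geometry$pixel_um,
                                  hdr$geometry$beamstop_px)
  }
  pattern_set(array(as.numeric(v), c(h, w, n)), mask, meta, geometry)
}

#' Run configuration
#'
#' Bundle of all tunable parameters for a simulation + classification run.
#' Defaults are the full-scale reference simulation conditions
#' (1 A wavelength, 512x512 detector with 300 um pixels, 10x10
#' beam stop, 2e12 photons per pulse into a 0.1 um focus with 10% jitter,
#' CC-margin threshold 0.02, 10 iterations).
#'
#' @param wavelength Wavelength in Angstrom.
#' @param distance Sample-to-detector distance in m.
#' @param shape Detector size in pixels (length-2, even).
#' @param pixel_um Pixel pitch in micrometers.
#' @param beamstop_px Beam-stop side in pixels.
#' @param photons_per_pulse Photons per pulse.
#' @param focus_um Beam focus diameter in micrometers.
#' @param jitter_sd Relative fluence jitter.
#' @param counts Patterns per species.
#' @param threshold CC-margin classification threshold (>= 0).
#' @param max_iter Iteration cap.
#' @param stop_tol Stop when the fraction of patterns whose class or
#'   orientation changed falls below this.
#' @param delta_deg Orientation-grid angular step in degrees.
#' @param n_theta Angular bins of the polar transform (power of two).
#' @param oversample Reciprocal-grid voxels per detector pixel step.
#' @param atom_sigma Gaussian atom width in Angstrom.
#' @param seed Integer random seed.
#' @return Object of class `"run_config"` (a named list).
#' @export
run_config <- function(wavelength = 1, distance = 0.5, shape = c(512, 512),
                       pixel_um = 300, beamstop_px = 10,
                       photons_per_pulse = 2e12, focus_um = 0.1,
                       jitter_sd = 0.10, counts = c(20000, 10000, 5000),
                       threshold = 0.02, max_iter = 10, stop_tol = 0.001,
                       delta_deg = 6, n_theta = 256, oversample = 2,
                       atom_sigma = 1.0, seed = 1) {
  cfg <- list(wavelength = wavelength, distance = distance,
              shape = as.integer(shape), pixel_um = pixel_um,
              beamstop_px = as.integer(beamstop_px),
              photons_per_pulse = photons_per_pulse, focus_um = focus_um,
              jitter_sd = jitter_sd, counts = as.integer(counts),
              threshold = threshold, max_iter = as.integer(max_iter),
              stop_tol = stop_tol, delta_deg = delta_deg,
              n_theta = as.integer(n_theta), oversample = oversample,
              atom_sigma = atom_sigma, seed = as.integer(seed))
  .validate_config(cfg)
  structure(cfg, class = "run_config")
}

.validate_config <- function(cfg) {
  with(cfg, {
    stopifnot(wavelength > 0, distance > 0, pixel_um > 0,
              photons_per_pulse > 0, focus_um > 0, jitter_sd >= 0,
              threshold >= 0, max_iter >= 1, stop_tol >= 0,
              delta_deg > 0, delta_deg < 90, oversample > 0,
              atom_sigma > 0, all(counts > 0))
    if (any(shape %% 2 != 0)) stop("detector shape must be even-sided")
    if (bitwAnd(n_theta, n_theta - 1L) != 0L)
      stop("n_theta must be a power of two")
  })
  invisible(cfg)
}

#' @export
print.run_config <- function(x, ...) {
  cat("run configuration:\n")
  for (f in names(x)) {
    cat(sprintf("  %-18s %s\n", f, paste(format(x[[f]]), collapse = " ")))
  }
  invisible(x)
}

#' Detector geometry implied by a configuration
#' @param cfg A [run_config()].
#' @return A [detector_geometry()].
#' @export
config_geometry <- function(cfg) {
  detector_geometry(cfg$wavelength, cfg$distance, cfg$shape, cfg$pixel_um,
                    cfg$beamstop_px)
}

#' Beam model implied by a configuration
#' @param cfg A [run_config()].
#' @return A [beam_model()].
#' @export
config_beam <- function(cfg) {
  beam_model(cfg$photons_per_pulse, cfg$focus_um, cfg$jitter_sd)
}

#' Read / write a run configuration as YAML
#'
#' @param path YAML file path.
#' @return [read_config()] returns a [run_config()]; [write_config()]
#'   returns `path` invisibly.
#' @export
read_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(run_config, y)
}

#' @rdname read_config
#' @param cfg A [run_config()].
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}
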