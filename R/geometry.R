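#' Detector geometry
#'
#' Flat photon-counting detector normal to the beam.  Reciprocal space uses
#' the crystallographic convention \eqn{|q| = 2 \sin\theta / \lambda} (units
#' 1/Angstrom), so the resolution of a pixel is \eqn{d = 1/|q|}.  The beam
#' center is at pixel coordinate `(shape + 1) / 2` in each dimension, i.e.
#' between the four central pixels for an even-sided detector, which makes
#' the pixel grid exactly centrosymmetric about the beam.
#'
#' @param wavelength X-ray wavelength in Angstrom.
#' @param distance Sample-to-detector distance in meters.
#' @param shape Integer vector of length 2, detector size in pixels (rows,
#'   columns).
#' @param pixel_um Pixel pitch in micrometers.
#' @param beamstop_px Side length, in pixels, of the square beam-stop mask
#'   centered on the beam (0 for none).
#' @return Object of class `"detector_geometry"`.
#' @export
#' @examples
#' # geometry used for the SPARTA-type simulations: 6.6 A at the edge
#' g <- detector_geometry(wavelength = 1, distance = 0.5,
#'                        shape = c(512, 512), pixel_um = 300,
#'                        beamstop_px = 10)
#' round(edge_resolution(g), 1)
detector_geometry <- function(wavelength, distance, shape, pixel_um,
                              beamstop_px = 0) {
  shape <- as.integer(shape)
  if (length(shape) == 1) shape <- c(shape, shape)
  stopifnot(wavelength > 0, distance > 0, all(shape >= 2), pixel_um > 0,
            beamstop_px >= 0)
  structure(
    list(wavelength = wavelength, distance = distance, shape = shape,
         pixel_um = pixel_um, beamstop_px = as.integer(beamstop_px),
         center = (shape + 1) / 2),
    class = "detector_geometry")
}

#' @export
print.detector_geometry <- function(x, ...) {
  cat(sprintf(paste0("detector: %dx%d px, %.0f um pitch, D = %.3g m, ",
                     "lambda = %.3g A\n  edge resolution %.2f A, ",
                     "beam stop %dx%d px\n"),
              x$shape[1], x$shape[2], x$pixel_um, x$distance, x$wavelength,
              edge_resolution(x), x$beamstop_px, x$beamstop_px))
  invisible(x)
}

#' Scattering angle and momentum transfer at a detector radius
#'
#' @param r_px In-plane distance from the beam center in pixels.
#' @param geometry A [detector_geometry()].
#' @return List with `two_theta` (radians), `q` (1/Angstrom) and the
#'   in-plane/axial components `q_ip`, `q_z` of the momentum transfer.
#' @keywords internal
.q_at_radius <- function(r_px, geometry) {
  r_m <- r_px * geometry$pixel_um * 1e-6
  two_theta <- atan2(r_m, geometry$distance)
  q <- 2 * sin(two_theta / 2) / geometry$wavelength
  list(two_theta = two_theta, q = q,
       q_ip = sin(two_theta) / geometry$wavelength,
       q_z = (cos(two_theta) - 1) / geometry$wavelength)
}

#' Resolution at the detector edge
#'
#' `1 / |q|` at the center of the outermost pixel on the detector's short
#' axis (`(n - 1)/2` pixels from the beam center): the resolution of the
#' outermost recorded sample, the conventional single-number resolution of
#' a pattern.
#'
#' @param geometry A [detector_geometry()].
#' @return Resolution in Angstrom.
#' @export
edge_resolution <- function(geometry) {
  1 / .q_at_radius((min(geometry$shape) - 1) / 2, geometry)$q
}

#' Per-pixel reciprocal vectors and solid angles (Ewald map)
#'
#' For every pixel, the scattering vector `q = k_out - k_in` (lab frame,
#' 1/Angstrom; `k_in` along +z) and the solid angle subtended by the pixel,
#' `Omega = (p^2 / D^2) cos^3(2 theta)` (flat-detector formula).  All `q`
#' lie on the Ewald sphere of radius `1/lambda` centered at
#' `(0, 0, -1/lambda)`; `q_z <= 0` everywhere and `|q| = 0` at the beam
#' center.
#'
#' @param geometry A [detector_geometry()].
#' @return Object of class `"ewald_map"`: list with `qx`, `qy`, `qz`,
#'   `omega` (matrices of the detector shape), `mask` (logical matrix, TRUE
#'   where the pixel is usable, i.e. outside the beam stop), and the
#'   generating `geometry`.
#' @export
ewald_map <- function(geometry) {
  h <- geometry$shape[1]; w <- geometry$shape[2]
  cx <- geometry$center[1]; cy <- geometry$center[2]
  x <- (seq_len(h) - cx)           # rows
  y <- (seq_len(w) - cy)           # columns
  X <- matrix(x, h, w)
  Y <- matrix(y, h, w, byrow = TRUE)
  r <- sqrt(X^2 + Y^2)
  qa <- .q_at_radius(r, geometry)
  phi <- atan2(Y, X)
  qx <- qa$q_ip * cos(phi)
  qy <- qa$q_ip * sin(phi)
  qz <- matrix(qa$q_z, h, w)
  p_m <- geometry$pixel_um * 1e-6
  omega <- (p_m^2 / geometry$distance^2) * cos(qa$two_theta)^3
  mask <- matrix(TRUE, h, w)
  if (geometry$beamstop_px > 0) {
    half <- geometry$beamstop_px / 2
    mask[abs(X) <= half & abs(Y) <= half] <- FALSE
  }
  structure(list(qx = qx, qy = qy, qz = qz, omega = matrix(omega, h, w),
                 mask = mask, geometry = geometry),
            class = "ewald_map")
}

#' Stack the q vectors of an Ewald map as an N x 3 matrix
#' @param ewald An [ewald_map()].
#' @return Matrix with one row per pixel (column-major pixel order).
#' @keywords internal
.ewald_qmat <- function(ewald) {
  cbind(as.vector(ewald$qx), as.vector(ewald$qy), as.vector(ewald$qz))
}

#' Geometry of the 2x-downsampled detector
#'
#' 2x2 binning doubles the pixel pitch and halves the pixel counts; the
#' physical extent, and therefore the edge resolution, is unchanged.
#'
#' @param geometry A [detector_geometry()].
#' @return A [detector_geometry()] for the binned detector.
#' @export
downsample_geometry <- function(geometry) {
  stopifnot(all(geometry$shape %% 2 == 0))
  detector_geometry(geometry$wavelength, geometry$distance,
                    geometry$shape %/% 2, geometry$pixel_um * 2,
                    beamstop_px = ceiling(geometry$beamstop_px / 2))
}
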