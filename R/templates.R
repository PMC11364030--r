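#' Initial 3D intensity templates from predicted structures
#'
#' A template is `|F(q)|^2` of a (predicted) atomic model sampled on the
#' same reciprocal grid the reconstruction uses.  Two routes are available:
#'
#' * `"analytic"` (default): the Gaussian-atom transform evaluated in closed
#'   form at every grid point — exact at any q, no gridding artifacts.
#' * `"density_fft"`: rasterize the electron density ([model_to_density()])
#'   and take its discrete Fourier transform.  This mirrors the
#'   density-map-then-transform construction and is kept as an independent
#'   cross-check; it is accurate only while the density grid samples the
#'   Gaussian atoms finely (voxel below about `sigma`) and the box is padded.
#'
#' @param model A (predicted) [atomic_model()]; it is centered on its
#'   electron centroid before transforming.
#' @param n Grid side in voxels.
#' @param dq Grid step in 1/Angstrom; `n/2 * dq` must reach the detector
#'   corner |q| for the geometry the patterns were recorded with (see
#'   [volume_grid()]).
#' @param sigma Gaussian atom width in Angstrom.
#' @param method `"analytic"` or `"density_fft"`.
#' @return An [intensity_volume()], non-negative and Friedel-symmetric.
#' @export
build_template <- function(model, n, dq, sigma = default_atom_sigma,
                           method = c("analytic", "density_fft")) {
  method <- match.arg(method)
  model <- center_model(model)
  if (method == "analytic") {
    return(model_to_intensity(model, n, dq, sigma))
  }
  # density route: real-space box L = 1/dq sampled at n voxels
  voxel <- 1 / (n * dq)
  xyz <- model_xyz(model)
  if (max(abs(xyz)) + 5 * sigma > (n / 2) * voxel) {
    stop("grid too coarse for this model: the real-space box 1/dq cannot ",
         "contain it; decrease dq or use method = 'analytic'")
  }
  if (voxel > sigma) {
    warning("density voxel exceeds the atom width; the density_fft route ",
            "will alias; prefer method = 'analytic'")
  }
  rho <- model_to_density(model, voxel, n, sigma)
  ctr <- floor(n / 2) + 1
  sh <- c(seq(ctr, n), seq_len(ctr - 1))       # ifftshift
  a <- rho$data[sh, sh, sh]
  Fg <- stats::fft(a, inverse = TRUE) * voxel^3  # exp(+2 pi i q.r) convention
  ush <- c(seq(n - ctr + 2, n), seq_len(n - ctr + 1))  # fftshift
  I <- Mod(Fg[ush, ush, ush])^2
  friedel_symmetrize(intensity_volume(I, dq))
}

#' Downsample a pattern by a factor of two
#'
#' 2x2 photon-count sum binning: total counts are conserved and sums of
#' Poisson counts remain Poisson.  A binned pixel of the mask is masked if
#' any constituent pixel was masked.
#'
#' @param x Count matrix (even-sided) or a [pattern_set()].
#' @param mask Optional logical matrix binned alongside a matrix `x`.
#' @return Same type as `x`: binned matrix (with attribute `"mask"` when a
#'   mask was supplied) or a binned [pattern_set()] with updated geometry.
#' @export
downsample_pattern <- function(x, mask = NULL) {
  bin2 <- function(m) {
    d <- dim(m)
    if (any(d %% 2 != 0)) stop("pattern dimensions must be even")
    a <- m
    dim(a) <- c(2, d[1] %/% 2, d[2])
    a <- colSums(a)
    a <- aperm(a, c(2, 1))
    dim(a) <- c(2, d[2] %/% 2, d[1] %/% 2)
    t(colSums(a))
  }
  if (inherits(x, "pattern_set")) {
    d <- dim(x$patterns)
    out <- array(0, c(d[1] %/% 2, d[2] %/% 2, d[3]))
    for (i in seq_len(d[3])) out[, , i] <- bin2(x$patterns[, , i])
    newmask <- bin2(1 - x$mask) == 0
    geom <- if (is.null(x$geometry)) NULL else downsample_geometry(x$geometry)
    return(pattern_set(out, newmask, x$meta, geom))
  }
  out <- bin2(x)
  if (!is.null(mask)) attr(out, "mask") <- bin2(1 - mask) == 0
  out
}
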