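#' Pattern-template matching
#'
#' The orientation/classification engine compares every diffraction pattern
#' with Ewald-sphere slices of every template.  Both are resampled onto a
#' common polar lattice centered on the beam; the in-plane (self-rotation)
#' angle gamma then acts as an exact cyclic shift along the angular axis —
#' rotating the particle about the beam axis rotates its Ewald slice in
#' plane even on the curved sphere — so the Pearson correlation at all
#' `n_theta` gamma values is obtained at once by FFT cross-correlation
#' along that axis, with per-shift renormalization under the joint validity
#' mask, exactly equal to evaluating the masked Pearson at every shift.
#'
#' `CC_max(n, m)` is the maximum of these correlations over all grid
#' directions and shifts for pattern `n` against template `m`; its argmax is
#' the recovered orientation.
#'
#' @name match
NULL

#' Polar lattice for a detector
#'
#' Radial bins span the annulus between the beam-stop corner and the
#' largest full circle inscribed in the detector (with a one-pixel guard
#' for bilinear support); angular bins divide the full circle.
#'
#' @param geometry A [detector_geometry()].
#' @param n_theta Angular bins (power of two).
#' @param n_r Radial bins; default twice the annulus width in pixels.
#' @return Object of class `"polar_spec"`: radii `r` (pixels), angles
#'   `theta`, and the per-bin Ewald `q` vectors (`n_theta*n_r` x 3).
#' @export
polar_spec <- function(geometry, n_theta = 64, n_r = NULL) {
  half <- min(geometry$shape) / 2
  r_min <- if (geometry$beamstop_px > 0)
    geometry$beamstop_px / 2 * sqrt(2) + 1.5 else 1
  r_max <- half - 1.5
  if (r_max <= r_min) stop("detector too small for the beam stop")
  if (is.null(n_r)) n_r <- floor(2 * (r_max - r_min)) + 1
  r <- seq(r_min, r_max, length.out = n_r)
  theta <- 2 * pi * (seq_len(n_theta) - 1) / n_theta
  qa <- .q_at_radius(r, geometry)
  # q on the Ewald sphere for each (theta, r); theta varies fastest
  qx <- outer(cos(theta), qa$q_ip)
  qy <- outer(sin(theta), qa$q_ip)
  qz <- matrix(qa$q_z, n_theta, n_r, byrow = TRUE)
  structure(list(r = r, theta = theta, n_theta = n_theta, n_r = n_r,
                 q = cbind(as.vector(qx), as.vector(qy), as.vector(qz)),
                 geometry = geometry),
            class = "polar_spec")
}

#' Transform a detector image to polar coordinates
#'
#' Bilinear sampling on the `(r, theta)` lattice of a [polar_spec()] (or an
#' ad hoc lattice given `n_r`/`n_theta`); bins whose bilinear support
#' touches a masked or out-of-image pixel are marked invalid.
#'
#' @param image Numeric matrix.
#' @param mask Logical matrix (TRUE = usable), or `NULL`.
#' @param spec A [polar_spec()]; alternatively pass `n_r` and `n_theta` to
#'   build a beam-centered lattice for a bare image.
#' @param n_r,n_theta Used only when `spec` is `NULL`.
#' @return Object of class `"polar_image"`: `data` and `valid` matrices of
#'   dimension `n_theta x n_r`, plus the lattice.
#' @export
to_polar <- function(image, mask = NULL, spec = NULL, n_r = NULL,
                     n_theta = 64) {
  if (is.null(spec)) {
    h <- nrow(image); w <- ncol(image)
    half <- min(h, w) / 2
    if (is.null(n_r)) n_r <- floor(half)
    if (n_r > half) stop("n_r exceeds the image half-width")
    r <- seq(1, half - 1.5, length.out = n_r)
    theta <- 2 * pi * (seq_len(n_theta) - 1) / n_theta
    center <- c((h + 1) / 2, (w + 1) / 2)
  } else {
    r <- spec$r; theta <- spec$theta
    n_r <- spec$n_r; n_theta <- spec$n_theta
    center <- spec$geometry$center
  }
  x <- center[1] + outer(cos(theta), r)
  y <- center[2] + outer(sin(theta), r)
  s <- .bilinear_sample(image, mask, as.vector(x), as.vector(y))
  structure(list(data = matrix(s$value, n_theta, n_r),
                 valid = matrix(s$valid, n_theta, n_r),
                 r = r, theta = theta),
            class = "polar_image")
}

#' @export
print.polar_image <- function(x, ...) {
  cat(sprintf("polar image: %d theta x %d r bins, %.1f%% valid\n",
              nrow(x$data), ncol(x$data), 100 * mean(x$valid)))
  invisible(x)
}

#' Cut an Ewald-sphere slice from a 3D intensity
#'
#' Trilinear interpolation of the volume at the rotated Ewald q of every
#' detector pixel, `R q(pixel)`.  Pixels under the beam stop, outside the
#' volume, or touching missing (uncovered) voxels are invalid.
#'
#' @param volume An [intensity_volume()].
#' @param orient An [orientation()] or 3x3 rotation matrix.
#' @param ewald An [ewald_map()].
#' @return List with `data` and `valid` matrices of the detector shape.
#' @export
slice_volume <- function(volume, orient, ewald) {
  R <- if (inherits(orient, "orientation")) orient$R else orient
  q <- .ewald_qmat(ewald) %*% t(R)
  s <- .slice_values(volume, q)
  h <- nrow(ewald$qx)
  data <- matrix(s$value, h, ncol(ewald$qx))
  valid <- matrix(s$valid, h, ncol(ewald$qx)) & ewald$mask
  data[!valid] <- 0
  list(data = data, valid = valid)
}

# Slice a volume directly onto the polar Ewald lattice at direction
# (alpha, beta, gamma = 0).  Because gamma is an exact cyclic shift of the
# theta axis, slices at all gamma are shifts of this one.
.slice_polar <- function(volume, alpha, beta, pspec, gamma = 0) {
  R <- euler_to_matrix(alpha, beta, gamma)
  s <- .slice_values(volume, pspec$q %*% t(R))
  structure(list(data = matrix(s$value, pspec$n_theta, pspec$n_r),
                 valid = matrix(s$valid, pspec$n_theta, pspec$n_r),
                 r = pspec$r, theta = pspec$theta),
            class = "polar_image")
}

#' Pearson correlation between two masked images
#'
#' Plain Pearson r over the jointly valid pixels.  Returns `NA` when fewer
#' than two pixels are valid or either side has zero variance; callers
#' treat `NA` as minus infinity when maximizing.
#'
#' @param a,b Numeric vectors/matrices of equal length.
#' @param valid Logical, jointly valid entries; `NULL` means all.
#' @return Scalar in `[-1, 1]`, or `NA`.
#' @export
pearson_cc <- function(a, b, valid = NULL) {
  a <- as.vector(a); b <- as.vector(b)
  if (!is.null(valid)) {
    a <- a[valid]; b <- b[valid]
  }
  n <- length(a)
  if (n < 2) return(NA_real_)
  va <- stats::var(a); vb <- stats::var(b)
  if (va == 0 || vb == 0) return(NA_real_)
  stats::cor(a, b)
}

# FFT terms of one side of the masked cross-correlation.
# x: polar_image.  Returns fft along theta of {m, x m, x^2 m}.
.polar_fft_terms <- function(x) {
  m <- x$valid * 1
  d <- x$data * m
  list(M = stats::mvfft(m), X = stats::mvfft(d), X2 = stats::mvfft(d * d),
       radial_mask = all(x$valid == matrix(x$valid[1, ],
                                           nrow(x$valid), ncol(x$valid),
                                           byrow = TRUE)))
}

#' Masked Pearson correlation at every in-plane rotation
#'
#' Evaluates the Pearson correlation between a pattern and a slice in polar
#' coordinates at all `n_theta` cyclic shifts of the slice's angular axis,
#' renormalizing per shift under the joint validity mask; this equals the
#' brute-force loop that shifts, masks and correlates at each gamma, to
#' floating-point accuracy.  The six masked sums required per shift (joint
#' count, masked sums and squares of both sides, cross term) are each a
#' cyclic cross-correlation along theta and are computed via FFTs; when
#' both validity masks are angularly invariant only the cross term varies
#' with shift and the remaining sums collapse to constants (same result,
#' fewer transforms).
#'
#' @param pattern_polar,slice_polar [to_polar()] images on one lattice.
#' @return List with `cc` (length `n_theta`, the Pearson at slice shift
#'   `k-1` bins, i.e. gamma = `2 pi (k-1)/n_theta`), `cc_max`, and
#'   `gamma` of the maximum.  All-invalid overlaps give `NA` entries.
#' @export
ccmax_over_gamma <- function(pattern_polar, slice_polar) {
  stopifnot(all(dim(pattern_polar$data) == dim(slice_polar$data)))
  A <- .polar_fft_terms(pattern_polar)
  B <- .polar_fft_terms(slice_polar)
  cc <- .cc_shift_profile(A, B, nrow(pattern_polar$data))
  k <- which.max(ifelse(is.na(cc), -Inf, cc))
  list(cc = cc, cc_max = cc[k],
       gamma = 2 * pi * (k - 1) / length(cc))
}

# Shift profile of masked Pearson CC from FFT terms of both sides.
# Correlates pattern (fixed) against the slice shifted by k bins:
# sums over theta of A(theta) * B(theta + k) = IFFT(conj(FFT A) FFT B).
.cc_shift_profile <- function(A, B, n_theta) {
  xcorr <- function(Fa, Fb) {
    prod <- Conj(Fa) * Fb
    Re(stats::mvfft(as.matrix(rowSums(prod)), inverse = TRUE)) / n_theta
  }
  if (A$radial_mask && B$radial_mask) {
    # masks are theta-invariant: all sums except the cross term are
    # shift-independent
    N <- Re(sum(Conj(A$M[1, ]) * B$M[1, ])) / n_theta
    SP <- Re(sum(Conj(A$X[1, ]) * B$M[1, ])) / n_theta
    SPP <- Re(sum(Conj(A$X2[1, ]) * B$M[1, ])) / n_theta
    SS <- Re(sum(Conj(A$M[1, ]) * B$X[1, ])) / n_theta
    SSS <- Re(sum(Conj(A$M[1, ]) * B$X2[1, ])) / n_theta
    SPS <- xcorr(A$X, B$X)
  } else {
    N <- xcorr(A$M, B$M)
    SP <- xcorr(A$X, B$M)
    SPP <- xcorr(A$X2, B$M)
    SS <- xcorr(A$M, B$X)
    SSS <- xcorr(A$M, B$X2)
    SPS <- xcorr(A$X, B$X)
  }
  vp <- rep_len(N * SPP - SP^2, n_theta)
  vs <- rep_len(N * SSS - SS^2, n_theta)
  num <- rep_len(N * SPS - SP * SS, n_theta)
  Nv <- rep_len(N, n_theta)
  # relative guards: declare the CC undefined when a side's variance is
  # zero up to FFT round-off (relative to its raw second moment)
  tolp <- 1e-9 * rep_len(N * SPP, n_theta)
  tols <- 1e-9 * rep_len(N * SSS, n_theta)
  cc <- rep(NA_real_, n_theta)
  good <- which(Nv >= 2 & vp > tolp & vs > tols)
  cc[good] <- num[good] / sqrt(vp[good] * vs[good])
  pmin(1, pmax(-1, cc))
}
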