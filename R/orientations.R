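#' Orientations on SO(3)
#'
#' Particle orientations are parameterized by intrinsic zyz Euler angles
#' \eqn{(\alpha, \beta, \gamma)} with the X-ray beam along +z:
#' \eqn{R(\alpha,\beta,\gamma) = R_z(\alpha) R_y(\beta) R_z(\gamma)}.
#' \eqn{(\alpha, \beta)} select the direction from which the Ewald sphere
#' cuts the 3D intensity and \eqn{\gamma} is the in-plane self-rotation of
#' the resulting pattern, which is why \eqn{\gamma} can be searched as a
#' cyclic shift of the pattern in polar coordinates.
#'
#' @name orientations
NULL

.rot_z <- function(a) {
  ca <- cos(a); sa <- sin(a)
  matrix(c(ca, sa, 0, -sa, ca, 0, 0, 0, 1), 3, 3)
}

.rot_y <- function(b) {
  cb <- cos(b); sb <- sin(b)
  matrix(c(cb, 0, -sb, 0, 1, 0, sb, 0, cb), 3, 3)
}

#' Convert zyz Euler angles to a rotation matrix
#'
#' @param alpha,beta,gamma Euler angles in radians (intrinsic zyz).
#' @return 3x3 rotation matrix `R = Rz(alpha) %*% Ry(beta) %*% Rz(gamma)`.
#' @export
#' @examples
#' euler_to_matrix(0, 0, 0)           # identity
#' euler_to_matrix(pi / 2, 0, 0)      # quarter turn about the beam axis
euler_to_matrix <- function(alpha, beta, gamma) {
  .rot_z(alpha) %*% .rot_y(beta) %*% .rot_z(gamma)
}

#' Recover zyz Euler angles from a rotation matrix
#'
#' Inverse of [euler_to_matrix()] with `beta` in `[0, pi]`.  At gimbal lock
#' (`beta` = 0 or pi, where only `alpha + gamma` resp. `alpha - gamma` is
#' determined) the convention `gamma = 0` is used.
#'
#' @param R 3x3 rotation matrix.
#' @return Numeric vector `c(alpha, beta, gamma)` in radians.
#' @export
matrix_to_euler <- function(R) {
  stopifnot(is.matrix(R), all(dim(R) == c(3, 3)))
  cb <- max(-1, min(1, R[3, 3]))
  beta <- acos(cb)
  if (abs(sin(beta)) < 1e-12) {
    # gimbal lock: only alpha +/- gamma is determined; put it all in alpha
    if (cb > 0) alpha <- atan2(R[2, 1], R[1, 1])
    else alpha <- atan2(-R[2, 1], -R[1, 1])
    gamma <- 0
  } else {
    alpha <- atan2(R[2, 3], R[1, 3])
    gamma <- atan2(R[3, 2], -R[3, 1])
  }
  c(alpha = alpha %% (2 * pi), beta = beta, gamma = gamma %% (2 * pi))
}

#' Construct an orientation object
#'
#' @param alpha,beta,gamma zyz Euler angles in radians.
#' @return An object of class `"orientation"`: a list with the angles and the
#'   cached rotation matrix `R`.
#' @export
orientation <- function(alpha, beta, gamma) {
  structure(
    list(alpha = alpha, beta = beta, gamma = gamma,
         R = euler_to_matrix(alpha, beta, gamma)),
    class = "orientation")
}

#' @export
print.orientation <- function(x, ...) {
  cat(sprintf("orientation (zyz): alpha=%.3f beta=%.3f gamma=%.3f rad\n",
              x$alpha, x$beta, x$gamma))
  invisible(x)
}

#' Quasi-uniform orientation grid for template slicing
#'
#' Builds a set of slice directions \eqn{(\alpha, \beta)} by placing rings of
#' constant \eqn{\beta} at angular spacing `delta` and filling each ring with
#' `ceiling(2 pi sin(beta) / delta)` equally spaced \eqn{\alpha} samples, so
#' the areal density of directions is approximately constant on the sphere.
#' The in-plane angle \eqn{\gamma} is not discretized here; it is resolved
#' exhaustively by the polar-FFT correlation in the matching step.
#'
#' By default the full sphere of directions is covered.  For intensities the
#' Friedel redundancy of a single pattern is the in-plane rotation
#' \eqn{\gamma \to \gamma + \pi} (in the flat-Ewald limit), not the antipodal
#' slice direction: the slice from direction \eqn{-m} is the mirror image of
#' the slice from \eqn{+m} and, for a chiral particle, is not reachable by
#' any in-plane rotation.  Restricting directions to a half-sphere
#' (`half = TRUE`) therefore mis-orients patterns whose true direction lies
#' in the other half and is provided only for experimentation.
#'
#' @param delta Angular step in radians (`0 < delta < pi/2`).
#' @param half If `TRUE`, cover only `beta` in `[0, pi/2]`.
#' @return An object of class `"orientation_grid"`: list with matrix `dirs`
#'   (columns `alpha`, `beta`), `delta`, and `half`.
#' @export
sample_grid <- function(delta, half = FALSE) {
  stopifnot(is.numeric(delta), length(delta) == 1, delta > 0, delta < pi / 2)
  beta_max <- if (half) pi / 2 else pi
  n_rings <- ceiling(beta_max / delta)
  betas <- seq(0, beta_max, length.out = n_rings + 1)
  dirs <- list()
  for (b in betas) {
    n_a <- max(1L, ceiling(2 * pi * sin(b) / delta))
    # stagger alternate rings by half a step to avoid meridian alignment
    off <- (which(betas == b) %% 2) * pi / n_a
    alphas <- (2 * pi * (seq_len(n_a) - 1) / n_a + off) %% (2 * pi)
    dirs[[length(dirs) + 1]] <- cbind(alpha = alphas, beta = rep(b, n_a))
  }
  dirs <- do.call(rbind, dirs)
  structure(list(dirs = dirs, delta = delta, half = half),
            class = "orientation_grid")
}

#' @export
print.orientation_grid <- function(x, ...) {
  cat(sprintf("orientation grid: %d directions, delta = %.2f deg (%s sphere)\n",
              nrow(x$dirs), x$delta * 180 / pi,
              if (x$half) "half" else "full"))
  invisible(x)
}

#' Draw Haar-uniform random orientations
#'
#' `alpha` and `gamma` are uniform on `[0, 2 pi)` and `cos(beta)` uniform on
#' `[-1, 1]`, which together give the Haar (rotation-invariant) measure on
#' SO(3) in zyz Euler angles.
#'
#' @param n Number of orientations.
#' @return List of `n` [orientation()] objects.
#' @export
sample_random <- function(n) {
  stopifnot(n >= 1)
  alpha <- stats::runif(n, 0, 2 * pi)
  beta <- acos(stats::runif(n, -1, 1))
  gamma <- stats::runif(n, 0, 2 * pi)
  lapply(seq_len(n), function(i) orientation(alpha[i], beta[i], gamma[i]))
}

#' Friedel-equivalent orientation
#'
#' A diffraction pattern of a centrosymmetric intensity (the modulus of the
#' transform of a real density) is unchanged, in the flat-Ewald limit, when
#' the particle is rotated by pi about the beam axis: the pattern rotates by
#' pi in plane and Friedel symmetry maps it back onto itself.  A recovered
#' orientation is therefore only determined up to this mate.
#'
#' @param R 3x3 rotation matrix.
#' @return The mate `R %*% Rz(pi)`.
#' @export
friedel_mate <- function(R) R %*% .rot_z(pi)

#' Geodesic distance between rotations
#'
#' `acos((tr(R1' R2) - 1) / 2)`, the rotation angle taking one orientation to
#' the other, in radians.
#'
#' @param R1,R2 3x3 rotation matrices.
#' @param friedel If `TRUE` (default), return the minimum over the
#'   Friedel-equivalent mate of `R2` (see [friedel_mate()]).
#' @return Angle in radians in `[0, pi]`.
#' @export
rotation_distance <- function(R1, R2, friedel = TRUE) {
  ang <- function(A, B) {
    t <- (sum(diag(crossprod(A, B))) - 1) / 2
    acos(max(-1, min(1, t)))
  }
  d <- ang(R1, R2)
  if (friedel) d <- min(d, ang(R1, friedel_mate(R2)))
  d
}
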