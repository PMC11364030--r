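#' 3D diffraction-intensity volumes
#'
#' An intensity volume holds \eqn{I(q) = |F(q)|^2} on a cubic reciprocal
#' grid with step `dq` (1/Angstrom).  The zero-frequency voxel sits at index
#' `floor(n/2) + 1` along each axis.  An optional logical `coverage` array
#' marks voxels whose value is defined; merged reconstructions leave voxels
#' that no pattern touched marked as missing, and slices treat those as
#' invalid pixels rather than fabricating intensity.
#'
#' @param data Numeric 3D array, cubic (`n x n x n`).
#' @param dq Voxel step in 1/Angstrom.
#' @param coverage Optional logical array of the same dimension; `NULL`
#'   means fully covered.
#' @return Object of class `"intensity_volume"`.
#' @export
intensity_volume <- function(data, dq, coverage = NULL) {
  d <- dim(data)
  stopifnot(length(d) == 3, d[1] == d[2], d[2] == d[3], dq > 0)
  if (!is.null(coverage)) stopifnot(all(dim(coverage) == d))
  structure(list(data = data, dq = dq, coverage = coverage),
            class = "intensity_volume")
}

#' @export
print.intensity_volume <- function(x, ...) {
  n <- dim(x$data)[1]
  miss <- if (is.null(x$coverage)) 0 else mean(!x$coverage)
  cat(sprintf(
    "intensity volume: %d^3 voxels, dq = %.4g 1/A (edge |q| = %.4g, d = %.3g A), %.1f%% missing\n",
    n, x$dq, (n / 2) * x$dq, 1 / ((n / 2) * x$dq), 100 * miss))
  invisible(x)
}

#' Reciprocal-space axis coordinates of a volume
#' @param n Grid size per side.
#' @param dq Voxel step.
#' @return Numeric vector of length `n` (1/Angstrom), zero at the center
#'   voxel `floor(n/2) + 1`.
#' @export
q_axis <- function(n, dq) (seq_len(n) - (floor(n / 2) + 1)) * dq

#' Voxel radii |q| of a volume
#' @param volume An [intensity_volume()].
#' @return 3D array of |q| values.
#' @keywords internal
.voxel_qnorm <- function(volume) {
  n <- dim(volume$data)[1]
  ax <- q_axis(n, volume$dq)
  r2 <- outer(outer(ax^2, ax^2, "+"), ax^2, "+")
  sqrt(r2)
}

#' Friedel-symmetrize a volume
#'
#' Averages `I(q)` with `I(-q)`.  For a fully covered volume this is
#' `(I + rev(I)) / 2` on the index-reversed grid; with a coverage mask the
#' average is taken where both mates are present and the present mate is
#' copied where only one is.
#'
#' @param volume An [intensity_volume()].
#' @return The symmetrized volume.
#' @export
friedel_symmetrize <- function(volume) {
  n <- dim(volume$data)[1]
  ctr <- floor(n / 2) + 1
  idx <- 2 * ctr - seq_len(n)         # index of -q; may fall outside 1..n
  ok <- idx >= 1 & idx <= n
  v <- volume$data
  if (is.null(volume$coverage)) {
    m <- v
    m[ok, ok, ok] <- (v[ok, ok, ok] + v[idx[ok], idx[ok], idx[ok]]) / 2
    volume$data <- m
  } else {
    cov <- volume$coverage
    v2 <- array(0, dim(v)); c2 <- array(FALSE, dim(v))
    v2[ok, ok, ok] <- v[idx[ok], idx[ok], idx[ok]]
    c2[ok, ok, ok] <- cov[idx[ok], idx[ok], idx[ok]]
    num <- v * cov + v2 * c2
    den <- cov + c2
    out <- num / pmax(den, 1L)
    out[den == 0L] <- 0
    volume$data <- out
    volume$coverage <- den > 0L
  }
  volume
}

#' Downsample a volume by a factor of two
#'
#' 2x2x2 mean binning; the voxel step doubles, the reciprocal extent is
#' unchanged.  Coverage (if any) is propagated: a binned voxel is covered if
#' any constituent voxel was, and its value is the mean of the covered
#' constituents.
#'
#' @param volume An [intensity_volume()].
#' @return The binned volume.
#' @export
downsample_volume <- function(volume) {
  n <- dim(volume$data)[1]
  if (n %% 2 != 0) stop("volume side must be even to downsample")
  m <- n %/% 2
  bin3 <- function(a) {
    # sum over 2x2x2 blocks via successive axis folding
    dim(a) <- c(2, m, 2, m, 2, m)
    a <- colSums(a)                 # over dim 1 -> (m,2,m,2,m)
    a <- aperm(a, c(2, 1, 3, 4, 5)) # (2,m,m,2,m)
    a <- colSums(a)                 # (m,m,2,m)
    a <- aperm(a, c(3, 1, 2, 4))    # (2,m,m,m)
    colSums(a)                      # (m,m,m)
  }
  if (is.null(volume$coverage)) {
    intensity_volume(bin3(volume$data) / 8, volume$dq * 2)
  } else {
    cnt <- bin3(array(as.numeric(volume$coverage), dim(volume$data)))
    s <- bin3(volume$data * volume$coverage)
    intensity_volume(ifelse(cnt > 0, s / cnt, 0), volume$dq * 2,
                     coverage = cnt > 0)
  }
}

#' Pick the reciprocal grid that matches a detector
#'
#' Chooses the cubic grid on which templates are built and reconstructions
#' accumulated: the voxel step is the per-pixel radial q-step at the detector
#' half-width divided by `oversample`, and the side length is the smallest
#' even number such that the inscribed ball covers the detector-corner |q|
#' plus an interpolation margin.
#'
#' Oversampling the grid relative to the detector pixels keeps trilinear
#' interpolation error small compared with the speckle width of the largest
#' particle in the mixture.
#'
#' @param geometry A [detector_geometry()].
#' @param oversample Voxels per detector pixel step (default 2).
#' @return List with `n` (side) and `dq`.
#' @export
volume_grid <- function(geometry, oversample = 2) {
  half <- min(geometry$shape) / 2
  q_edge <- .q_at_radius(half, geometry)$q
  q_corner <- .q_at_radius(sqrt(sum((geometry$shape / 2)^2)), geometry)$q
  dq <- q_edge / half / oversample
  n <- 2 * ceiling(q_corner / dq + 3)
  n <- n + (n %% 4)   # keep n divisible by 4 so the 2x-binned grid is even
  list(n = as.integer(n), dq = dq)
}
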