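#' Evaluation: resolution curves, confusion matrices, orientation errors
#'
#' These functions compare a run's output against the hidden truth carried
#' in the pattern metadata (labels, orientations) and against ground-truth
#' intensity volumes.  Resolution is reported where the shell correlation
#' first drops below 0.5.
#'
#' @name evaluate
NULL

#' Shell correlation between two volumes
#'
#' Pearson correlation inside spherical shells of |q|, between two volumes
#' on the same grid.  Voxels marked missing in either volume are excluded
#' pairwise; shells with fewer than 10 valid voxel pairs are reported `NA`.
#' The resolution is the first |q| where the curve crosses below 0.5
#' (linear interpolation between shell centers), converted to d = 1/|q|.
#'
#' @param vol_a,vol_b [intensity_volume()] objects with equal `n` and `dq`.
#' @param n_shells Number of shells (default 50).
#' @param q_max Outer |q| bound; default the inscribed-ball radius.
#' @return Object of class `"shell_cc_curve"`: data frame `shells` with
#'   `q_lo`, `q_hi`, `q_mid`, `d` (Angstrom), `cc`, `n`, plus
#'   `resolution` (Angstrom; `NA` if the curve starts below 0.5, `1/q_max`
#'   if it never drops).
#' @export
shell_cc <- function(vol_a, vol_b, n_shells = 50, q_max = NULL) {
  stopifnot(all(dim(vol_a$data) == dim(vol_b$data)),
            isTRUE(all.equal(vol_a$dq, vol_b$dq)))
  n <- dim(vol_a$data)[1]
  if (is.null(q_max)) q_max <- (n / 2) * vol_a$dq
  qn <- .voxel_qnorm(vol_a)
  ok <- qn <= q_max & qn > 0
  if (!is.null(vol_a$coverage)) ok <- ok & vol_a$coverage
  if (!is.null(vol_b$coverage)) ok <- ok & vol_b$coverage
  edges <- seq(0, q_max, length.out = n_shells + 1)
  bin <- findInterval(qn[ok], edges, rightmost.closed = TRUE)
  a <- vol_a$data[ok]; b <- vol_b$data[ok]
  cc <- rep(NA_real_, n_shells); cnt <- integer(n_shells)
  sp <- split(seq_along(bin), factor(bin, levels = seq_len(n_shells)))
  for (s in seq_len(n_shells)) {
    i <- sp[[s]]
    cnt[s] <- length(i)
    if (length(i) >= 10) {
      va <- stats::var(a[i]); vb <- stats::var(b[i])
      if (va > 0 && vb > 0) cc[s] <- stats::cor(a[i], b[i])
    }
  }
  q_mid <- (edges[-1] + edges[-(n_shells + 1)]) / 2
  shells <- data.frame(q_lo = edges[-(n_shells + 1)], q_hi = edges[-1],
                       q_mid = q_mid, d = 1 / q_mid, cc = cc, n = cnt)
  resolution <- .resolution_at_half(q_mid, cc, q_max)
  structure(list(shells = shells, resolution = resolution),
            class = "shell_cc_curve")
}

# First crossing of 0.5, linear interpolation in q between shell centers.
# The search starts where the curve first attains 0.5: the lowest covered
# shells can sit below 0.5 for spurious reasons (few voxel pairs, and for
# small particles almost no angular contrast within a thin shell), and the
# resolution should report where established correlation is lost, not
# leading noise.  Curves that never reach 0.5 give NA; curves that never
# drop report the band limit 1/q_max.
.resolution_at_half <- function(q, cc, q_max) {
  ok <- which(!is.na(cc))
  if (length(ok) == 0) return(NA_real_)
  q <- q[ok]; cc <- cc[ok]
  start <- which(cc >= 0.5)
  if (length(start) == 0) return(NA_real_)
  j0 <- start[1]
  below <- which(cc < 0.5 & seq_along(cc) > j0)
  if (length(below) == 0) return(1 / q_max)
  j <- below[1]
  q_cross <- q[j - 1] + (0.5 - cc[j - 1]) * (q[j] - q[j - 1]) /
    (cc[j] - cc[j - 1])
  1 / q_cross
}

#' @export
print.shell_cc_curve <- function(x, ...) {
  cat(sprintf("shell CC curve: %d shells to q = %.4g 1/A; resolution (CC=0.5): %s A\n",
              nrow(x$shells), max(x$shells$q_hi),
              if (is.na(x$resolution)) "NA" else sprintf("%.1f", x$resolution)))
  invisible(x)
}

#' @export
plot.shell_cc_curve <- function(x, ...) {
  s <- x$shells
  graphics::plot(s$q_mid, s$cc, type = "l", ylim = c(0, 1),
                 xlab = "|q| (1/Angstrom)", ylab = "shell CC", ...)
  graphics::abline(h = 0.5, lty = 3)
  if (!is.na(x$resolution)) {
    graphics::abline(v = 1 / x$resolution, lty = 3)
    graphics::mtext(sprintf("%.1f A", x$resolution), side = 3, adj = 1)
  }
  invisible(x)
}

#' Confusion matrices and classification accuracy per iteration
#'
#' Accuracy is the number of correctly classified patterns divided by the
#' number of successfully classified patterns (unclassified patterns are
#' excluded from the denominator).
#'
#' @param x A `"spi_run"` object, or a list of [assign_classes()] results.
#' @param truth Integer vector of true species labels (defaults to the
#'   pattern metadata of a run).
#' @return List (one element per iteration) of class `"confusion_summary"`:
#'   `matrix` (true species x assigned class + `unclassified`), `accuracy`
#'   (`NA` when nothing was classified), `iteration`.
#' @export
confusion <- function(x, truth = NULL) {
  asgs <- if (inherits(x, "spi_run")) x$assignments else x
  if (is.null(truth)) {
    if (!inherits(x, "spi_run")) stop("truth labels required")
    truth <- x$patterns$meta$label
  }
  lapply(seq_along(asgs), function(it) {
    a <- asgs[[it]]
    if (nrow(a) != length(truth)) stop("label/assignment length mismatch")
    K <- max(truth, na.rm = TRUE)
    amax <- if (all(is.na(a$class))) 0L else max(a$class, na.rm = TRUE)
    M <- max(K, amax, 1)
    cls <- a$class
    tab <- table(factor(truth, levels = seq_len(K)),
                 factor(ifelse(is.na(cls), M + 1, cls), levels = seq_len(M + 1)))
    tab <- as.matrix(tab)
    colnames(tab) <- c(paste0("class", seq_len(M)), "unclassified")
    rownames(tab) <- paste0("species", seq_len(K))
    n_cls <- sum(tab[, seq_len(M)])
    correct <- sum(diag(tab[, seq_len(min(K, M)), drop = FALSE]))
    structure(list(matrix = tab,
                   accuracy = if (n_cls > 0) correct / n_cls else NA_real_,
                   iteration = it),
              class = "confusion_summary")
  })
}

#' @export
print.confusion_summary <- function(x, ...) {
  cat(sprintf("iteration %d: accuracy %s\n", x$iteration,
              if (is.na(x$accuracy)) "NA (nothing classified)"
              else sprintf("%.2f%%", 100 * x$accuracy)))
  print(x$matrix)
  invisible(x)
}

#' Per-pattern orientation error
#'
#' Geodesic SO(3) distance between each pattern's recovered orientation and
#' its true orientation, minimized over the Friedel-equivalent mate of the
#' truth (a pattern determines its orientation only up to an in-plane
#' rotation by pi; see [friedel_mate()]).
#'
#' @param assignment An [assign_classes()] result.
#' @param meta Data frame with truth columns `alpha`, `beta`, `gamma`
#'   (e.g. `pattern_set$meta`).
#' @return Numeric vector of angles in radians (`NA` for unclassified
#'   patterns).
#' @export
orientation_error <- function(assignment, meta) {
  stopifnot(nrow(assignment) == nrow(meta))
  vapply(seq_len(nrow(assignment)), function(i) {
    if (is.na(assignment$class[i])) return(NA_real_)
    Rhat <- euler_to_matrix(assignment$alpha[i], assignment$beta[i],
                            assignment$gamma[i])
    Rtrue <- euler_to_matrix(meta$alpha[i], meta$beta[i], meta$gamma[i])
    rotation_distance(Rhat, Rtrue, friedel = TRUE)
  }, 0)
}
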