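#' Threshold classification, merging, and the outer iteration
#'
#' One iteration of the algorithm: correlate every pattern with every
#' template over all orientations ([compute_cc_table()]), classify each
#' pattern to the template with the highest `CC_max` provided the margin
#' over the runner-up exceeds the threshold (else leave it unclassified),
#' then merge the classified patterns of each class — each pattern's photon
#' counts scattered onto the reciprocal grid along its best-orientation
#' Ewald sphere — into an updated 3D intensity per class.  Every pattern is
#' re-evaluated at every iteration, so early misclassifications can be
#' corrected as the templates improve.
#'
#' @name classify_reconstruct_module
NULL

#' Classify patterns from a CC table
#'
#' A pattern is assigned to the class with the highest `CC_max` if and only
#' if the gap to the second highest exceeds `threshold` (strict); otherwise
#' it is unclassified.  With a single template every pattern with a finite
#' CC is assigned to it.
#'
#' @param table A [compute_cc_table()] result.
#' @param threshold Non-negative CC margin.
#' @return Object of class `"spi_assignment"`: data frame with columns
#'   `class` (integer or `NA` = unclassified), `alpha`, `beta`, `gamma`
#'   (best orientation of the winning class; `NA` when unclassified), `cc`
#'   (winning CC), `margin`.
#' @export
assign_classes <- function(table, threshold) {
  stopifnot(threshold >= 0)
  cc <- table$cc
  np <- nrow(cc); nm <- ncol(cc)
  ccw <- ifelse(is.na(cc), -Inf, cc)
  best <- max.col(ccw, ties.method = "first")
  cc1 <- ccw[cbind(seq_len(np), best)]
  if (nm == 1) {
    margin <- rep(Inf, np)
  } else {
    cc2 <- apply(ccw, 1, function(r) -sort(-r, partial = 2)[2])
    margin <- cc1 - cc2
  }
  classified <- is.finite(cc1) & (margin > threshold)
  cls <- ifelse(classified, best, NA_integer_)
  pick <- function(M) ifelse(classified, M[cbind(seq_len(np), best)], NA_real_)
  out <- data.frame(class = cls,
                    alpha = pick(table$alpha),
                    beta = pick(table$beta),
                    gamma = pick(table$gamma),
                    cc = ifelse(is.finite(cc1), cc1, NA_real_),
                    margin = ifelse(is.finite(margin), margin, NA_real_))
  class(out) <- c("spi_assignment", "data.frame")
  out
}

#' @export
print.spi_assignment <- function(x, ...) {
  n <- nrow(x)
  tab <- table(factor(x$class))
  cat(sprintf("assignment: %d patterns, %d unclassified (%.1f%%)\n",
              n, sum(is.na(x$class)), 100 * mean(is.na(x$class))))
  if (length(tab)) {
    cat("  per class:",
        paste(sprintf("%s:%d", names(tab), tab), collapse = " "), "\n")
  }
  invisible(x)
}

#' Merge classified patterns into per-class 3D intensities
#'
#' For each class, every classified pattern's unmasked pixels are placed at
#' their rotated Ewald positions `R q(pixel)` and accumulated into the
#' reciprocal grid by trilinear scattering; the voxel value is the
#' weight-normalized mean of the deposited photon counts, then Friedel
#' symmetrized.  Voxels no pattern touched are 0 and marked missing.
#'
#' @param patterns A [pattern_set()] (with geometry).
#' @param assignment An [assign_classes()] result.
#' @param n_classes Number of classes (defaults to `max(class)`).
#' @param n,dq Reciprocal grid (defaults from [volume_grid()] of the
#'   pattern geometry).
#' @param oversample Used when `n`/`dq` are derived from the geometry.
#' @param normalize If `TRUE`, rescale each pattern to a common total count
#'   over the unmasked pixels before deposition, suppressing pulse-energy
#'   variation.  Off by default: the correlations that consume the merged
#'   volumes are scale-invariant per shell, so the correction is optional.
#' @return List of [intensity_volume()] (element `k` is `NULL` if class `k`
#'   received no patterns; callers carry the previous template forward).
#' @export
merge_patterns <- function(patterns, assignment, n_classes = NULL,
                           n = NULL, dq = NULL, oversample = 2,
                           normalize = FALSE) {
  geom <- patterns$geometry
  if (is.null(geom)) stop("pattern set carries no detector geometry")
  if (is.null(n) || is.null(dq)) {
    vg <- volume_grid(geom, oversample)
    n <- vg$n; dq <- vg$dq
  }
  if (is.null(n_classes)) n_classes <- max(assignment$class, na.rm = TRUE)
  ew <- ewald_map(geom)
  qm <- .ewald_qmat(ew)
  keep_px <- as.vector(ew$mask)
  out <- vector("list", n_classes)
  for (k in seq_len(n_classes)) {
    idx <- which(!is.na(assignment$class) & assignment$class == k)
    if (length(idx) == 0) next
    s <- array(0, c(n, n, n)); w <- array(0, c(n, n, n))
    if (normalize) {
      totals <- vapply(idx, function(i)
        sum(patterns$patterns[, , i][patterns$mask]), 0)
      ref <- mean(totals[totals > 0])
    }
    for (i in idx) {
      R <- euler_to_matrix(assignment$alpha[i], assignment$beta[i],
                           assignment$gamma[i])
      qrot <- qm[keep_px, , drop = FALSE] %*% t(R)
      vals <- as.vector(patterns$patterns[, , i])[keep_px]
      if (normalize) {
        tot <- sum(patterns$patterns[, , i][patterns$mask])
        if (tot > 0) vals <- vals * (ref / tot)
      }
      acc <- .scatter_values(n, dq, qrot, vals)
      s <- s + acc$sum; w <- w + acc$weight
    }
    cov <- w > 1e-9
    v <- s / pmax(w, 1e-9)
    v[!cov] <- 0
    out[[k]] <- friedel_symmetrize(intensity_volume(v, dq, coverage = cov))
  }
  out
}

#' Run the one-step classification--multireconstruction algorithm
#'
#' Implements the full iterative loop: (1) patterns and initial templates
#' are downsampled by two; (2) each template is sliced at every orientation
#' of a quasi-uniform grid; (3) each pattern is correlated with every slice
#' (polar FFT over the in-plane angle); (4) patterns are classified by the
#' thresholded CC margin; (5) each class's patterns are merged into an
#' updated 3D intensity at their best orientations; (6) repeat until
#' class/orientation assignments stabilize or the iteration cap is reached.
#' All patterns are re-classified at every iteration.
#'
#' @param patterns A full-resolution [pattern_set()] with geometry.
#' @param templates List of initial [intensity_volume()] templates on the
#'   full-resolution grid (`volume_grid(geometry, oversample)`), e.g. from
#'   [build_template()] of predicted structures.  May be `NULL` when
#'   `initial_assignment` is given (warm start: templates are then merged
#'   from that assignment first).
#' @param config A [run_config()]; uses `threshold`, `max_iter`,
#'   `stop_tol`, `delta_deg`, `n_theta`, `oversample`.
#' @param initial_assignment Optional [assign_classes()]-shaped warm start.
#' @param downsample Apply the 2x preprocessing (default TRUE).
#' @param verbose Print one line per iteration.
#' @return Object of class `"spi_run"`: final `assignment`, final
#'   `volumes` (downsampled grid), `history` data frame (per iteration:
#'   class counts, unclassified count, changed fraction, mean winning CC),
#'   `assignments` (list, one per iteration), the downsampled `patterns`,
#'   grid parameters, and `iterations`.
#' @export
classify_reconstruct <- function(patterns, templates, config,
                                 initial_assignment = NULL,
                                 downsample = TRUE, verbose = FALSE) {
  stopifnot(inherits(patterns, "pattern_set"))
  ps <- if (downsample) downsample_pattern(patterns) else patterns
  geom <- ps$geometry
  vg <- volume_grid(geom, config$oversample)
  if (!is.null(templates)) {
    vols <- lapply(templates, function(v) {
      if (downsample) downsample_volume(v) else v
    })
    # reconstruct on the template grid; it must cover the detector corner
    vg <- list(n = dim(vols[[1]]$data)[1], dq = vols[[1]]$dq)
    q_corner <- .q_at_radius(sqrt(sum((geom$shape / 2)^2)), geom)$q
    if ((vg$n / 2 - 1) * vg$dq < q_corner) {
      stop("template grid does not reach the detector-corner |q|; ",
           "build templates with volume_grid()")
    }
  } else {
    if (is.null(initial_assignment)) {
      stop("either templates or an initial assignment is required")
    }
    vols <- merge_patterns(ps, initial_assignment, n = vg$n, dq = vg$dq)
    if (any(vapply(vols, is.null, TRUE))) stop("warm start left a class empty")
  }
  nm <- length(vols)
  np <- n_patterns(ps)
  grid <- sample_grid(config$delta_deg * pi / 180)
  history <- NULL
  assignments <- list()
  prev <- NULL
  for (it in seq_len(config$max_iter)) {
    tab <- compute_cc_table(ps, vols, grid, n_theta = config$n_theta)
    asg <- assign_classes(tab, config$threshold)
    n_uncl <- sum(is.na(asg$class))
    if (n_uncl == np) {
      stop("all patterns unclassified at iteration ", it,
           ": threshold too strict or templates too poor")
    }
    changed <- if (is.null(prev)) 1 else {
      mean(!(identical_class <- (is.na(prev$class) & is.na(asg$class)) |
               (!is.na(prev$class) & !is.na(asg$class) &
                  prev$class == asg$class &
                  prev$alpha == asg$alpha & prev$beta == asg$beta &
                  prev$gamma == asg$gamma)), na.rm = TRUE)
    }
    counts <- vapply(seq_len(nm), function(k)
      sum(!is.na(asg$class) & asg$class == k), 0L)
    history <- rbind(history, data.frame(
      iteration = it, t(stats::setNames(counts, paste0("class", seq_len(nm)))),
      unclassified = n_uncl, changed = changed,
      mean_cc = mean(asg$cc, na.rm = TRUE)))
    assignments[[it]] <- asg
    if (verbose) {
      message(sprintf(
        "iter %2d: classified %s | unclassified %d (%.1f%%) | changed %.3f",
        it, paste(counts, collapse = "/"), n_uncl, 100 * n_uncl / np, changed))
    }
    merged <- merge_patterns(ps, asg, n_classes = nm, n = vg$n, dq = vg$dq)
    for (k in seq_len(nm)) if (!is.null(merged[[k]])) vols[[k]] <- merged[[k]]
    prev <- asg
    if (changed < config$stop_tol) break
  }
  structure(list(assignment = prev, volumes = vols, history = history,
                 assignments = assignments, patterns = ps,
                 grid = grid, n = vg$n, dq = vg$dq,
                 config = config, iterations = nrow(history)),
            class = "spi_run")
}

#' @export
print.spi_run <- function(x, ...) {
  cat(sprintf("spi_run: %d patterns, %d classes, %d iteration(s)\n",
              n_patterns(x$patterns), length(x$volumes), x$iterations))
  print(utils::tail(x$history, 3), row.names = FALSE)
  invisible(x)
}

#' @export
summary.spi_run <- function(object, ...) {
  h <- object$history
  cat("iteration history:\n")
  print(h, row.names = FALSE)
  a <- object$assignment
  cat(sprintf("final: %d/%d classified (%.1f%%), mean winning CC %.3f\n",
              sum(!is.na(a$class)), nrow(a),
              100 * mean(!is.na(a$class)), mean(a$cc, na.rm = TRUE)))
  invisible(h)
}

#' @export
plot.spi_run <- function(x, ...) {
  h <- x$history
  nm <- length(x$volumes)
  counts <- t(as.matrix(h[, paste0("class", seq_len(nm))]))
  counts <- rbind(counts, unclassified = h$unclassified)
  graphics::barplot(counts, names.arg = h$iteration,
                    col = c(grDevices::hcl.colors(nm, "Dark 3"), "grey70"),
                    xlab = "iteration", ylab = "patterns",
                    legend.text = rownames(counts), ...)
  invisible(x)
}
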