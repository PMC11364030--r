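#' Correlation table between patterns and templates
#'
#' For every (pattern, template) pair, the maximum Pearson correlation over
#' all grid directions and all in-plane rotations, and the orientation that
#' attains it.  This is the inner loop of the classification algorithm; the
#' in-plane angle is resolved by FFT cross-correlation in polar coordinates
#' (see [ccmax_over_gamma()]) and the computation is batched over patterns,
#' so one slice is correlated with every pattern at once.
#'
#' Ties in the argmax resolve to the lowest shift index, then the lowest
#' grid-direction index (deterministic).
#'
#' @param patterns A [pattern_set()] carrying its [detector_geometry()]
#'   (already downsampled if the pipeline downsamples).
#' @param volumes List of [intensity_volume()] templates on a grid matching
#'   that geometry.
#' @param grid An [sample_grid()] orientation grid.
#' @param n_theta Angular bins for the polar transform.
#' @param pspec Optional [polar_spec()] override.
#' @param min_valid_frac Minimum fraction of polar bins that must be
#'   jointly valid for a correlation to enter the maximization (default
#'   0.5).  A Pearson coefficient computed over a small surviving subset
#'   of bins, maximized over tens of thousands of candidate orientations,
#'   is upward-biased by selection; slices through sparsely covered
#'   regions of a reconstructed template would otherwise win spuriously.
#' @return Object of class `"cc_table"`: matrices `cc`, `alpha`, `beta`,
#'   `gamma` of dimension `n_patterns x n_templates` (`cc` is `NA` where no
#'   valid correlation existed), plus the grid and polar lattice used.
#' @export
compute_cc_table <- function(patterns, volumes, grid, n_theta = 64,
                             pspec = NULL, min_valid_frac = 0.5) {
  stopifnot(inherits(patterns, "pattern_set"))
  geom <- patterns$geometry
  if (is.null(geom)) stop("pattern set carries no detector geometry")
  if (is.null(pspec)) pspec <- polar_spec(geom, n_theta = n_theta)
  nt <- pspec$n_theta; nr <- pspec$n_r
  np <- n_patterns(patterns)
  nm <- length(volumes)

  # polar transform of every pattern; the validity lattice is shared
  # because the detector mask is shared across the set
  pol0 <- to_polar(patterns$patterns[, , 1], patterns$mask, pspec)
  mA <- pol0$valid * 1
  radA <- all(pol0$valid == matrix(pol0$valid[1, ], nt, nr, byrow = TRUE))
  fM <- stats::mvfft(mA)
  # conjugated, (r fastest, omega slowest) x pattern matrices
  CX <- matrix(0i, nr * nt, np)
  CX2 <- matrix(0i, nr * nt, np)
  for (i in seq_len(np)) {
    p <- if (i == 1) pol0 else to_polar(patterns$patterns[, , i],
                                        patterns$mask, pspec)
    d <- p$data * mA
    CX[, i] <- as.vector(t(stats::mvfft(d)))
    CX2[, i] <- as.vector(t(stats::mvfft(d * d)))
  }
  CX <- Conj(CX); CX2 <- Conj(CX2)
  cM <- Conj(as.vector(t(fM)))
  dc <- seq_len(nr)                       # rows holding the omega = 0 block
  min_valid <- max(2, ceiling(min_valid_frac * nt * nr))

  fold <- function(M) {                   # sum over r -> (nt x ncol)
    dim(M) <- c(nr, nt * ncol(M))
    out <- colSums(M)
    dim(out) <- c(nt, length(out) / nt)
    out
  }
  ifft_cols <- function(M) Re(stats::mvfft(M, inverse = TRUE)) / nt

  cc_best <- matrix(-Inf, np, nm)
  al_best <- matrix(NA_real_, np, nm)
  be_best <- matrix(NA_real_, np, nm)
  ga_best <- matrix(NA_real_, np, nm)
  dirs <- grid$dirs

  for (m in seq_len(nm)) {
    vol <- volumes[[m]]
    best_cc <- rep(-1.5, np); best_dir <- rep(1L, np); best_k <- rep(1L, np)
    for (g in seq_len(nrow(dirs))) {
      sp <- .slice_polar(vol, dirs[g, 1], dirs[g, 2], pspec)
      mB <- sp$valid * 1
      s <- sp$data * mB
      fBM <- stats::mvfft(mB); fBX <- stats::mvfft(s)
      fBX2 <- stats::mvfft(s * s)
      bM <- as.vector(t(fBM)); bX <- as.vector(t(fBX))
      bX2 <- as.vector(t(fBX2))
      radB <- all(sp$valid == matrix(sp$valid[1, ], nt, nr, byrow = TRUE))
      if (radA && radB) {
        N <- Re(sum(cM[dc] * bM[dc])) / nt
        if (N < min_valid) next
        SP <- Re(colSums(CX[dc, , drop = FALSE] * bM[dc])) / nt
        SPP <- Re(colSums(CX2[dc, , drop = FALSE] * bM[dc])) / nt
        SS <- Re(sum(cM[dc] * bX[dc])) / nt
        SSS <- Re(sum(cM[dc] * bX2[dc])) / nt
        SPS <- ifft_cols(fold(CX * bX))           # nt x np
        vp <- N * SPP - SP^2                      # per pattern
        vs <- N * SSS - SS^2                      # scalar
        ccm <- N * SPS - matrix(SP * SS, nt, np, byrow = TRUE)
        den <- sqrt(pmax(vp * vs, 0))
        ok <- vp > 1e-9 * N * SPP & vs > 1e-9 * N * SSS & den > 0
        ccm <- sweep(ccm, 2, ifelse(ok, den, Inf), "/")
        ccm[, !ok] <- -1.5
      } else {
        NN <- ifft_cols(as.matrix(fold(as.matrix(cM * bM))))  # nt x 1
        SPm <- ifft_cols(fold(CX * bM))
        SPPm <- ifft_cols(fold(CX2 * bM))
        SSv <- ifft_cols(as.matrix(fold(as.matrix(cM * bX))))
        SSSv <- ifft_cols(as.matrix(fold(as.matrix(cM * bX2))))
        SPS <- ifft_cols(fold(CX * bX))
        Nv <- as.vector(NN); SSvv <- as.vector(SSv); SSSvv <- as.vector(SSSv)
        vp <- Nv * SPPm - SPm^2                   # nt x np
        vs <- Nv * SSSvv - SSvv^2                 # nt
        num <- Nv * SPS - SPm * SSvv
        den <- sqrt(pmax(vp * vs, 0))
        bad <- !(Nv >= min_valid & vp > 1e-9 * Nv * SPPm &
                   vs > 1e-9 * Nv * SSSvv & den > 0)
        ccm <- num / den
        ccm[bad] <- -1.5
      }
      ccm[!is.finite(ccm)] <- -1.5
      ccm <- pmin(pmax(ccm, -1.5), 1)   # ccm first: pmin/pmax keep its dim
      # per-pattern best shift for this direction, then running best
      tcc <- t(ccm)                               # np x nt
      k <- max.col(tcc, ties.method = "first")
      v <- tcc[cbind(seq_len(np), k)]
      upd <- v > best_cc
      best_cc[upd] <- v[upd]; best_dir[upd] <- g; best_k[upd] <- k[upd]
    }
    seen <- best_cc > -1.5
    cc_best[, m] <- ifelse(seen, best_cc, NA_real_)
    al_best[, m] <- dirs[best_dir, 1]
    be_best[, m] <- dirs[best_dir, 2]
    ga_best[, m] <- 2 * pi * (best_k - 1) / nt
  }
  structure(list(cc = cc_best, alpha = al_best, beta = be_best,
                 gamma = ga_best, grid = grid, pspec = pspec,
                 n_theta = nt),
            class = "cc_table")
}

#' @export
print.cc_table <- function(x, ...) {
  cat(sprintf("CC table: %d patterns x %d templates, grid of %d directions x %d shifts\n",
              nrow(x$cc), ncol(x$cc), nrow(x$grid$dirs), x$n_theta))
  cat(sprintf("  mean CC_max per template: %s\n",
              paste(sprintf("%.3f", colMeans(x$cc, na.rm = TRUE)),
                    collapse = " ")))
  invisible(x)
}

#' Best-matching orientation for one table entry
#' @param table A [compute_cc_table()] result.
#' @param i Pattern index.
#' @param m Template index.
#' @return An [orientation()].
#' @export
table_orientation <- function(table, i, m) {
  orientation(table$alpha[i, m], table$beta[i, m], table$gamma[i, m])
}
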