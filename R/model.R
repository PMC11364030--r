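#' Atomic models
#'
#' An atomic model is a data frame-backed object with one row per atom:
#' element symbol, orthogonal coordinates in Angstrom, occupancy, B-factor
#' and chain/residue labels.  It is the real-space input to the forward
#' model: each atom contributes an isotropic Gaussian of Z electrons to the
#' electron density.
#'
#' @name atomic_model
NULL

# electron counts for the elements that occur in protein structures
# (plus a few common hetero elements); pseudo-atoms in toy fixtures use "C"
.electron_table <- c(
  H = 1, C = 6, N = 7, O = 8, F = 9, NA. = 11, MG = 12, P = 15, S = 16,
  CL = 17, K = 19, CA = 20, MN = 25, FE = 26, CO = 27, NI = 28, CU = 29,
  ZN = 30, SE = 34, BR = 35, I = 53)

#' Electron count for element symbols
#' @param element Character vector of element symbols (case-insensitive).
#' @return Integer vector of electron counts.
#' @export
electron_count <- function(element) {
  key <- toupper(trimws(element))
  key[key == "NA"] <- "NA."
  z <- .electron_table[key]
  if (anyNA(z)) {
    stop("unknown element symbol(s): ",
         paste(unique(element[is.na(z)]), collapse = ", "))
  }
  unname(z)
}

#' Construct an atomic model
#'
#' @param element Character vector of element symbols.
#' @param xyz Numeric matrix (n x 3) of coordinates in Angstrom.
#' @param occupancy Occupancies (default 1).
#' @param b B-factors in A^2 (kept for provenance; not used by the forward
#'   model, which has a single Gaussian width per run).
#' @param chain,resno Chain identifiers and residue numbers.
#' @return Object of class `"atomic_model"` (a data frame).
#' @export
atomic_model <- function(element, xyz, occupancy = 1, b = 0,
                         chain = "A", resno = seq_along(element)) {
  xyz <- as.matrix(xyz)
  stopifnot(ncol(xyz) == 3, nrow(xyz) == length(element), nrow(xyz) >= 1,
            all(is.finite(xyz)))
  electron_count(element)  # validate symbols early
  df <- data.frame(element = as.character(element),
                   x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                   occupancy = rep_len(occupancy, length(element)),
                   b = rep_len(b, length(element)),
                   chain = rep_len(as.character(chain), length(element)),
                   resno = rep_len(as.integer(resno), length(element)),
                   stringsAsFactors = FALSE)
  class(df) <- c("atomic_model", "data.frame")
  df
}

#' @export
print.atomic_model <- function(x, ...) {
  cat(sprintf("atomic model: %d atoms, %d chain(s), %.0f electrons\n",
              nrow(x), length(unique(x$chain)), total_electrons(x)))
  cat(sprintf("  extent: %.1f x %.1f x %.1f A, Rg = %.2f A\n",
              diff(range(x$x)), diff(range(x$y)), diff(range(x$z)),
              radius_of_gyration(x)))
  invisible(x)
}

#' Model coordinates as an n x 3 matrix
#' @param model An [atomic_model()].
#' @return Numeric matrix.
#' @export
model_xyz <- function(model) cbind(model$x, model$y, model$z)

#' Occupancy-weighted total electron count
#' @param model An [atomic_model()].
#' @return Scalar.
#' @export
total_electrons <- function(model) {
  sum(electron_count(model$element) * model$occupancy)
}

#' Electron-weighted radius of gyration
#' @param model An [atomic_model()].
#' @return Rg in Angstrom.
#' @export
radius_of_gyration <- function(model) {
  w <- electron_count(model$element) * model$occupancy
  xyz <- model_xyz(model)
  ctr <- colSums(xyz * w) / sum(w)
  sqrt(sum(w * rowSums(sweep(xyz, 2, ctr)^2)) / sum(w))
}

#' Center a model on its electron centroid
#' @param model An [atomic_model()].
#' @return The translated model.
#' @export
center_model <- function(model) {
  w <- electron_count(model$element) * model$occupancy
  xyz <- model_xyz(model)
  ctr <- colSums(xyz * w) / sum(w)
  model$x <- model$x - ctr[1]
  model$y <- model$y - ctr[2]
  model$z <- model$z - ctr[3]
  model
}

#' Apply a rigid transform to a model
#' @param model An [atomic_model()].
#' @param R 3x3 rotation matrix (applied first).
#' @param t Translation vector in Angstrom (applied second).
#' @return The transformed model.
#' @export
transform_model <- function(model, R = diag(3), t = c(0, 0, 0)) {
  xyz <- model_xyz(model) %*% t(R)
  model$x <- xyz[, 1] + t[1]
  model$y <- xyz[, 2] + t[2]
  model$z <- xyz[, 3] + t[3]
  model
}

#' Coordinate RMSD between two models with identical atom order
#' @param a,b [atomic_model()] objects of equal size.
#' @return RMSD in Angstrom.
#' @export
model_rmsd <- function(a, b) {
  stopifnot(nrow(a) == nrow(b))
  sqrt(mean(rowSums((model_xyz(a) - model_xyz(b))^2)))
}

#' Read an atomic model from a PDB or mmCIF file
#'
#' Parsing is done with the bio3d package; the result is converted to an
#' [atomic_model()].  Element symbols are taken from the element column when
#' present, otherwise inferred from the atom name.  Hydrogens are kept if
#' present.
#'
#' @param path Path to a `.pdb`/`.ent` or `.cif` file.
#' @param chain Optional chain selector (character vector); only atoms on
#'   those chains are returned.
#' @return An [atomic_model()].
#' @export
read_model <- function(path, chain = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  pdb <- if (ext == "cif") bio3d::read.cif(path) else bio3d::read.pdb(path)
  at <- pdb$atom
  if (!is.null(chain)) {
    at <- at[at$chain %in% chain, , drop = FALSE]
    if (nrow(at) == 0) stop("chain selector matched zero atoms: ",
                            paste(chain, collapse = ","))
  }
  elem <- at$elesy
  if (is.null(elem) || all(is.na(elem)) || all(trimws(elem) == "")) {
    elem <- substr(trimws(at$elety), 1, 1)
  } else {
    bad <- is.na(elem) | trimws(elem) == ""
    elem[bad] <- substr(trimws(at$elety[bad]), 1, 1)
  }
  occ <- at$o; occ[is.na(occ)] <- 1
  b <- at$b; b[is.na(b)] <- 0
  atomic_model(element = trimws(elem),
               xyz = cbind(at$x, at$y, at$z),
               occupancy = occ, b = b,
               chain = at$chain, resno = at$resno)
}

#' Write an atomic model to a PDB file
#'
#' @param model An [atomic_model()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  xyz <- as.vector(t(model_xyz(model)))
  bio3d::write.pdb(file = path, xyz = xyz,
                   type = rep("ATOM", nrow(model)),
                   resno = model$resno, chain = model$chain,
                   resid = rep("GLY", nrow(model)),
                   elety = model$element, elesy = model$element,
                   o = model$occupancy, b = model$b)
  invisible(path)
}

#' Number of distinct residues in a model
#' @param model An [atomic_model()].
#' @return Integer count of unique (chain, residue-number) pairs.
#' @export
residue_count <- function(model) {
  nrow(unique(data.frame(model$chain, model$resno)))
}
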