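# Excitonic site Hamiltonians of FMO monomers: construction, validation,
# file parsing and eigen-systems.

.packaged_species <- c("P_aestuarii", "C_tepidum")

.species_file <- function(species) {
  fn <- paste0("H_", species, "_synthetic.csv")
  path <- system.file("extdata", fn, package = "fmodyn")
  if (identical(path, "")) stop("packaged Hamiltonian file not found: ", fn)
  path
}

#' Construct an excitonic site Hamiltonian
#'
#' Wraps a real symmetric matrix of site energies (diagonal, cm\eqn{^{-1}})
#' and excitonic couplings (off-diagonal, cm\eqn{^{-1}}) in the
#' single-excitation site basis, with validation.
#'
#' @param matrix Real square symmetric matrix in cm\eqn{^{-1}}.
#' @param species Label for the matrix (a species name for the packaged
#'   monomer models, anything descriptive otherwise).
#' @return An object of class `exciton_hamiltonian` with elements `matrix`,
#'   `species` and `site_count`.
#' @examples
#' H <- exciton_hamiltonian(diag(c(100, 200)), species = "toy_dimer")
#' @export
exciton_hamiltonian <- function(matrix, species = "custom") {
  m <- as.matrix(matrix)
  if (!is.numeric(m) || nrow(m) != ncol(m)) {
    stop("Hamiltonian must be a numeric square matrix")
  }
  if (any(!is.finite(m))) stop("Hamiltonian contains non-finite entries")
  scale <- max(1, max(abs(m)))
  asym <- abs(m - t(m))
  if (max(asym) > 1e-12 * scale) {
    ij <- which(asym == max(asym), arr.ind = TRUE)[1, ]
    stop(sprintf(
      "Hamiltonian is not symmetric: entry (%d,%d)=%g differs from (%d,%d)=%g",
      ij[1], ij[2], m[ij[1], ij[2]], ij[2], ij[1], m[ij[2], ij[1]]))
  }
  m <- (m + t(m)) / 2
  dimnames(m) <- NULL
  structure(list(matrix = m, species = species, site_count = nrow(m)),
            class = "exciton_hamiltonian")
}

#' @export
print.exciton_hamiltonian <- function(x, ...) {
  cat(sprintf("<exciton_hamiltonian> %s: %d sites, energies %.0f..%.0f cm^-1\n",
              x$species, x$site_count,
              min(diag(x$matrix)), max(diag(x$matrix))))
  invisible(x)
}

#' Load a site Hamiltonian by species label or from a matrix file
#'
#' For the packaged monomer models pass a species label
#' (`"P_aestuarii"` or `"C_tepidum"`); otherwise pass a path to a CSV matrix
#' file (square, comma-separated, `#`-prefixed header lines allowed).
#' Packaged matrices are additionally checked to be 8x8 with site energies
#' in the physically sensible window 11,000--13,000 cm\eqn{^{-1}}.
#'
#' The packaged matrices are synthetic stand-ins compiled from published
#' eight-site FMO excitonic models (see the file headers and the package
#' vignette for provenance and caveats).
#'
#' @param source Species label (one of `"P_aestuarii"`, `"C_tepidum"`) or a
#'   file path.
#' @return An [exciton_hamiltonian()] object.
#' @examples
#' H <- load_hamiltonian("P_aestuarii")
#' H$site_count
#' @export
load_hamiltonian <- function(source) {
  stopifnot(is.character(source), length(source) == 1)
  packaged <- source %in% .packaged_species
  path <- if (packaged) .species_file(source) else source
  if (!file.exists(path)) {
    stop("no packaged species and no file found for '", source,
         "' (packaged: ", paste(.packaged_species, collapse = ", "), ")")
  }
  m <- as.matrix(utils::read.table(path, sep = ",", comment.char = "#",
                                   header = FALSE))
  if (nrow(m) != ncol(m)) {
    stop(sprintf("matrix file '%s' is %dx%d, expected square",
                 path, nrow(m), ncol(m)))
  }
  H <- exciton_hamiltonian(m, species = if (packaged) source else
                                          basename(path))
  if (packaged) {
    if (H$site_count != 8) stop("packaged Hamiltonian must be 8x8")
    d <- diag(H$matrix)
    if (any(d < 11000 | d > 13000)) {
      k <- which(d < 11000 | d > 13000)[1]
      stop(sprintf("site energy %g at site %d outside [11000, 13000] cm^-1",
                   d[k], k))
    }
  }
  H
}

#' Eigen-system of a site Hamiltonian
#'
#' Diagonalizes the site Hamiltonian and returns the excitonic basis: real
#' eigenvalues in ascending order and orthonormal eigenvectors as columns.
#' The sign of each eigenvector is fixed by making its entry of largest
#' magnitude positive.
#'
#' @param H An [exciton_hamiltonian()] or a plain symmetric matrix.
#' @return An object of class `eigen_system` with `energies` (ascending,
#'   cm\eqn{^{-1}}) and `vectors` (orthonormal columns; column k is the
#'   excitonic state of energy `energies[k]`).
#' @examples
#' es <- eigensystem(load_hamiltonian("P_aestuarii"))
#' es$energies
#' @export
eigensystem <- function(H) {
  m <- if (inherits(H, "exciton_hamiltonian")) H$matrix else
    exciton_hamiltonian(H)$matrix
  e <- eigen(m, symmetric = TRUE)
  idx <- order(e$values)
  vals <- e$values[idx]
  vecs <- e$vectors[, idx, drop = FALSE]
  for (k in seq_len(ncol(vecs))) {
    j <- which.max(abs(vecs[, k]))
    if (vecs[j, k] < 0) vecs[, k] <- -vecs[, k]
  }
  structure(list(energies = vals, vectors = vecs), class = "eigen_system")
}

#' @export
print.eigen_system <- function(x, ...) {
  cat("<eigen_system>", length(x$energies), "levels, energies:",
      paste(sprintf("%.1f", x$energies), collapse = " "), "\n")
  invisible(x)
}
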