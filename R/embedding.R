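# Mapping between the n-dimensional single-excitation manifold and the
# 2^n multi-qubit space, partial transposes and partial traces.
#
# Bit convention: site k corresponds to the qubit with bit weight 2^(k-1)
# (little-endian), so the computational-basis index of the state with only
# site k excited is 1 + 2^(k-1); index 1 is the all-ground state.

#' Embed a single-excitation state into the multi-qubit space
#'
#' Maps an `n x n` site-basis density matrix (trace \eqn{t \le 1}) into the
#' \eqn{2^n}-dimensional qubit space. Single-excitation populations and
#' coherences are carried over unchanged; the all-ground population absorbs
#' the trace deficit \eqn{1 - t} (physically: excitation already delivered
#' to the reaction centre), so the embedded state has unit trace.
#'
#' @param rho Site-basis density matrix (real or complex).
#' @return A \eqn{2^n \times 2^n} complex density matrix.
#' @export
embed_single_excitation <- function(rho) {
  rho <- as.matrix(rho)
  n <- nrow(rho)
  stopifnot(ncol(rho) == n, n <= 12)
  dimn <- 2^n
  out <- matrix(0 + 0i, dimn, dimn)
  idx <- 1 + 2^(seq_len(n) - 1)
  out[idx, idx] <- rho
  deficit <- 1 - Re(sum(diag(rho)))
  if (deficit < -1e-6) stop("trace of rho exceeds 1 beyond tolerance")
  out[1, 1] <- max(deficit, 0)
  out
}

#' Embed a single-excitation amplitude vector as a multi-qubit pure state
#'
#' @param a Length-`n` amplitude vector over sites (normalized).
#' @return A \eqn{2^n} complex state vector with amplitude `a[k]` on the
#'   basis state with only qubit `k` excited.
#' @export
embed_state_vector <- function(a) {
  a <- as.complex(a)
  n <- length(a)
  stopifnot(n <= 12)
  if (abs(sum(Mod(a)^2) - 1) > 1e-8) stop("amplitudes must be normalized")
  v <- rep(0 + 0i, 2^n)
  v[1 + 2^(seq_len(n) - 1)] <- a
  v
}

#' Partial transpose of a multi-qubit density matrix
#'
#' Transposes the indices of the selected qubits between row and column.
#'
#' @param rho \eqn{2^m \times 2^m} density matrix.
#' @param qubits Qubits (1-based, little-endian bit order) to transpose.
#' @param n_qubits Total number of qubits m.
#' @return The partially transposed matrix.
#' @export
partial_transpose <- function(rho, qubits, n_qubits) {
  rho <- as.matrix(rho)
  d <- 2^n_qubits
  stopifnot(nrow(rho) == d, ncol(rho) == d)
  qubits <- as.integer(qubits)
  stopifnot(all(qubits >= 1), all(qubits <= n_qubits))
  mask <- sum(2^(qubits - 1))
  i <- 0:(d - 1)
  # swap the masked bits of row and column indices
  row <- rep(i, times = d); col <- rep(i, each = d)
  nr <- bitwOr(bitwAnd(row, bitwNot(mask)), bitwAnd(col, mask))
  nc <- bitwOr(bitwAnd(col, bitwNot(mask)), bitwAnd(row, mask))
  out <- matrix(0 + 0i, d, d)
  out[cbind(nr + 1, nc + 1)] <- rho[cbind(row + 1, col + 1)]
  out
}

#' Reduced multi-qubit state of a subset of sites
#'
#' Traces the embedded single-excitation state over all sites not in
#' `sites`, returning the reduced density matrix of the selected qubits in
#' the given site order (the first listed site is qubit 1 of the output,
#' little-endian). Populations of excited sites outside the subset, and any
#' trace deficit, accumulate in the all-ground population of the output;
#' coherences among the selected sites are retained and all other
#' coherences vanish in the partial trace.
#'
#' @param rho Site-basis density matrix (trace \eqn{\le 1}).
#' @param sites Distinct site indices (e.g. a triple like `c(3, 6, 7)`).
#' @return A \eqn{2^m \times 2^m} Hermitian unit-trace density matrix,
#'   m = `length(sites)`.
#' @examples
#' rho <- initial_state_localized(3)
#' reduce_to_sites(rho, c(3, 4, 8))  # |100><100| on qubit order (3,4,8)
#' @export
reduce_to_sites <- function(rho, sites) {
  rho <- as.matrix(rho)
  n <- nrow(rho)
  sites <- as.integer(sites)
  m <- length(sites)
  if (anyDuplicated(sites) || any(sites < 1) || any(sites > n)) {
    stop("sites must be distinct indices in 1..", n)
  }
  tr <- Re(sum(diag(rho)))
  if (tr > 1 + 1e-8) stop("trace of rho exceeds 1")
  ground <- 1 - sum(Re(diag(rho))[sites])
  if (ground < -1e-6) stop("negative ground population beyond tolerance")
  d <- 2^m
  out <- matrix(0 + 0i, d, d)
  idx <- 1 + 2^(seq_len(m) - 1)   # position of |1_q> for qubit q
  out[idx, idx] <- rho[sites, sites]
  out[1, 1] <- max(ground, 0)
  (out + Conj(t(out))) / 2
}
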