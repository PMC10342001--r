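# Superoperator-supervector machinery: density matrices are vectorized
# column-major, so A rho B becomes kron(t(B), A) %*% vec(rho).

#' Sandwich superoperator of a pair of matrices
#'
#' Returns the linear map on vectorized density matrices that implements
#' \eqn{\rho \mapsto A\rho B}. With column-major vectorization this is the
#' Kronecker product \eqn{B^T \otimes A}.
#'
#' @param A,B Conformable square matrices (real or complex).
#' @return A dense \eqn{n^2 \times n^2} matrix acting on `as.vector(rho)`.
#' @examples
#' A <- matrix(rnorm(4), 2); B <- matrix(rnorm(4), 2)
#' rho <- matrix(rnorm(4), 2)
#' max(abs(sandwich_superoperator(A, B) %*% as.vector(rho) -
#'         as.vector(A %*% rho %*% B)))
#' @export
sandwich_superoperator <- function(A, B) {
  A <- as.matrix(A); B <- as.matrix(B)
  if (nrow(A) != ncol(A) || nrow(B) != ncol(B) || ncol(A) != nrow(B)) {
    stop("A and B must be square and conformable with rho")
  }
  kronecker(t(B), A)
}

# sparse triplets (i, j, x) of the commutator superoperator [M, .] for a
# real symmetric M: kron(I, M) - kron(M, I)
.comm_triplets <- function(M) {
  n <- nrow(M)
  In <- diag(n)
  K <- kronecker(In, M) - kronecker(M, In)
  w <- which(K != 0, arr.ind = TRUE)
  list(i = w[, 1], j = w[, 2], x = K[w])
}

# diagonal (as a vector over vec indices) of the commutator superoperator
# [P_k, .] for the site projector P_k: entry (i,j) gets delta_ik - delta_jk
.proj_comm_diag <- function(k, n) {
  d <- outer(seq_len(n) == k, rep(TRUE, n)) * 1 -
       outer(rep(TRUE, n), seq_len(n) == k) * 1
  as.vector(d)
}

# diagonal of the anticommutator superoperator {P_k, .}: delta_ik + delta_jk
.proj_anti_diag <- function(k, n) {
  d <- outer(seq_len(n) == k, rep(TRUE, n)) * 1 +
       outer(rep(TRUE, n), seq_len(n) == k) * 1
  as.vector(d)
}
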