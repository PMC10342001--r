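# Lexicographically ordered site permutations with factorial-number-system
# ranking, and the permutation action on density matrices.

#' Enumerate all site permutations in lexicographic order
#'
#' Lists the \eqn{n!} permutations of `1..n` ordered place by place
#' (lexicographically): the first is the identity `(1, 2, ..., n)`, the
#' last is the reversal `(n, n-1, ..., 1)`.
#'
#' @param n Number of sites (default 8; `8! = 40320`).
#' @return An object of class `permutation_set` with `perms`
#'   (\eqn{n! \times n} integer matrix, one permutation per row) and `n`.
#' @examples
#' enumerate_permutations(3)$perms
#' @export
enumerate_permutations <- function(n = 8) {
  n <- as.integer(n)
  stopifnot(n >= 1, n <= 10)
  total <- factorial(n)
  perms <- matrix(0L, total, n)
  for (r in seq_len(total)) perms[r, ] <- perm_unrank(r, n)
  structure(list(perms = perms, n = n), class = "permutation_set")
}

#' @export
print.permutation_set <- function(x, ...) {
  cat(sprintf("<permutation_set> %d! = %d permutations of 1..%d\n",
              x$n, nrow(x$perms), x$n))
  invisible(x)
}

#' Unrank a permutation (lexicographic order, 1-based)
#'
#' Constant-time unranking through the factorial number system: ordinal 1
#' maps to the identity, ordinal \eqn{n!} to the reversal.
#'
#' @param r Ordinal in `1..factorial(n)`.
#' @param n Number of elements.
#' @return Integer permutation vector of length `n`.
#' @export
perm_unrank <- function(r, n) {
  r <- as.numeric(r) - 1
  stopifnot(r >= 0, r < factorial(n))
  avail <- seq_len(n)
  out <- integer(n)
  for (i in seq_len(n)) {
    f <- factorial(n - i)
    d <- floor(r / f)
    r <- r - d * f
    out[i] <- avail[d + 1]
    avail <- avail[-(d + 1)]
  }
  out
}

#' Rank of a permutation (lexicographic order, 1-based)
#'
#' Inverse of [perm_unrank()].
#'
#' @param p Integer permutation of `1..n`.
#' @return Ordinal in `1..factorial(length(p))`.
#' @export
perm_rank <- function(p) {
  n <- length(p)
  if (!setequal(p, seq_len(n))) stop("p is not a permutation of 1..", n)
  avail <- seq_len(n)
  r <- 0
  for (i in seq_len(n)) {
    d <- match(p[i], avail) - 1
    r <- r + d * factorial(n - i)
    avail <- avail[avail != p[i]]
  }
  as.integer(r + 1)
}

#' Apply a site permutation to a density matrix
#'
#' Relabels the sites of `rho`: with the default `"forward"` convention the
#' output entry \eqn{(i, j)} equals the input entry
#' \eqn{(\pi(i), \pi(j))}, i.e. the state that site \eqn{\pi(i)} held is
#' moved to site \eqn{i}. The `"transpose"` convention applies the inverse
#' permutation (entry \eqn{(\pi(i), \pi(j))} of the output equals entry
#' \eqn{(i, j)} of the input); the asymptotically dominant permutation of a
#' transfer analysis depends on this choice, which is therefore exposed.
#'
#' @param rho Square density matrix.
#' @param p Integer permutation of the sites.
#' @param convention `"forward"` (default) or `"transpose"`.
#' @return Permuted density matrix.
#' @examples
#' permute_state(initial_state_localized(1, 2), c(2, 1))
#' @export
permute_state <- function(rho, p, convention = c("forward", "transpose")) {
  convention <- match.arg(convention)
  rho <- as.matrix(rho)
  n <- nrow(rho)
  p <- as.integer(p)
  if (!setequal(p, seq_len(n))) {
    stop("p is not a permutation of 1..", n)
  }
  if (convention == "transpose") p <- order(p)
  rho[p, p, drop = FALSE]
}
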