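# Enumeration of the auxiliary-density-operator (ADO) multi-index hierarchy.

.compositions <- function(s, n) {
  # all n-vectors of non-negative integers summing to s, first component
  # descending (so (1,0) precedes (0,1))
  if (n == 1) return(matrix(s, 1, 1))
  out <- vector("list", s + 1)
  for (n1 in s:0) {
    rest <- .compositions(s - n1, n - 1)
    out[[s - n1 + 1]] <- cbind(n1, rest, deparse.level = 0)
  }
  do.call(rbind, out)
}

#' Enumerate the ADO hierarchy index set
#'
#' Lists all multi-indices \eqn{n = (n_1,\dots,n_N)} of non-negative
#' integers with \eqn{\sum_k n_k \le D}, graded by the level
#' \eqn{s = \sum_k n_k} and ordered lexicographically within each level.
#' Ordinal 1 is the zero index, whose ADO is the physical reduced density
#' matrix. The raise/lower maps give, for each index and site, the ordinal
#' of the index with \eqn{n_k} increased/decreased by one (`NA` when the
#' neighbour is absent, i.e. beyond the depth-`D` cut-off or below zero).
#'
#' @param n_sites Number of sites \eqn{N}.
#' @param depth Hierarchy depth \eqn{D \ge 0}.
#' @return An object of class `hierarchy_index_set` with elements
#'   `indices` (M x N integer matrix), `level` (row sums), `raise_map`,
#'   `lower_map` (M x N integer matrices of ordinals or `NA`), `n_sites`,
#'   `depth`.
#' @examples
#' h <- enumerate_hierarchy(2, 1)
#' h$indices
#' @export
enumerate_hierarchy <- function(n_sites, depth) {
  n_sites <- as.integer(n_sites); depth <- as.integer(depth)
  stopifnot(n_sites >= 1, depth >= 0)
  idx <- do.call(rbind, lapply(0:depth, .compositions, n = n_sites))
  storage.mode(idx) <- "integer"
  m <- nrow(idx)
  key <- apply(idx, 1, paste, collapse = ".")
  pos <- stats::setNames(seq_len(m), key)
  lev <- as.integer(rowSums(idx))
  raise <- lower <- matrix(NA_integer_, m, n_sites)
  for (k in seq_len(n_sites)) {
    up <- idx; up[, k] <- up[, k] + 1L
    ok <- rowSums(up) <= depth
    raise[ok, k] <- pos[apply(up[ok, , drop = FALSE], 1, paste,
                              collapse = ".")]
    dn <- idx; dn[, k] <- dn[, k] - 1L
    ok <- idx[, k] > 0L
    lower[ok, k] <- pos[apply(dn[ok, , drop = FALSE], 1, paste,
                              collapse = ".")]
  }
  structure(list(indices = idx, level = lev, raise_map = raise,
                 lower_map = lower, n_sites = n_sites, depth = depth),
            class = "hierarchy_index_set")
}

#' @export
print.hierarchy_index_set <- function(x, ...) {
  cat(sprintf("<hierarchy_index_set> N=%d, D=%d, %d indices\n",
              x$n_sites, x$depth, nrow(x$indices)))
  invisible(x)
}
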