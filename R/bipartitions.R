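# The catalog of site bipartitions A|B used by the bipartition-averaged
# entanglement measures.

#' Enumerate all site bipartitions
#'
#' Lists every bipartition A|B of the sites `1..n` with
#' \eqn{|A| \le \lfloor n/2 \rfloor}, graded by order \eqn{m = |A|} and
#' lexicographic within each order. For the half-split order
#' \eqn{m = n/2} each complementary pair is listed once, keeping the set
#' that contains site 1. For n = 8 the per-order counts are
#' (8, 28, 56, 35), 127 bipartitions in total.
#'
#' @param n Number of sites (even or odd, default 8).
#' @return An object of class `bipartition_catalog`: `groups` is a list
#'   (one per order) of lists of integer vectors A; `counts` the per-order
#'   sizes; `n` the site count.
#' @examples
#' cat8 <- enumerate_bipartitions(8)
#' cat8$counts
#' @export
enumerate_bipartitions <- function(n = 8) {
  n <- as.integer(n)
  stopifnot(n >= 2)
  half <- n %/% 2L
  groups <- vector("list", half)
  for (m in seq_len(half)) {
    sets <- utils::combn(n, m, simplify = FALSE)
    if (2L * m == n) {
      sets <- Filter(function(a) 1L %in% a, sets)
    }
    groups[[m]] <- sets
  }
  structure(list(groups = groups,
                 counts = vapply(groups, length, 0L), n = n),
            class = "bipartition_catalog")
}

#' @export
print.bipartition_catalog <- function(x, ...) {
  cat(sprintf("<bipartition_catalog> n=%d, counts (%s), total %d\n",
              x$n, paste(x$counts, collapse = ", "), sum(x$counts)))
  invisible(x)
}

#' Flatten a bipartition catalog
#'
#' @param catalog A [enumerate_bipartitions()] catalog.
#' @return A list of bipartitions in catalog order, each a list with
#'   components `A` (integer vector), `B` (complement) and `order`.
#' @export
bipartition_list <- function(catalog) {
  stopifnot(inherits(catalog, "bipartition_catalog"))
  out <- list()
  for (m in seq_along(catalog$groups)) {
    for (a in catalog$groups[[m]]) {
      out[[length(out) + 1L]] <-
        list(A = a, B = setdiff(seq_len(catalog$n), a), order = m)
    }
  }
  out
}

.bip_label <- function(A) paste(A, collapse = "")
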