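# Tracking the transference of the entry state through the dynamics by
# maximizing the Uhlmann fidelity over all site permutations.

.sqrt_reference <- function(reference) {
  reference <- as.matrix(reference)
  if (abs(Re(sum(diag(reference))) - 1) > 1e-6) {
    stop("reference state must have unit trace")
  }
  .sqrtm_psd(reference)
}

#' Permutation-maximized fidelity track of a trajectory
#'
#' For each sampled frame \eqn{\rho(t)} and every site permutation
#' \eqn{\pi}, computes the Uhlmann fidelity between the reference state
#' (typically the entry state \eqn{\rho(0)}) and the permuted frame, and
#' records the maximum \eqn{F_\Pi(t)} and its arg-max ordinal. Ties are
#' broken towards the lowest ordinal, so a permutation-invariant frame
#' reports the identity. The fidelity uses the trajectory frames as stored
#' (an overall trace deficit from trapping lowers all fidelities alike).
#'
#' @param traj A `heom_trajectory`.
#' @param reference Unit-trace reference density matrix.
#' @param time_stride Sample every `time_stride`-th stored frame
#'   (default 10, i.e. every 0.01 ps at the default storage stride).
#' @param perms Optional [enumerate_permutations()] set (built on demand).
#' @param convention Permutation action, see [permute_state()].
#' @return An object of class `permutation_track`: data frame `track` with
#'   columns `time`, `best_index` (ordinal), `best_permutation` (digit
#'   string), `best_fidelity`, plus `n_permutations`.
#' @export
fidelity_track <- function(traj, reference, time_stride = 10, perms = NULL,
                           convention = c("forward", "transpose")) {
  stopifnot(inherits(traj, "heom_trajectory"))
  convention <- match.arg(convention)
  n <- dim(traj$rho)[1]
  if (is.null(perms)) perms <- enumerate_permutations(n)
  stopifnot(inherits(perms, "permutation_set"), perms$n == n)
  time_stride <- max(1L, as.integer(time_stride))
  sel <- seq(1, length(traj$times), by = time_stride)
  if (!length(sel)) stop("empty trajectory")
  S <- .sqrt_reference(reference)
  pm <- perms$perms
  if (convention == "transpose") pm <- t(apply(pm, 1, order))
  storage.mode(pm) <- "integer"
  bi <- integer(length(sel)); bf <- numeric(length(sel))
  for (s in seq_along(sel)) {
    fv <- fidelity_sweep_cpp(S, traj$rho[, , sel[s]], pm)
    bi[s] <- which.max(fv)          # first maximum: lowest ordinal on ties
    bf[s] <- fv[bi[s]]
  }
  structure(list(
    track = data.frame(
      time = traj$times[sel], best_index = bi,
      best_permutation = vapply(
        bi, function(r) paste(perms$perms[r, ], collapse = ""), ""),
      best_fidelity = bf),
    n_permutations = nrow(pm)),
    class = "permutation_track")
}

#' @export
print.permutation_track <- function(x, ...) {
  cat(sprintf(
    "<permutation_track> %d frames x %d permutations, F range [%.3f, %.3f]\n",
    nrow(x$track), x$n_permutations,
    min(x$track$best_fidelity), max(x$track$best_fidelity)))
  invisible(x)
}

#' Full permutation-fidelity landscape of a trajectory
#'
#' Dense matrix of the fidelity of every permutation at every sampled
#' frame (the heat-map view of the transfer analysis); row-wise maxima
#' reproduce [fidelity_track()].
#'
#' @inheritParams fidelity_track
#' @param cell_budget Refuse to allocate more than this many cells
#'   (default \eqn{2 \times 10^7}); increase the stride or the budget for
#'   larger exports.
#' @return List with `times` and `fidelities`
#'   (frames x permutations matrix).
#' @export
fidelity_landscape <- function(traj, reference, time_stride = 10,
                               perms = NULL,
                               convention = c("forward", "transpose"),
                               cell_budget = 2e7) {
  stopifnot(inherits(traj, "heom_trajectory"))
  convention <- match.arg(convention)
  n <- dim(traj$rho)[1]
  if (is.null(perms)) perms <- enumerate_permutations(n)
  time_stride <- max(1L, as.integer(time_stride))
  sel <- seq(1, length(traj$times), by = time_stride)
  ncell <- length(sel) * nrow(perms$perms)
  if (ncell > cell_budget) {
    stop(sprintf(
      "landscape would need %g cells (> budget %g); increase time_stride or cell_budget",
      ncell, cell_budget))
  }
  S <- .sqrt_reference(reference)
  pm <- perms$perms
  if (convention == "transpose") pm <- t(apply(pm, 1, order))
  storage.mode(pm) <- "integer"
  out <- matrix(0, length(sel), nrow(pm))
  for (s in seq_along(sel)) {
    out[s, ] <- fidelity_sweep_cpp(S, traj$rho[, , sel[s]], pm)
  }
  list(times = traj$times[sel], fidelities = out)
}
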