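# Bath/trapping parameters and initial states of the excitation dynamics.

#' Bath and trapping parameters of the monomer model
#'
#' Collects the Drude-Lorentz bath parameters and the reaction-centre
#' trapping rate. Scalars are recycled to one value per site. Defaults are
#' the commonly analysed monomer settings: reorganization energy
#' \eqn{\lambda = 35} cm\eqn{^{-1}} (the literature range is 35--65),
#' bath cutoff \eqn{\gamma = 50} cm\eqn{^{-1}}, trapping
#' \eqn{r_{\mathrm{trap}} = 1} ps\eqn{^{-1}} on the reaction-centre-facing
#' sites 3 and 4, and the spectroscopy temperature 77 K.
#'
#' @param lambda Per-site reorganization energies, cm\eqn{^{-1}}
#'   (scalar or length-`n_sites` vector, non-negative).
#' @param gamma Per-site bath cutoff frequencies, cm\eqn{^{-1}} (positive).
#' @param temperature Temperature in kelvin (positive).
#' @param r_trap Trapping rate in ps\eqn{^{-1}} (non-negative).
#' @param trap_sites Sites drained towards the reaction centre.
#' @param n_sites Number of sites.
#' @return An object of class `bath_parameters`.
#' @examples
#' bath_parameters(lambda = 65, temperature = 293)
#' @export
bath_parameters <- function(lambda = 35, gamma = 50, temperature = 77,
                            r_trap = 1, trap_sites = c(3, 4), n_sites = 8) {
  stopifnot(n_sites >= 1)
  lam <- rep_len(as.numeric(lambda), n_sites)
  gam <- rep_len(as.numeric(gamma), n_sites)
  if (any(!is.finite(lam)) || any(lam < 0)) {
    stop("lambda must be finite and non-negative")
  }
  if (any(!is.finite(gam)) || any(gam <= 0)) {
    stop("gamma must be finite and positive")
  }
  if (!is.finite(temperature) || temperature <= 0) {
    stop("temperature must be finite and positive")
  }
  if (!is.finite(r_trap) || r_trap < 0) {
    stop("r_trap must be finite and non-negative")
  }
  trap_sites <- as.integer(trap_sites)
  if (length(trap_sites) &&
      (any(trap_sites < 1) || any(trap_sites > n_sites))) {
    stop("trap_sites must be within 1..n_sites")
  }
  structure(list(lambda = lam, gamma = gam, temperature = temperature,
                 r_trap = r_trap, trap_sites = trap_sites,
                 n_sites = as.integer(n_sites)),
            class = "bath_parameters")
}

#' @export
print.bath_parameters <- function(x, ...) {
  cat(sprintf(
    "<bath_parameters> lambda %s cm^-1, gamma %s cm^-1, T=%g K, r_trap=%g/ps, traps {%s}\n",
    paste(unique(x$lambda), collapse = "/"),
    paste(unique(x$gamma), collapse = "/"),
    x$temperature, x$r_trap, paste(x$trap_sites, collapse = ",")))
  invisible(x)
}

#' Excitation localized on one site
#'
#' Density matrix \eqn{|k\rangle\langle k|} of a single excitation sitting
#' on site `k` of the single-excitation manifold.
#'
#' @param k Site index, 1-based.
#' @param n_sites Number of sites.
#' @return A real `n_sites` x `n_sites` rank-1 projector with unit trace.
#' @examples
#' initial_state_localized(8)
#' @export
initial_state_localized <- function(k, n_sites = 8) {
  k <- as.integer(k)
  if (length(k) != 1 || is.na(k) || k < 1 || k > n_sites) {
    stop("site index k must lie in 1..", n_sites)
  }
  rho <- matrix(0, n_sites, n_sites)
  rho[k, k] <- 1
  rho
}

#' Dephased (FRET-type) entry state of the excitation
#'
#' The excitation entering through site `i` dephased in the excitonic basis:
#' \deqn{\rho = \sum_k |\langle\epsilon_k|i\rangle|^2
#'   |\epsilon_k\rangle\langle\epsilon_k|,}
#' the Foerster-resonance-transfer-motivated initial condition. It is
#' diagonal in the excitonic basis, so it commutes with the Hamiltonian and
#' is stationary under the closed-system dynamics; the bath and trapping
#' move it.
#'
#' @param H An [exciton_hamiltonian()] (or symmetric matrix).
#' @param i Entry site (1-based); site 8 is the physical light-entry site of
#'   the monomer.
#' @return Real symmetric positive semidefinite matrix with unit trace.
#' @examples
#' rho0 <- initial_state_fret(load_hamiltonian("P_aestuarii"), 8)
#' diag(rho0)
#' @export
initial_state_fret <- function(H, i = 8) {
  es <- eigensystem(H)
  n <- length(es$energies)
  i <- as.integer(i)
  if (length(i) != 1 || is.na(i) || i < 1 || i > n) {
    stop("entry site i must lie in 1..", n)
  }
  w <- es$vectors[i, ]^2
  rho <- es$vectors %*% (w * t(es$vectors))
  (rho + t(rho)) / 2
}
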