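# Seed-deterministic generators of FMO-like Hamiltonians, analytic toy
# dynamics and random multi-qubit test states.

#' Random FMO-like exciton Hamiltonian
#'
#' Draws a symmetric site Hamiltonian emulating the statistical shape of
#' published FMO monomer models: near-degenerate site energies around
#' 12,400 cm\eqn{^{-1}} and couplings decaying with site distance,
#' \eqn{J_{ij} \sim N(0, (j_0 e^{-|i-j|/\ell})^2)}.
#'
#' @param n_sites Number of sites (default 8).
#' @param diag_mean,diag_sd Site-energy distribution, cm\eqn{^{-1}}
#'   (defaults 12400 and 100).
#' @param j_scale Coupling scale \eqn{j_0} in cm\eqn{^{-1}} (default 50).
#' @param j_decay Coupling decay length \eqn{\ell} in site units
#'   (default 2).
#' @param seed Integer seed; identical seeds give identical matrices.
#' @return An [exciton_hamiltonian()] with species `"synthetic"`.
#' @export
random_exciton_hamiltonian <- function(n_sites = 8, diag_mean = 12400,
                                       diag_sd = 100, j_scale = 50,
                                       j_decay = 2, seed = 1) {
  stopifnot(n_sites >= 2)
  set.seed(seed)
  m <- matrix(0, n_sites, n_sites)
  diag(m) <- stats::rnorm(n_sites, diag_mean, diag_sd)
  for (i in seq_len(n_sites - 1)) {
    for (j in (i + 1):n_sites) {
      m[i, j] <- m[j, i] <-
        stats::rnorm(1, 0, j_scale * exp(-abs(i - j) / j_decay))
    }
  }
  exciton_hamiltonian(m, species = "synthetic")
}

#' Closed-form dimer populations in the unitary limit
#'
#' Rabi oscillation of a two-site system with site energies `eps1`, `eps2`
#' and coupling `J` (all cm\eqn{^{-1}}), starting from site 1:
#' \deqn{P_2(t) = \frac{J^2}{\delta^2 + J^2}
#'   \sin^2\!\big(\sqrt{\delta^2 + J^2}\; t\big),}
#' with \eqn{\delta = (\epsilon_1 - \epsilon_2)/2} and all energies
#' converted to rad/ps. The analytic oracle for the closed-system limit of
#' the propagator.
#'
#' @param eps1,eps2 Site energies, cm\eqn{^{-1}}.
#' @param J Coupling, cm\eqn{^{-1}}.
#' @param t_grid Times in ps.
#' @return Data frame with `time`, `p1`, `p2` (`p1 + p2 = 1`).
#' @export
dimer_reference_dynamics <- function(eps1, eps2, J, t_grid) {
  d <- wavenumber_to_angular_frequency((eps1 - eps2) / 2)
  Jw <- wavenumber_to_angular_frequency(J)
  Om <- sqrt(d^2 + Jw^2)
  p2 <- if (Om == 0) rep(0, length(t_grid)) else
    (Jw^2 / Om^2) * sin(Om * t_grid)^2
  data.frame(time = t_grid, p1 = 1 - p2, p2 = p2)
}

#' W state of m qubits
#'
#' The uniform single-excitation superposition
#' \eqn{(|10\cdots0\rangle + |010\cdots0\rangle + \cdots)/\sqrt m}.
#'
#' @param m Number of qubits (at least 2).
#' @return Normalized complex state vector of length \eqn{2^m}.
#' @export
w_state <- function(m) {
  stopifnot(m >= 2)
  embed_state_vector(rep(1 / sqrt(m), m))
}

#' Random product state of m qubits
#'
#' @param m Number of qubits.
#' @param seed Optional integer seed.
#' @return List with `vector` (the \eqn{2^m} state vector) and `factors`
#'   (the single-qubit states).
#' @export
random_product_state <- function(m, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  phis <- replicate(m, .random_qubit(), simplify = FALSE)
  list(vector = .product_vector(phis), factors = phis)
}

#' Random fully separable mixture with certificate
#'
#' Convex mixture of random product states; the generating ensemble is
#' returned as a separability certificate, so the state is fully separable
#' by construction (its partial transpose across any bipartition is
#' positive).
#'
#' @param m Number of qubits.
#' @param members Number of product states mixed (at least 1).
#' @param seed Optional integer seed.
#' @return List with `rho` (the \eqn{2^m} density matrix), `weights` and
#'   `members` (the certificate ensemble of state vectors).
#' @export
random_separable_mixture <- function(m, members = 4, seed = NULL) {
  stopifnot(members >= 1)
  if (!is.null(seed)) set.seed(seed)
  vs <- replicate(members, random_product_state(m)$vector,
                  simplify = FALSE)
  w <- stats::rexp(members); w <- w / sum(w)
  list(rho = .sigma_of_ensemble(w, vs), weights = w, members = vs)
}

#' Random density matrix (Ginibre ensemble)
#'
#' @param d Dimension.
#' @param seed Optional integer seed.
#' @return A \eqn{d \times d} positive definite unit-trace complex matrix.
#' @export
random_density <- function(d, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  g <- matrix(complex(real = stats::rnorm(d * d),
                      imaginary = stats::rnorm(d * d)), d, d)
  rho <- g %*% Conj(t(g))
  rho / Re(sum(diag(rho)))
}
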