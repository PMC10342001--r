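# Assembly of the sparse HEOM generator and fixed-step propagation.
#
# Working convention (hbar = 1, energies in rad/ps, time in ps), with
# V_k = |k><k| and n the ADO multi-index:
#   d rho_n/dt = -i [H_S + sum_k lambda_k V_k, rho_n]
#                - (sum_k n_k gamma_k) rho_n
#                - r_trap sum_{j in traps} {V_j, rho_n}
#                + i sum_k [V_k, rho_{n_k^+}]
#                + i sum_k n_k ( 2 lambda_k k_B T [V_k, rho_{n_k^-}]
#                                - i lambda_k gamma_k {V_k, rho_{n_k^-}} )
# Terms that would reach beyond the depth-D cut-off are dropped. This is the
# standard unscaled high-temperature Drude-Lorentz hierarchy (a single
# exponential per site, no Matsubara terms); the anticommutator-to-commutator
# ratio of the down-coupling equals -i*gamma_k/(2 k_B T), i.e. beta hbar
# gamma/2 with beta = 1/(k_B T).

#' Assemble the sparse HEOM generator
#'
#' Builds the linear generator of the hierarchical equations of motion on
#' the stacked, vectorized ADO state. The mean site energy is subtracted
#' from the diagonal of the Hamiltonian before assembly (a pure global
#' phase; populations and all measures are invariant) and recorded in the
#' returned object.
#'
#' @param H An [exciton_hamiltonian()].
#' @param bath A [bath_parameters()] with matching `n_sites`.
#' @param hier A [enumerate_hierarchy()] index set with matching `n_sites`.
#' @return An object of class `heom_generator` with sparse real and
#'   imaginary parts `Gr`, `Gi` (each `M*n^2` square, `Matrix` sparse), the
#'   hierarchy, and a `params` record (including the diagonal `offset`
#'   removed, in cm\eqn{^{-1}}).
#' @examples
#' H <- exciton_hamiltonian(matrix(c(0, 100, 100, 200), 2), "toy")
#' b <- bath_parameters(n_sites = 2, trap_sites = integer(0), r_trap = 0)
#' g <- assemble_heom_generator(H, b, enumerate_hierarchy(2, 2))
#' @export
assemble_heom_generator <- function(H, bath, hier) {
  stopifnot(inherits(H, "exciton_hamiltonian"),
            inherits(bath, "bath_parameters"),
            inherits(hier, "hierarchy_index_set"))
  n <- H$site_count
  if (bath$n_sites != n || hier$n_sites != n) {
    stop("site counts of Hamiltonian (", n, "), bath (", bath$n_sites,
         ") and hierarchy (", hier$n_sites, ") disagree")
  }
  n2 <- n * n
  M <- nrow(hier$indices)
  offset <- mean(diag(H$matrix))
  Hw <- wavenumber_to_angular_frequency(H$matrix - diag(offset, n))
  lam <- wavenumber_to_angular_frequency(bath$lambda)
  gam <- wavenumber_to_angular_frequency(bath$gamma)
  kT <- wavenumber_to_angular_frequency(
    thermal_energy_wavenumber(bath$temperature))

  Hp <- Hw + diag(lam, n)
  commH <- .comm_triplets(Hp)
  cdiag <- lapply(seq_len(n), .proj_comm_diag, n = n)
  adiag <- lapply(seq_len(n), .proj_anti_diag, n = n)
  trap_diag <- rep(0, n2)
  for (j in bath$trap_sites) trap_diag <- trap_diag + adiag[[j]]

  vec_idx <- seq_len(n2)
  ir <- list(); jr <- list(); xr <- list()   # real part triplets
  ii <- list(); ji <- list(); xi <- list()   # imaginary part triplets
  pr <- 0L; pi <- 0L
  addr <- function(i, j, x) {
    pr <<- pr + 1L; ir[[pr]] <<- i; jr[[pr]] <<- j; xr[[pr]] <<- x
  }
  addi <- function(i, j, x) {
    pi <<- pi + 1L; ii[[pi]] <<- i; ji[[pi]] <<- j; xi[[pi]] <<- x
  }
  for (a in seq_len(M)) {
    off_a <- (a - 1L) * n2
    nn <- hier$indices[a, ]
    # coherent commutator (imaginary part -K)
    addi(off_a + commH$i, off_a + commH$j, -commH$x)
    # damping + trapping (real diagonal)
    dr <- rep(-sum(nn * gam), n2) - bath$r_trap * trap_diag
    addr(off_a + vec_idx, off_a + vec_idx, dr)
    for (k in seq_len(n)) {
      up <- hier$raise_map[a, k]
      if (!is.na(up)) {
        off_u <- (up - 1L) * n2
        nz <- which(cdiag[[k]] != 0)
        addi(off_a + nz, off_u + nz, cdiag[[k]][nz])
      }
      if (nn[k] > 0L) {
        dn <- hier$lower_map[a, k]
        off_d <- (dn - 1L) * n2
        nz <- which(cdiag[[k]] != 0)
        addi(off_a + nz, off_d + nz, nn[k] * 2 * lam[k] * kT * cdiag[[k]][nz])
        nz <- which(adiag[[k]] != 0)
        addr(off_a + nz, off_d + nz, nn[k] * lam[k] * gam[k] * adiag[[k]][nz])
      }
    }
  }
  dim_full <- M * n2
  Gr <- Matrix::sparseMatrix(i = unlist(ir), j = unlist(jr), x = unlist(xr),
                             dims = c(dim_full, dim_full))
  Gi <- Matrix::sparseMatrix(i = unlist(ii), j = unlist(ji), x = unlist(xi),
                             dims = c(dim_full, dim_full))
  # ingredients of the structured (dense-block) evaluation of the same
  # generator, used by the fast propagation path
  tv <- rep(0, n); tv[bath$trap_sites] <- bath$r_trap
  structured <- list(
    Hp = Hp, damp = as.vector(hier$indices %*% gam),
    trap = outer(tv, rep(1, n)) + outer(rep(1, n), tv),
    nmat = hier$indices,
    raise0 = ifelse(is.na(hier$raise_map), -1L, hier$raise_map - 1L),
    lower0 = ifelse(is.na(hier$lower_map), -1L, hier$lower_map - 1L),
    cC = 2 * lam * kT, cA = lam * gam)
  structure(list(
    Gr = Gr, Gi = Gi, hier = hier, n_sites = n, structured = structured,
    params = list(species = H$species, offset_cm1 = offset,
                  lambda = bath$lambda, gamma = bath$gamma,
                  temperature = bath$temperature, r_trap = bath$r_trap,
                  trap_sites = bath$trap_sites, depth = hier$depth)),
    class = "heom_generator")
}

#' @export
print.heom_generator <- function(x, ...) {
  cat(sprintf("<heom_generator> N=%d, D=%d, dim %d, nnz %d\n",
              x$n_sites, x$hier$depth, nrow(x$Gr),
              length(x$Gr@x) + length(x$Gi@x)))
  invisible(x)
}

#' Propagate the HEOM
#'
#' Fixed-step classical 4th-order (Runge-Kutta) integration of the HEOM
#' generator from a system density matrix (all auxiliaries start at zero).
#' The physical (ordinal-0) member is stored every `store_every` steps;
#' auxiliaries are discarded.
#'
#' @param gen A [assemble_heom_generator()] object.
#' @param rho0 Initial system density matrix (Hermitian, positive
#'   semidefinite, trace at most 1).
#' @param dt Integration step in ps (default \eqn{10^{-4}}).
#' @param t_end Final time in ps; `t_end = 0` returns the single initial
#'   frame.
#' @param store_every Store one frame every this many steps (default 10,
#'   i.e. a stored stride of \eqn{10^{-3}} ps at the default `dt`).
#' @param symmetrize Replace each stored frame by its Hermitian part
#'   (default `TRUE`; set `FALSE` to inspect raw integrator output).
#' @param engine `"structured"` (default; dense-block evaluation of the
#'   generator, fast) or `"sparse"` (generic sparse-matrix path). Both
#'   implement the same generator and agree to integrator round-off.
#' @return An object of class `heom_trajectory`: `times` (ps), `rho`
#'   (complex `n x n x T` array) and `metadata` (all parameters).
#' @examples
#' H <- exciton_hamiltonian(matrix(c(0, 100, 100, 0), 2), "toy")
#' b <- bath_parameters(lambda = 0, n_sites = 2, r_trap = 0,
#'                      trap_sites = integer(0))
#' g <- assemble_heom_generator(H, b, enumerate_hierarchy(2, 0))
#' tr <- propagate(g, initial_state_localized(1, 2), dt = 1e-3, t_end = 0.1)
#' @export
propagate <- function(gen, rho0, dt = 1e-4, t_end = 15, store_every = 10,
                      symmetrize = TRUE,
                      engine = c("structured", "sparse")) {
  engine <- match.arg(engine)
  stopifnot(inherits(gen, "heom_generator"))
  n <- gen$n_sites
  rho0 <- as.matrix(rho0)
  if (nrow(rho0) != n || ncol(rho0) != n) stop("rho0 must be ", n, "x", n)
  if (max(abs(rho0 - Conj(t(rho0)))) > 1e-10) stop("rho0 must be Hermitian")
  tr0 <- Re(sum(diag(rho0)))
  if (tr0 > 1 + 1e-8 || tr0 <= 0) stop("trace of rho0 must lie in (0, 1]")
  if (min(eigen(rho0, symmetric = TRUE, only.values = TRUE)$values) <
      -1e-8) {
    stop("rho0 must be positive semidefinite")
  }
  if (dt <= 0) stop("dt must be positive")
  nsteps <- as.integer(round(t_end / dt))
  store_every <- max(1L, as.integer(store_every))
  M <- nrow(gen$hier$indices)
  y0 <- complex(real = 0, imaginary = 0)
  y0 <- rep(y0, M * n * n)
  y0[seq_len(n * n)] <- as.vector(rho0) + 0i
  frames <- if (engine == "structured") {
    s <- gen$structured
    heom_rk4_structured_cpp(s$Hp + 0i, s$damp, s$trap, s$nmat, s$raise0,
                            s$lower0, s$cC, s$cA, y0, dt, nsteps,
                            store_every, as.integer(n * n))
  } else {
    heom_rk4_cpp(gen$Gr, gen$Gi, y0, dt, nsteps, store_every,
                 as.integer(n * n))
  }
  nst <- ncol(frames)
  times <- (seq_len(nst) - 1) * store_every * dt
  rho <- array(frames, dim = c(n, n, nst))
  if (symmetrize) {
    for (t in seq_len(nst)) {
      rho[, , t] <- (rho[, , t] + Conj(t(rho[, , t]))) / 2
    }
  }
  structure(list(
    times = times, rho = rho,
    metadata = c(gen$params,
                 list(dt = dt, t_end = t_end, store_every = store_every,
                      n_sites = n, symmetrized = symmetrize))),
    class = "heom_trajectory")
}

#' @export
print.heom_trajectory <- function(x, ...) {
  cat(sprintf(
    "<heom_trajectory> %d sites, %d frames over [0, %.4g] ps, trace %.4f -> %.4f\n",
    dim(x$rho)[1], length(x$times), max(x$times),
    Re(sum(diag(x$rho[, , 1]))),
    Re(sum(diag(x$rho[, , length(x$times)])))))
  invisible(x)
}

#' Extract one frame of a trajectory
#'
#' @param traj A `heom_trajectory`.
#' @param t Index of the stored frame (1-based).
#' @return Complex density matrix at that frame.
#' @export
trajectory_frame <- function(traj, t) {
  stopifnot(inherits(traj, "heom_trajectory"))
  traj$rho[, , t]
}

#' Site populations of a trajectory
#'
#' @param traj A `heom_trajectory`.
#' @return Data frame with columns `time`, `site`, `population`.
#' @export
trajectory_populations <- function(traj) {
  stopifnot(inherits(traj, "heom_trajectory"))
  n <- dim(traj$rho)[1]
  pops <- t(apply(traj$rho, 3, function(m) Re(diag(m))))
  data.frame(
    time = rep(traj$times, times = n),
    site = rep(seq_len(n), each = length(traj$times)),
    population = as.vector(pops))
}
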