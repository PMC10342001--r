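# Propagator checks against closed-form oracles at desk scale.

test_that("closed-system limit reproduces the dimer Rabi oscillation", {
  J <- 100; de <- 60
  H <- exciton_hamiltonian(matrix(c(de, J, J, -de), 2), "dimer")
  b <- bath_parameters(lambda = 0, gamma = 50, temperature = 77,
                       r_trap = 0, trap_sites = integer(0), n_sites = 2)
  g <- assemble_heom_generator(H, b, enumerate_hierarchy(2, 0))
  tr <- propagate(g, initial_state_localized(1, 2), dt = 1e-4, t_end = 1)
  p2 <- vapply(seq_along(tr$times), function(t) Re(tr$rho[2, 2, t]), 0)
  ref <- dimer_reference_dynamics(de, -de, J, tr$times)
  expect_lt(max(abs(p2 - ref$p2)), 1e-6)
})

test_that("trace is conserved without trapping and decays with it", {
  H <- exciton_hamiltonian(matrix(c(0, 100, 100, 50), 2), "dimer")
  b0 <- bath_parameters(lambda = 35, gamma = 50, temperature = 77,
                        r_trap = 0, trap_sites = integer(0), n_sites = 2)
  g0 <- assemble_heom_generator(H, b0, enumerate_hierarchy(2, 3))
  tr0 <- propagate(g0, initial_state_localized(1, 2), dt = 1e-4, t_end = 2)
  traces <- vapply(seq_along(tr0$times),
                   function(t) Re(sum(diag(tr0$rho[, , t]))), 0)
  expect_lt(max(abs(traces - 1)), 1e-8)

  b1 <- bath_parameters(lambda = 35, gamma = 50, temperature = 77,
                        r_trap = 1, trap_sites = 2L, n_sites = 2)
  g1 <- assemble_heom_generator(H, b1, enumerate_hierarchy(2, 3))
  tr1 <- propagate(g1, initial_state_localized(1, 2), dt = 1e-4, t_end = 2)
  traces1 <- vapply(seq_along(tr1$times),
                    function(t) Re(sum(diag(tr1$rho[, , t]))), 0)
  expect_true(all(diff(traces1) <= 1e-12))
  expect_lt(traces1[length(traces1)], 1)
})

test_that("pure trapping follows the exponential drain law", {
  H <- exciton_hamiltonian(matrix(0, 2, 2), "zero")
  b <- bath_parameters(lambda = 0, gamma = 50, temperature = 77,
                       r_trap = 1, trap_sites = 1L, n_sites = 2)
  g <- assemble_heom_generator(H, b, enumerate_hierarchy(2, 0))
  tr <- propagate(g, initial_state_localized(1, 2), dt = 1e-4, t_end = 1)
  traces <- vapply(seq_along(tr$times),
                   function(t) Re(sum(diag(tr$rho[, , t]))), 0)
  expect_equal(traces, exp(-2 * tr$times), tolerance = 1e-10)
})

test_that("pure dephasing matches the exact cumulant decay", {
  # uncoupled two-site system, bath on site 1 only: the coherence decays
  # exactly as exp(-(2 lambda kB T / gamma^2)(gamma t - 1 + e^(-gamma t)))
  H <- exciton_hamiltonian(matrix(0, 2, 2), "dephase")
  b <- bath_parameters(lambda = c(35, 0), gamma = 50, temperature = 77,
                       r_trap = 0, trap_sites = integer(0), n_sites = 2)
  g <- assemble_heom_generator(H, b, enumerate_hierarchy(2, 25))
  tr <- propagate(g, matrix(0.5, 2, 2), dt = 1e-4, t_end = 0.5)
  lam <- wavenumber_to_angular_frequency(35)
  gam <- wavenumber_to_angular_frequency(50)
  kT <- wavenumber_to_angular_frequency(thermal_energy_wavenumber(77))
  t <- tr$times
  exact <- 0.5 * exp(-(2 * lam * kT / gam^2) * (gam * t - 1 + exp(-gam * t)))
  got <- vapply(seq_along(t), function(s) Mod(tr$rho[1, 2, s]), 0)
  expect_lt(max(abs(got - exact)), 1e-10)
})

test_that("stored states stay Hermitian and nearly positive", {
  set.seed(2)
  H <- random_exciton_hamiltonian(4, seed = 2)
  b <- bath_parameters(lambda = 35, gamma = 50, temperature = 150,
                       r_trap = 1, trap_sites = c(2, 3), n_sites = 4)
  g <- assemble_heom_generator(H, b, enumerate_hierarchy(4, 3))
  tr <- propagate(g, initial_state_fret(H, 1), dt = 1e-4, t_end = 1,
                  symmetrize = FALSE)
  for (s in seq(1, length(tr$times), by = 100)) {
    rho <- tr$rho[, , s]
    expect_lt(max(Mod(rho - Conj(t(rho)))), 1e-8)
    expect_gt(min(Re(eigen((rho + Conj(t(rho))) / 2, symmetric = TRUE,
                           only.values = TRUE)$values)), -1e-6)
  }
})

test_that("halving the step leaves stored populations unchanged to 1e-6", {
  H <- exciton_hamiltonian(matrix(c(100, 80, 80, -50), 2), "dimer")
  b <- bath_parameters(lambda = 35, gamma = 50, temperature = 100,
                       r_trap = 0.5, trap_sites = 2L, n_sites = 2)
  g <- assemble_heom_generator(H, b, enumerate_hierarchy(2, 3))
  r0 <- initial_state_localized(1, 2)
  tA <- propagate(g, r0, dt = 2e-4, t_end = 0.4, store_every = 5)
  tB <- propagate(g, r0, dt = 1e-4, t_end = 0.4, store_every = 10)
  expect_equal(tA$times, tB$times, tolerance = 1e-12)
  expect_lt(max(Mod(tA$rho - tB$rho)), 1e-6)
})

test_that("structured and sparse engines implement the same generator", {
  set.seed(9)
  H <- random_exciton_hamiltonian(3, seed = 9)
  b <- bath_parameters(lambda = c(35, 50, 20), gamma = 50,
                       temperature = 200, r_trap = 0.7, trap_sites = 2L,
                       n_sites = 3)
  g <- assemble_heom_generator(H, b, enumerate_hierarchy(3, 3))
  r0 <- initial_state_fret(H, 1)
  tS <- propagate(g, r0, dt = 1e-4, t_end = 0.2, engine = "structured")
  tG <- propagate(g, r0, dt = 1e-4, t_end = 0.2, engine = "sparse")
  expect_lt(max(Mod(tS$rho - tG$rho)), 1e-12)
})

test_that("t_end = 0 returns a single frame equal to the initial state", {
  H <- exciton_hamiltonian(matrix(c(0, 10, 10, 0), 2), "dimer")
  b <- bath_parameters(n_sites = 2, trap_sites = integer(0), r_trap = 0)
  g <- assemble_heom_generator(H, b, enumerate_hierarchy(2, 1))
  tr <- propagate(g, initial_state_localized(2, 2), t_end = 0)
  expect_identical(length(tr$times), 1L)
  expect_equal(Re(tr$rho[, , 1]), initial_state_localized(2, 2),
               tolerance = 1e-15)
})

test_that("divergent integration aborts naming the failing step", {
  H <- exciton_hamiltonian(matrix(c(0, 5000, 5000, 0), 2), "stiff")
  b <- bath_parameters(lambda = 0, n_sites = 2, trap_sites = integer(0),
                       r_trap = 0)
  g <- assemble_heom_generator(H, b, enumerate_hierarchy(2, 0))
  expect_error(
    propagate(g, initial_state_localized(1, 2), dt = 10, t_end = 10000,
              store_every = 1),
    "diverged")
})

test_that("generator input validation catches shape problems", {
  H <- exciton_hamiltonian(matrix(c(0, 10, 10, 0), 2), "dimer")
  b8 <- bath_parameters(n_sites = 8)
  expect_error(assemble_heom_generator(H, b8, enumerate_hierarchy(2, 1)),
               "disagree")
  b2 <- bath_parameters(n_sites = 2, trap_sites = integer(0), r_trap = 0)
  g <- assemble_heom_generator(H, b2, enumerate_hierarchy(2, 1))
  expect_error(propagate(g, matrix(c(1, 0.5, 0, 0), 2), t_end = 0.01),
               "Hermitian")
  expect_error(propagate(g, diag(c(2, 0)), t_end = 0.01), "trace")
})
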