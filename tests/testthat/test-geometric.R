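# Embedding, reductions, fidelity and the closest-separable-state
# optimizers, checked against closed forms and brute-force oracles.

test_that("qubit embedding preserves coherences and absorbs the deficit", {
  set.seed(1)
  rho <- 0.9 * pure_rho(rand_amplitudes(4))   # trace 0.9
  big <- embed_single_excitation(rho)
  expect_equal(Re(sum(diag(big))), 1, tolerance = 1e-12)
  idx <- 1 + 2^(0:3)
  expect_equal(big[idx, idx], rho + 0i, tolerance = 1e-12)
  expect_equal(Re(big[1, 1]), 0.1, tolerance = 1e-12)
})

test_that("three-site reductions follow the occupation bookkeeping", {
  expect_equal(reduce_to_sites(initial_state_localized(3), c(3, 4, 8)),
               {
                 m <- matrix(0 + 0i, 8, 8); m[2, 2] <- 1; m
               }, tolerance = 1e-12)
  # single-site analogue: population p maps to diag(1 - p, p)
  rho <- diag(c(0.3, 0.7, rep(0, 6)))
  expect_equal(reduce_to_sites(rho, 1), diag(c(0.7, 0.3)) + 0i,
               tolerance = 1e-12)
  # exhaustive index mapping on random diagonal (trace-deficient) inputs
  set.seed(12)
  for (rep in 1:5) {
    p <- runif(8); p <- 0.85 * p / sum(p)
    tri <- sample(8, 3)
    red <- reduce_to_sites(diag(p), tri)
    expect_equal(Re(diag(red)[1 + 2^(0:2)]), p[tri], tolerance = 1e-12)
    expect_equal(Re(red[1, 1]), 1 - sum(p[tri]), tolerance = 1e-12)
    expect_equal(Re(sum(diag(red))), 1, tolerance = 1e-12)
  }
  # coherences among the selected sites are retained in qubit order
  set.seed(13)
  rho2 <- pure_rho(rand_amplitudes(8))
  red2 <- reduce_to_sites(rho2, c(3, 6, 7))
  expect_equal(red2[2, 3], rho2[3, 6], tolerance = 1e-12)
  expect_equal(red2[2, 5], rho2[3, 7], tolerance = 1e-12)
  expect_error(reduce_to_sites(rho2, c(3, 3, 7)), "distinct")
})

test_that("closest product state recovers closed-form overlaps", {
  # product input
  pr <- random_product_state(4, seed = 21)
  expect_equal(closest_product_state_pure(pr$vector, restarts = 10,
                                          seed = 1)$value, 1,
               tolerance = 1e-9)
  # W state of three qubits
  expect_equal(closest_product_state_pure(w_state(3), restarts = 30,
                                          seed = 2)$value, 4 / 9,
               tolerance = 1e-7)
  # two-qubit pure state of concurrence C: (1 + sqrt(1 - C^2)) / 2
  set.seed(22)
  for (th in c(0.2, 0.7, pi / 4)) {
    psi <- rep(0 + 0i, 4)
    psi[2] <- cos(th); psi[3] <- sin(th)   # |10> and |01>
    C <- abs(sin(2 * th))
    expect_equal(closest_product_state_pure(psi, restarts = 20,
                                            tol = 1e-10)$value,
                 (1 + sqrt(1 - C^2)) / 2, tolerance = 1e-7)
  }
  expect_error(closest_product_state_pure(c(1, 1, 0, 0) + 0i),
               "normalized")
})

test_that("single-excitation overlaps are phase-gauge invariant", {
  set.seed(23)
  a <- rand_amplitudes(6)
  v1 <- closest_product_state_pure(embed_state_vector(a), restarts = 25,
                                   tol = 1e-10, seed = 3)$value
  a2 <- a * exp(1i * runif(6, 0, 2 * pi))
  v2 <- closest_product_state_pure(embed_state_vector(a2), restarts = 25,
                                   tol = 1e-10, seed = 3)$value
  expect_equal(v1, v2, tolerance = 1e-5)
})

test_that("more restarts never lower the best overlap", {
  psi <- embed_state_vector(rand_amplitudes(5))
  v5 <- closest_product_state_pure(psi, restarts = 5, seed = 7)$value
  v25 <- closest_product_state_pure(psi, restarts = 25, seed = 7)$value
  expect_gte(v25, v5 - 1e-12)
})

test_that("Uhlmann fidelity has its defining properties", {
  set.seed(24)
  rho <- random_density(4, seed = 31)
  expect_equal(uhlmann_fidelity(rho, rho), 1, tolerance = 1e-10)
  e1 <- diag(c(1, 0, 0, 0)); e2 <- diag(c(0, 1, 0, 0))
  expect_equal(uhlmann_fidelity(e1, e2), 0, tolerance = 1e-12)
  p <- c(0.1, 0.2, 0.3, 0.4); q <- c(0.4, 0.3, 0.2, 0.1)
  expect_equal(uhlmann_fidelity(diag(p), diag(q)), sum(sqrt(p * q))^2,
               tolerance = 1e-10)
  sig <- random_density(4, seed = 32)
  expect_equal(uhlmann_fidelity(rho, sig), uhlmann_fidelity(sig, rho),
               tolerance = 1e-10)
})

test_that("separable mixtures attain unit fidelity to the separable set", {
  sep <- random_separable_mixture(2, members = 3, seed = 2)
  r <- lambda_mixed(sep$rho, restarts = 2, seed = 3)
  expect_equal(r$value, 1, tolerance = 1e-4)
  sep3 <- random_separable_mixture(3, members = 5, seed = 7)
  r3 <- lambda_mixed(sep3$rho, restarts = 2, seed = 5)
  expect_equal(r3$value, 1, tolerance = 1e-4)
})

test_that("the mixed-state route agrees with the pure-state route", {
  w3 <- w_state(3)
  pure <- closest_product_state_pure(w3, restarts = 20, seed = 1)$value
  mixed <- lambda_mixed(pure_rho(w3), restarts = 2, seed = 4)$value
  expect_equal(mixed, pure, tolerance = 1e-6)
})

test_that("two-qubit Bell-diagonal mixture matches its concurrence form", {
  # Wei-Goldbart: for two-qubit states of concurrence C the closest
  # separable state gives Lambda = (1 + sqrt(1 - C^2)) / 2; for the
  # Bell state mixed with white noise at p = 1/2, C = (3p - 1)/2 = 1/4
  bell <- embed_state_vector(c(1, 1) / sqrt(2))
  rho <- 0.5 * pure_rho(bell) + 0.5 * diag(4) / 4
  r <- lambda_mixed(rho, restarts = 3, seed = 6)
  expect_equal(r$value, (1 + sqrt(1 - 0.25^2)) / 2, tolerance = 1e-3)
})

test_that("lambda results stay in [0, 1] with usable diagnostics", {
  set.seed(25)
  rho <- random_density(8, seed = 41)
  r <- lambda_mixed(rho, restarts = 2, max_iter = 30, seed = 8)
  expect_gte(r$value, 0); expect_lte(r$value, 1)
  expect_true(is.list(r$best_ensemble))
  expect_equal(sum(r$best_ensemble$weights), 1, tolerance = 1e-8)
})

test_that("localized eigenvectors of a diagonal model give Lambda = 1", {
  H <- exciton_hamiltonian(diag(1:8 * 100), "diag")
  tab <- lambda_of_eigenvectors(H, restarts = 5, seed = 1)
  expect_equal(tab$lambda, rep(1, 8), tolerance = 1e-9)
})
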