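test_that("permutations enumerate lexicographically with exact bounds", {
  p3 <- enumerate_permutations(3)
  expect_identical(nrow(p3$perms), 6L)
  expect_identical(p3$perms[1, ], c(1L, 2L, 3L))
  expect_identical(p3$perms[6, ], c(3L, 2L, 1L))
  expect_identical(perm_unrank(1, 8), 1:8)
  expect_identical(perm_unrank(factorial(8), 8), 8:1)
  expect_identical(perm_rank(8:1), as.integer(factorial(8)))
})

test_that("rank and unrank are mutually inverse", {
  set.seed(31)
  for (r in c(1, 2, 5040, 20000, 40320, sample(40320, 20))) {
    expect_identical(perm_rank(perm_unrank(r, 8)), as.integer(r))
  }
  p4 <- enumerate_permutations(4)
  for (r in 1:24) expect_identical(perm_rank(p4$perms[r, ]), r)
})

test_that("permutation action relabels sites and inverts exactly", {
  rho <- initial_state_localized(1, 2)
  expect_identical(permute_state(rho, c(2, 1)),
                   initial_state_localized(2, 2))
  set.seed(32)
  rho8 <- pure_rho(rand_amplitudes(8))
  p <- sample(8)
  expect_identical(permute_state(permute_state(rho8, p), order(p)), rho8)
  expect_identical(permute_state(rho8, 1:8), rho8)
  # transpose convention applies the inverse permutation
  expect_identical(permute_state(rho8, p, convention = "transpose"),
                   permute_state(rho8, order(p)))
  expect_error(permute_state(rho8, c(1, 1, 2:7)), "permutation")
})

test_that("the fidelity sweep matches a brute-force loop on 4 sites", {
  set.seed(33)
  ref <- pure_rho(rand_amplitudes(4))
  frames <- list(ref, 0.95 * pure_rho(rand_amplitudes(4)),
                 diag(runif(4)) / 2)
  frames[[3]] <- frames[[3]] / sum(diag(frames[[3]])) * 0.8
  traj <- toy_trajectory(frames, times = c(0, 0.5, 1))
  perms <- enumerate_permutations(4)
  track <- fidelity_track(traj, ref, time_stride = 1, perms = perms)
  land <- fidelity_landscape(traj, ref, time_stride = 1, perms = perms)
  for (s in 1:3) {
    oracle <- brute_force_track(traj$rho[, , s], ref, perms$perms)
    expect_equal(land$fidelities[s, ], oracle, tolerance = 1e-7)
    expect_equal(track$track$best_fidelity[s], max(oracle),
                 tolerance = 1e-7)
    # the reported arg-max attains the oracle maximum
    expect_equal(oracle[track$track$best_index[s]], max(oracle),
                 tolerance = 1e-7)
    # the maximum dominates the identity permutation
    expect_gte(track$track$best_fidelity[s], oracle[1] - 1e-7)
  }
  # at t = 0 the reference matches itself under the identity
  expect_identical(track$track$best_index[1], 1L)
  expect_equal(track$track$best_fidelity[1], 1, tolerance = 1e-9)
})

test_that("permutation-invariant states tie-break to the identity", {
  mixed <- diag(4) / 4
  traj <- toy_trajectory(list(mixed))
  track <- fidelity_track(traj, mixed, time_stride = 1,
                          perms = enumerate_permutations(4))
  expect_identical(track$track$best_index, 1L)
  land <- fidelity_landscape(traj, mixed, time_stride = 1,
                             perms = enumerate_permutations(4))
  expect_lt(diff(range(land$fidelities)), 1e-10)
})

test_that("the landscape refuses to exceed its cell budget", {
  traj <- toy_trajectory(list(diag(4) / 4, diag(4) / 4))
  expect_error(
    fidelity_landscape(traj, diag(4) / 4, time_stride = 1,
                       perms = enumerate_permutations(4),
                       cell_budget = 10),
    "budget")
})
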