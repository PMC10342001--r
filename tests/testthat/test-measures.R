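test_that("concurrences follow their closed forms", {
  rho <- diag(8) / 8
  rho[1, 2] <- rho[2, 1] <- 0.3
  expect_equal(pairwise_concurrence(rho, 1, 2), 0.6)
  expect_equal(pairwise_concurrence(diag(8) / 8, 3, 5), 0)
  expect_equal(pairwise_concurrence(bell_pair_rho(1, 2), 1, 2), 1,
               tolerance = 1e-12)
  expect_error(pairwise_concurrence(rho, 2, 2), "differ")

  expect_equal(single_site_concurrence(diag(c(0.5, 0.5, rep(0, 6))), 1), 1)
  expect_equal(single_site_concurrence(initial_state_localized(3), 3), 0)
  expect_equal(single_site_concurrence(diag(c(0.25, 0.75, rep(0, 6))), 1),
               2 * sqrt(0.1875))
})

test_that("l1 coherence vanishes on diagonal states and sums coherences", {
  expect_equal(l1_coherence(diag(runif(8))), 0)
  uni <- pure_rho(rep(1 / sqrt(8), 8))
  expect_equal(l1_coherence(uni), 7, tolerance = 1e-12)
  expect_equal(l1_coherence(bell_pair_rho(1, 2)), 1, tolerance = 1e-12)
  # consistency identity with the pairwise concurrences
  set.seed(11)
  for (rep in 1:5) {
    rho <- pure_rho(rand_amplitudes(8))
    s <- 0
    for (i in 1:7) for (j in (i + 1):8) {
      s <- s + pairwise_concurrence(rho, i, j)
    }
    expect_equal(l1_coherence(rho), s, tolerance = 1e-10)
  }
})

test_that("negativity and its logarithm behave across cuts", {
  expect_equal(negativity_bipartite(diag(8) / 8, 1), 0)
  expect_equal(negativity_bipartite(bell_pair_rho(1, 2), 1), 1,
               tolerance = 1e-12)
  uni <- pure_rho(rep(1 / sqrt(8), 8))
  expect_equal(negativity_bipartite(uni, 1), sqrt(7) / 4,
               tolerance = 1e-12)
  expect_equal(log_negativity(diag(8) / 8, c(1, 2)), 0)
  expect_equal(log_negativity(bell_pair_rho(1, 2), 1), 1,
               tolerance = 1e-12)
  # monotone bound through the total pairwise concurrence
  set.seed(3)
  rho <- pure_rho(rand_amplitudes(8))
  allC <- 0
  for (i in 1:7) for (j in (i + 1):8) {
    allC <- allC + pairwise_concurrence(rho, i, j)^2
  }
  for (A in list(1, c(1, 5), c(2, 3, 7))) {
    ln <- log_negativity(rho, A)
    expect_gte(ln, 0)
    expect_lte(ln, log2(1 + sqrt(allC)) + 1e-12)
  }
})

test_that("relative entropy of coherence matches hand computations", {
  expect_equal(relative_entropy_measure(diag(c(0.3, 0.7, rep(0, 6)))), 0,
               tolerance = 1e-10)
  uni <- pure_rho(rep(1 / sqrt(8), 8))
  expect_equal(relative_entropy_measure(uni), 3, tolerance = 1e-10)
  expect_equal(relative_entropy_measure(bell_pair_rho(1, 2)), 1,
               tolerance = 1e-10)
})

test_that("Meyer-Wallach is maximal exactly at uniform populations", {
  expect_equal(meyer_wallach(diag(8) / 8), 7 / 16)
  expect_equal(meyer_wallach(initial_state_localized(5)), 0)
  expect_equal(meyer_wallach(diag(c(0.5, 0.5, rep(0, 6)))), 0.25)
  set.seed(4)
  for (rep in 1:20) {
    rho <- pure_rho(rand_amplitudes(8))
    expect_lte(meyer_wallach(rho), 7 / 16 + 1e-12)
  }
})

test_that("partial-transpose negativity agrees with the coherence route", {
  # on single-excitation pure states the site-vs-rest negativity equals
  # twice the summed negative PT eigenvalues of the embedded qubit state
  set.seed(6)
  for (rep in 1:4) {
    a <- rand_amplitudes(8)
    rho <- pure_rho(a)
    for (k in c(1, 4, 8)) {
      big <- embed_single_excitation(rho)
      pt <- partial_transpose(big, k, 8)
      ev <- Re(eigen(pt, symmetric = TRUE, only.values = TRUE)$values)
      expect_equal(negativity_bipartite(rho, k), 2 * sum(abs(ev[ev < 0])),
                   tolerance = 1e-8)
    }
  }
})

test_that("normalised negativity spots Bell pairs and ignores the rest", {
  expect_equal(normalized_negativity(diag(8) / 8, c(1, 2)), 0,
               tolerance = 1e-10)
  expect_equal(normalized_negativity(bell_pair_rho(1, 2), 1), 1,
               tolerance = 1e-10)
})

test_that("weighted average entanglement decomposes consistently", {
  rho <- diag(c(0.2, 0.3, 0.5, rep(0, 5)))
  wd <- weighted_average_entanglement(rho)
  expect_equal(wd$total, 0)
  expect_true(all(wd$breakdown$contribution == 0))

  set.seed(8)
  rho2 <- pure_rho(rand_amplitudes(8))
  w2 <- weighted_average_entanglement(rho2)
  expect_equal(sum(w2$breakdown$contribution), w2$total,
               tolerance = 1e-12)
  expect_identical(nrow(w2$breakdown), 127L)
  expect_error(weighted_average_entanglement(rho2, "no_such"), "arg")
})
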