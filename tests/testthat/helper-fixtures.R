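# Shared fixtures and independent oracles used across the suite.

# random normalized single-excitation amplitude vector
rand_amplitudes <- function(n) {
  a <- complex(real = rnorm(n), imaginary = rnorm(n))
  a / sqrt(sum(Mod(a)^2))
}

# density matrix of a pure site-basis state
pure_rho <- function(a) {
  a <- as.complex(a)
  a %*% Conj(t(a))
}

# coherent two-site ("Bell-like") single-excitation state on sites k, l
bell_pair_rho <- function(k, l, n = 8) {
  a <- rep(0 + 0i, n); a[k] <- 1 / sqrt(2); a[l] <- 1 / sqrt(2)
  pure_rho(a)
}

# minimal trajectory container for analysis-stage tests
toy_trajectory <- function(rhos, times = seq_along(rhos) - 1) {
  n <- nrow(rhos[[1]])
  arr <- array(0 + 0i, dim = c(n, n, length(rhos)))
  for (t in seq_along(rhos)) arr[, , t] <- rhos[[t]]
  structure(list(times = times, rho = arr, metadata = list(n_sites = n)),
            class = "heom_trajectory")
}

# brute-force permutation fidelity sweep (independent of the C++ path)
brute_force_track <- function(rho, reference, perms) {
  vapply(seq_len(nrow(perms)), function(r) {
    p <- perms[r, ]
    uhlmann_fidelity(reference, rho[p, p])
  }, 0)
}

# exhaustive bipartition count oracle: every subset vs its complement,
# counted once per unordered pair
bipartition_count_oracle <- function(n) {
  (2^n - 2) / 2
}
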