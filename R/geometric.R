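# Geometric entanglement: maximum fidelity with respect to the closest
# fully separable state, for multi-qubit pure and mixed states.

# contract qubit r (little-endian position, 1-based) of a 2^nq tensor with
# the conjugate of a single-qubit state phi
.contract_qubit <- function(vec, nq, r, phi) {
  lower <- 2^(r - 1)
  upper <- 2^(nq - r)
  arr <- array(vec, c(lower, 2, upper))
  as.vector(Conj(phi[1]) * arr[, 1, ] + Conj(phi[2]) * arr[, 2, ])
}

# partial inner product <phi_(not q)|psi>, a 2-vector over qubit q
.partial_inner <- function(psi, m, q, phis) {
  T <- psi
  for (r in sort(setdiff(seq_len(m), q), decreasing = TRUE)) {
    T <- .contract_qubit(T, round(log2(length(T))), r, phis[[r]])
  }
  T
}

.random_qubit <- function() {
  v <- complex(real = stats::rnorm(2), imaginary = stats::rnorm(2))
  v / sqrt(sum(Mod(v)^2))
}

.product_vector <- function(phis) {
  # little-endian: qubit 1 is the fastest-varying index
  v <- phis[[1]]
  for (r in seq_along(phis)[-1]) v <- as.vector(outer(v, phis[[r]]))
  v
}

#' Closest product state of a multi-qubit pure state
#'
#' Maximizes the squared overlap \eqn{\Lambda = |\langle \phi_1 \otimes
#' \cdots \otimes \phi_m | \psi \rangle|^2} over product states by
#' alternating single-qubit updates: each update replaces qubit q's state
#' with the normalized partial inner product of \eqn{\psi} with the other
#' qubits' states, which is monotone in the overlap. The best result over
#' random restarts is returned. For pure states \eqn{\Lambda} equals the
#' maximum fidelity with respect to the closest fully separable state.
#'
#' @param psi Complex state vector of length \eqn{2^m}, normalized.
#' @param restarts Number of random restarts (default 100).
#' @param tol Stop a restart when the overlap gain per sweep falls below
#'   this (default \eqn{10^{-6}} on \eqn{\Lambda}).
#' @param max_sweeps Sweep cap per restart.
#' @param seed Optional integer seed for the restarts.
#' @return An object of class `lambda_result`: `value` (\eqn{\Lambda}),
#'   `product_state` (list of single-qubit states), `iterations` (sweeps of
#'   the best restart), `restarts_used`, `converged`, `seed`.
#' @examples
#' w <- w_state(3)
#' closest_product_state_pure(w, restarts = 20, seed = 1)$value  # 4/9
#' @export
closest_product_state_pure <- function(psi, restarts = 100, tol = 1e-6,
                                       max_sweeps = 500, seed = NULL) {
  psi <- as.complex(psi)
  m <- round(log2(length(psi)))
  if (2^m != length(psi)) stop("psi must have length 2^m")
  if (abs(sum(Mod(psi)^2) - 1) > 1e-8) stop("psi must be normalized")
  if (!is.null(seed)) set.seed(seed)
  best <- -1; best_phis <- NULL; best_it <- 0L; best_conv <- FALSE
  for (r in seq_len(restarts)) {
    phis <- replicate(m, .random_qubit(), simplify = FALSE)
    lam_prev <- -1; conv <- FALSE; it <- 0L
    for (sw in seq_len(max_sweeps)) {
      it <- sw
      lam <- 0
      for (q in seq_len(m)) {
        v <- .partial_inner(psi, m, q, phis)
        nv <- sqrt(sum(Mod(v)^2))
        if (nv > 0) phis[[q]] <- v / nv
        lam <- nv^2   # overlap after the update equals ||v||
      }
      if (lam - lam_prev < tol && sw > 1) { conv <- TRUE; break }
      lam_prev <- lam
    }
    if (lam > best) {
      best <- lam; best_phis <- phis; best_it <- it; best_conv <- conv
    }
  }
  structure(list(value = best, product_state = best_phis,
                 iterations = best_it, restarts_used = restarts,
                 converged = best_conv, seed = seed),
            class = "lambda_result")
}

#' @export
print.lambda_result <- function(x, ...) {
  cat(sprintf("<lambda_result> Lambda=%.6f (restarts=%d, converged=%s)\n",
              x$value, x$restarts_used, x$converged))
  invisible(x)
}

.sqrtm_psd <- function(rho, floor = 0) {
  e <- eigen((rho + Conj(t(rho))) / 2, symmetric = TRUE)
  v <- pmax(Re(e$values), floor)
  e$vectors %*% (sqrt(v) * Conj(t(e$vectors)))
}

#' Uhlmann fidelity of two density matrices
#'
#' \eqn{F(\rho,\sigma) = [\mathrm{Tr}\sqrt{\sqrt\rho\,\sigma\sqrt\rho}]^2},
#' symmetric in its arguments and equal to 1 iff the states coincide.
#'
#' @param rho,sigma Positive semidefinite unit-trace matrices (eigenvalues
#'   above \eqn{-10^{-6}} are tolerated and clipped).
#' @return Fidelity in \[0, 1\].
#' @export
uhlmann_fidelity <- function(rho, sigma) {
  rho <- as.matrix(rho); sigma <- as.matrix(sigma)
  stopifnot(all(dim(rho) == dim(sigma)))
  for (m in list(rho, sigma)) {
    ev <- eigen((m + Conj(t(m))) / 2, symmetric = TRUE,
                only.values = TRUE)$values
    if (min(Re(ev)) < -1e-6) stop("input not positive semidefinite")
  }
  S <- .sqrtm_psd(rho)
  ev <- Re(eigen(S %*% sigma %*% S, symmetric = TRUE,
                 only.values = TRUE)$values)
  min(sum(sqrt(pmax(ev, 0)))^2, 1)
}

# leading eigenvector of a 2x2 Hermitian matrix, closed form
.top_eigvec2 <- function(a, b, d) {
  # matrix [[a, b], [Conj(b), d]] with a, d real
  lam <- (a + d) / 2 + sqrt(((a - d) / 2)^2 + Mod(b)^2)
  if (Mod(b) < 1e-15) {
    if (a >= d) c(1 + 0i, 0) else c(0, 1 + 0i)
  } else {
    v <- c(b, lam - a)
    v / sqrt(sum(Mod(v)^2))
  }
}

# maximize <phi|T|phi> over product states |phi> by alternating single-qubit
# eigenvector updates (T Hermitian)
.best_product_of_operator <- function(T, m, restarts = 4, sweeps = 60,
                                      tol = 1e-10) {
  d <- 2^m
  best <- -Inf; best_phis <- NULL
  basis <- list(c(1 + 0i, 0), c(0, 1 + 0i))
  for (r in seq_len(restarts)) {
    phis <- replicate(m, .random_qubit(), simplify = FALSE)
    val_prev <- -Inf
    for (sw in seq_len(sweeps)) {
      for (q in seq_len(m)) {
        u <- vector("list", 2)
        for (b in 1:2) {
          ph <- phis; ph[[q]] <- basis[[b]]
          u[[b]] <- .product_vector(ph)
        }
        Tu <- list(T %*% u[[1]], T %*% u[[2]])
        phis[[q]] <- .top_eigvec2(
          Re(sum(Conj(u[[1]]) * Tu[[1]])),
          sum(Conj(u[[1]]) * Tu[[2]]),
          Re(sum(Conj(u[[2]]) * Tu[[2]])))
      }
      pv <- .product_vector(phis)
      val <- Re(sum(Conj(pv) * (T %*% pv)))
      if (val - val_prev < tol) break
      val_prev <- val
    }
    if (val > best) { best <- val; best_phis <- phis }
  }
  list(value = best, phis = best_phis)
}

# re-optimize the mixing weights over a fixed set of product states by
# exponentiated-gradient ascent on the (concave) fidelity; monotone
.reweight_ensemble <- function(w, members, S, fid_of, rounds = 8) {
  sigma <- .sigma_of_ensemble(w, members)
  f <- fid_of(sigma)
  for (r in seq_len(rounds)) {
    e <- eigen(S %*% sigma %*% S, symmetric = TRUE)
    lv <- pmax(Re(e$values), 1e-14)
    Minv <- e$vectors %*% ((1 / sqrt(lv)) * Conj(t(e$vectors)))
    T <- S %*% Minv %*% S
    T <- (T + Conj(t(T))) / 2
    g <- vapply(members, function(v) Re(sum(Conj(v) * (T %*% v))), 0)
    eta <- 1; f2 <- f; w2 <- w; s2 <- sigma
    repeat {
      w2 <- w * exp(eta * (g - max(g))); w2 <- w2 / sum(w2)
      s2 <- .sigma_of_ensemble(w2, members); f2 <- fid_of(s2)
      if (f2 >= f - 1e-12 || eta < 1e-4) break
      eta <- eta / 2
    }
    if (f2 <= f + 1e-12) break
    w <- w2; sigma <- s2; f <- f2
  }
  list(weights = w, sigma = sigma, fidelity = f)
}

.sigma_of_ensemble <- function(weights, members) {
  d <- length(members[[1]])
  s <- matrix(0 + 0i, d, d)
  for (k in seq_along(weights)) {
    s <- s + weights[k] * (members[[k]] %*% Conj(t(members[[k]])))
  }
  s
}

#' Maximum fidelity to the closest fully separable state (mixed states)
#'
#' Computes \eqn{\Lambda(\rho) = \max_{\sigma \in S} F(\rho, \sigma)} over
#' the convex set S of fully separable states by alternating an Uhlmann
#' step with a product step: the Uhlmann step forms the operator
#' \eqn{T = \sqrt\rho\,(\sqrt\rho\,\sigma\sqrt\rho)^{-1/2}\sqrt\rho} (the
#' polar-decomposition linearization of the concave fidelity at the current
#' \eqn{\sigma}), the product step finds the product state maximizing
#' \eqn{\langle\phi|T|\phi\rangle} by alternating single-qubit eigenvector
#' updates, and an exact line search mixes it into the ensemble. The
#' fidelity is monotone non-decreasing across iterations; the best value
#' over random restarts is returned.
#'
#' @param rho Density matrix over \eqn{m \le 8} qubits (dimension
#'   \eqn{2^m}).
#' @param ensemble_size Cap on the number of product states kept in the
#'   separable ensemble (default 16).
#' @param restarts Random restarts of the whole see-saw (default 50).
#' @param max_iter Atom-addition iteration cap per restart (default 60);
#'   each restart ends with a polish phase that re-optimizes every
#'   member's single-qubit factors and the mixing weights.
#' @param tol Stop when the fidelity gain falls below this (default
#'   \eqn{10^{-6}}).
#' @param seed Optional integer seed.
#' @return A `lambda_result` with `value`, `best_ensemble`
#'   (list `weights`, `members`), `iterations`, `restarts_used`,
#'   `converged`, `seed`.
#' @export
lambda_mixed <- function(rho, ensemble_size = 16, restarts = 50,
                         max_iter = 60, tol = 1e-6, seed = NULL) {
  rho <- as.matrix(rho)
  d <- nrow(rho)
  m <- round(log2(d))
  if (2^m != d || m > 8) stop("rho must act on m <= 8 qubits (dim 2^m)")
  ev <- eigen((rho + Conj(t(rho))) / 2, symmetric = TRUE,
              only.values = TRUE)$values
  if (min(Re(ev)) < -1e-6) stop("rho not positive semidefinite")
  if (!is.null(seed)) set.seed(seed)
  S <- .sqrtm_psd(rho)
  fid_of <- function(sigma) fidelity_with_sqrt_cpp(S, sigma)
  best <- -1; best_ens <- NULL; best_it <- 0L; best_conv <- FALSE
  for (r in seq_len(restarts)) {
    if (r == 1) {
      # deterministic start: closest product state of each eigenvector of
      # rho, weighted by its eigenvalue (near-optimal for separable inputs)
      ed <- eigen((rho + Conj(t(rho))) / 2, symmetric = TRUE)
      sel <- which(Re(ed$values) > 1e-10)
      fact <- lapply(sel, function(k) {
        closest_product_state_pure(ed$vectors[, k], restarts = 8,
                                   tol = tol)$product_state
      })
      members <- lapply(fact, .product_vector)
      w <- Re(ed$values[sel]); w <- pmax(w, 0); w <- w / sum(w)
    } else {
      k0 <- max(2L, min(ensemble_size, 4L))
      fact <- replicate(k0, replicate(m, .random_qubit(),
                                      simplify = FALSE), simplify = FALSE)
      members <- lapply(fact, .product_vector)
      w <- stats::rexp(k0); w <- w / sum(w)
    }
    sigma <- .sigma_of_ensemble(w, members)
    f <- fid_of(sigma); conv <- FALSE; it <- 0L
    # phase 1: conditional-gradient atom addition with exact line search
    for (step in seq_len(max_iter)) {
      it <- step
      e <- eigen(S %*% sigma %*% S, symmetric = TRUE)
      lv <- pmax(Re(e$values), 1e-14)
      Minv <- e$vectors %*% ((1 / sqrt(lv)) * Conj(t(e$vectors)))
      T <- S %*% Minv %*% S
      T <- (T + Conj(t(T))) / 2
      bp <- .best_product_of_operator(T, m)
      # concavity of F(rho, .) gives the optimality certificate
      #   F* <= F + sqrt(F) (max_phi <phi|T|phi> - sqrt(F)),
      # since grad F = sqrt(F) T and Tr(T sigma) = sqrt(F)
      gap <- sqrt(max(f, 0)) * (bp$value - sqrt(max(f, 0)))
      if (gap < tol) { conv <- TRUE; break }
      phi <- .product_vector(bp$phis)
      P <- phi %*% Conj(t(phi))
      g <- function(eps) fid_of((1 - eps) * sigma + eps * P)
      opt <- stats::optimize(g, c(0, 1), maximum = TRUE, tol = 1e-7)
      g1 <- g(1)
      eps <- if (g1 >= opt$objective) 1 else opt$maximum
      cand <- max(opt$objective, g1)
      if (cand <= f + 1e-14) break
      w <- c((1 - eps) * w, eps)
      members <- c(members, list(phi)); fact <- c(fact, list(bp$phis))
      keep <- w > 1e-10
      if (sum(keep) > ensemble_size) {
        keep <- rank(-w, ties.method = "first") <= ensemble_size
      }
      w <- w[keep] / sum(w[keep])
      members <- members[keep]; fact <- fact[keep]
      rw <- .reweight_ensemble(w, members, S, fid_of, rounds = 5)
      if (rw$fidelity >= f) {
        w <- rw$weights; sigma <- rw$sigma; f <- rw$fidelity
      } else {
        sigma <- .sigma_of_ensemble(w, members)
        f <- fid_of(sigma)
      }
    }
    # phase 2: polish each member's single-qubit factors holding the rest
    # fixed (coordinate ascent), interleaved with weight re-optimization
    for (round in seq_len(25)) {
      f_before <- f
      for (k in seq_along(members)) {
        if (w[k] < 1e-9) next
        sig_rest <- sigma - w[k] * (members[[k]] %*% Conj(t(members[[k]])))
        for (q in seq_len(m)) {
          cur <- fact[[k]][[q]]
          cur <- cur * exp(-1i * Arg(cur[1]))
          par0 <- c(2 * acos(pmin(1, Mod(cur[1]))), Arg(cur[2]))
          obj <- function(p) {
            ph <- fact[[k]]
            ph[[q]] <- c(cos(p[1] / 2), sin(p[1] / 2) * exp(1i * p[2]))
            v <- .product_vector(ph)
            -fid_of(sig_rest + w[k] * (v %*% Conj(t(v))))
          }
          op <- stats::optim(par0, obj, method = "Nelder-Mead",
                             control = list(maxit = 60, reltol = 1e-10))
          if (-op$value > f + 1e-14) {
            fact[[k]][[q]] <- c(cos(op$par[1] / 2),
                                sin(op$par[1] / 2) * exp(1i * op$par[2]))
            members[[k]] <- .product_vector(fact[[k]])
            sigma <- sig_rest +
              w[k] * (members[[k]] %*% Conj(t(members[[k]])))
            f <- -op$value
            sig_rest <- sigma -
              w[k] * (members[[k]] %*% Conj(t(members[[k]])))
          }
        }
      }
      rw <- .reweight_ensemble(w, members, S, fid_of, rounds = 5)
      if (rw$fidelity > f) {
        w <- rw$weights; sigma <- rw$sigma; f <- rw$fidelity
      }
      if (f - f_before < tol / 10) { conv <- TRUE; break }
    }
    if (f > best) {
      best <- f; best_ens <- list(weights = w, members = members)
      best_it <- it; best_conv <- conv
    }
  }
  structure(list(value = best, best_ensemble = best_ens,
                 iterations = best_it, restarts_used = restarts,
                 converged = best_conv, seed = seed),
            class = "lambda_result")
}

#' Geometric entanglement of the Hamiltonian eigenvectors
#'
#' Embeds each excitonic eigenvector as an 8-qubit single-excitation pure
#' state and computes its maximum squared overlap with a fully separable
#' state via [closest_product_state_pure()]. A localized eigenvector gives
#' \eqn{\Lambda = 1}; delocalization lowers \eqn{\Lambda}.
#'
#' @param H An [exciton_hamiltonian()].
#' @param restarts Restarts per eigenvector (default 100).
#' @param tol See-saw tolerance.
#' @param seed Integer seed controlling all restarts.
#' @return Data frame with columns `index` (ascending energy), `energy`
#'   (cm\eqn{^{-1}}), `lambda`, `converged`.
#' @export
lambda_of_eigenvectors <- function(H, restarts = 100, tol = 1e-6,
                                   seed = 1) {
  es <- eigensystem(H)
  n <- length(es$energies)
  set.seed(seed)
  lam <- numeric(n); conv <- logical(n)
  for (k in seq_len(n)) {
    res <- closest_product_state_pure(embed_state_vector(es$vectors[, k]),
                                      restarts = restarts, tol = tol)
    lam[k] <- res$value; conv[k] <- res$converged
  }
  data.frame(index = seq_len(n), energy = es$energies, lambda = lam,
             converged = conv)
}
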