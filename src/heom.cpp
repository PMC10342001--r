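// Hot loops: fixed-step RK4 propagation of the sparse HEOM generator and
// the exhaustive permutation fidelity sweep.
// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

// RK4 integration of dy/dt = (Gr + i*Gi) y, storing the first `nblock`
// components (the vectorized physical density matrix) every `store_every`
// steps, including the initial state.
// [[Rcpp::export]]
arma::cx_mat heom_rk4_cpp(const arma::sp_mat& Gr, const arma::sp_mat& Gi,
                          const arma::cx_vec& y0, double dt, int nsteps,
                          int store_every, int nblock) {
  arma::sp_cx_mat G(Gr, Gi);
  arma::cx_vec y = y0;
  const int nstore = nsteps / store_every + 1;
  arma::cx_mat out(nblock, nstore);
  out.col(0) = y.head(nblock);
  int stored = 1;
  arma::cx_vec k1, k2, k3, k4;
  for (int s = 1; s <= nsteps; ++s) {
    k1 = G * y;
    k2 = G * (y + (dt / 2.0) * k1);
    k3 = G * (y + (dt / 2.0) * k2);
    k4 = G * (y + dt * k3);
    y += (dt / 6.0) * (k1 + 2.0 * k2 + 2.0 * k3 + k4);
    if (s % store_every == 0) {
      out.col(stored) = y.head(nblock);
      ++stored;
      if (!y.head(nblock).is_finite()) {
        Rcpp::stop("HEOM integration diverged (non-finite state) at step %d "
                   "(t = %g ps)", s, s * dt);
      }
    }
    if (s % 4096 == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}

// Uhlmann fidelity of `rho` against a fixed reference, for every row
// permutation in `perms` (1-based site indices, one permutation per row):
// F_pi = (tr sqrt(S rho_pi S))^2 with S = sqrt(reference) precomputed, and
// (rho_pi)_{ij} = rho_{pi(i), pi(j)}.
// [[Rcpp::export]]
arma::vec fidelity_sweep_cpp(const arma::cx_mat& sqrt_ref,
                             const arma::cx_mat& rho,
                             const arma::imat& perms) {
  const arma::uword n = rho.n_rows;
  const arma::uword np = perms.n_rows;
  arma::vec out(np);
  arma::cx_mat rp(n, n), m(n, n);
  arma::vec ev;
  for (arma::uword p = 0; p < np; ++p) {
    for (arma::uword i = 0; i < n; ++i) {
      const arma::uword pi = perms(p, i) - 1;
      for (arma::uword j = 0; j < n; ++j) {
        rp(i, j) = rho(pi, perms(p, j) - 1);
      }
    }
    m = sqrt_ref * rp * sqrt_ref;
    m = 0.5 * (m + m.t());
    arma::eig_sym(ev, m);
    double f = 0.0;
    for (arma::uword i = 0; i < n; ++i) {
      if (ev(i) > 0.0) f += std::sqrt(ev(i));
    }
    out(p) = std::min(f * f, 1.0);
    if (p % 8192 == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}

// Uhlmann fidelity (tr sqrt(S sigma S))^2 with S = sqrt(rho) precomputed;
// the inner evaluation of the separable-state optimizers.
// [[Rcpp::export]]
double fidelity_with_sqrt_cpp(const arma::cx_mat& S,
                              const arma::cx_mat& sigma) {
  arma::cx_mat m = S * sigma * S;
  m = 0.5 * (m + m.t());
  arma::vec ev;
  arma::eig_sym(ev, m);
  double f = 0.0;
  for (arma::uword i = 0; i < ev.n_elem; ++i) {
    if (ev(i) > 0.0) f += std::sqrt(ev(i));
  }
  f = f * f;
  return f > 1.0 ? 1.0 : f;
}

// Structured HEOM right-hand side and RK4 loop: the commutator is a dense
// n x n product per ADO and every hierarchy coupling is elementwise on one
// row and one column, which avoids materializing the sparse generator.
static void heom_deriv(const arma::cx_vec& y, arma::cx_vec& dy,
                       const arma::cx_mat& Hp, const arma::vec& damp,
                       const arma::mat& trap, const arma::imat& nmat,
                       const arma::imat& raise_m, const arma::imat& lower_m,
                       const arma::vec& cC, const arma::vec& cA) {
  const arma::uword n = Hp.n_rows;
  const arma::uword n2 = n * n;
  const arma::uword M = nmat.n_rows;
  const std::complex<double> I(0.0, 1.0);
  for (arma::uword a = 0; a < M; ++a) {
    const arma::cx_mat A(const_cast<std::complex<double>*>(y.memptr()) +
                         a * n2, n, n, false, true);
    arma::cx_mat D(dy.memptr() + a * n2, n, n, false, true);
    D = -I * (Hp * A - A * Hp);
    D -= damp(a) * A;
    D -= trap % A;  // trap(i,j) = r_trap * (1_{i in T} + 1_{j in T})
    for (arma::uword k = 0; k < n; ++k) {
      const arma::sword up = raise_m(a, k);
      if (up >= 0) {
        const arma::cx_mat B(const_cast<std::complex<double>*>(y.memptr()) +
                             up * n2, n, n, false, true);
        for (arma::uword j = 0; j < n; ++j) D(k, j) += I * B(k, j);
        for (arma::uword i = 0; i < n; ++i) D(i, k) -= I * B(i, k);
      }
      const int nk = nmat(a, k);
      if (nk > 0) {
        const arma::sword dn = lower_m(a, k);
        const arma::cx_mat B(const_cast<std::complex<double>*>(y.memptr()) +
                             dn * n2, n, n, false, true);
        const std::complex<double> cr = I * (nk * cC(k));
        const double ca = nk * cA(k);
        for (arma::uword j = 0; j < n; ++j) {
          D(k, j) += (cr + ca) * B(k, j);
        }
        for (arma::uword i = 0; i < n; ++i) {
          D(i, k) += (-cr + ca) * B(i, k);
        }
      }
    }
  }
}

// [[Rcpp::export]]
arma::cx_mat heom_rk4_structured_cpp(const arma::cx_mat& Hp,
                                     const arma::vec& damp,
                                     const arma::mat& trap,
                                     const arma::imat& nmat,
                                     const arma::imat& raise_m,
                                     const arma::imat& lower_m,
                                     const arma::vec& cC,
                                     const arma::vec& cA,
                                     const arma::cx_vec& y0, double dt,
                                     int nsteps, int store_every,
                                     int nblock) {
  arma::cx_vec y = y0;
  const int nstore = nsteps / store_every + 1;
  arma::cx_mat out(nblock, nstore);
  out.col(0) = y.head(nblock);
  int stored = 1;
  arma::cx_vec k1(y.n_elem), k2(y.n_elem), k3(y.n_elem), k4(y.n_elem);
  arma::cx_vec tmp(y.n_elem);
  for (int s = 1; s <= nsteps; ++s) {
    heom_deriv(y, k1, Hp, damp, trap, nmat, raise_m, lower_m, cC, cA);
    tmp = y + (dt / 2.0) * k1;
    heom_deriv(tmp, k2, Hp, damp, trap, nmat, raise_m, lower_m, cC, cA);
    tmp = y + (dt / 2.0) * k2;
    heom_deriv(tmp, k3, Hp, damp, trap, nmat, raise_m, lower_m, cC, cA);
    tmp = y + dt * k3;
    heom_deriv(tmp, k4, Hp, damp, trap, nmat, raise_m, lower_m, cC, cA);
    y += (dt / 6.0) * (k1 + 2.0 * k2 + 2.0 * k3 + k4);
    if (s % store_every == 0) {
      out.col(stored) = y.head(nblock);
      ++stored;
      if (!y.head(nblock).is_finite()) {
        Rcpp::stop("HEOM integration diverged (non-finite state) at step %d "
                   "(t = %g ps)", s, s * dt);
      }
    }
    if (s % 4096 == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}
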