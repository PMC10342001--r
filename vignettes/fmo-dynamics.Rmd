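---
title: "Models and methods behind fmodyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind fmodyn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(fmodyn)
```

# The physical model

Each monomer of the Fenna–Matthews–Olson (FMO) antenna holds eight
bacteriochlorophyll-a pigments. Spectroscopy shows that to an excellent
approximation at most one pigment is excited at a time (dipole blockade),
so the electronic state lives in the 8-dimensional single-excitation
manifold spanned by the occupation states $|k\rangle$. The system
Hamiltonian $H_S$ is a real symmetric 8×8 matrix of site energies
(diagonal, around 12,100–12,700 cm$^{-1}$) and dipolar couplings
(off-diagonal, up to ~100 cm$^{-1}$). The protein scaffold is a phonon
bath; its effect enters through three per-site parameters:

* $\lambda_k$, the reorganization energy (default 35 cm$^{-1}$; the
  literature brackets it between 35 and 65 cm$^{-1}$ and commonly
  analyses both extremes applied uniformly to all sites). It controls
  the dephasing strength and the relocalization term
  $\sum_k \lambda_k |k\rangle\langle k|$ added to $H_S$.
* $\gamma_k$, the Drude–Lorentz cutoff (default 50 cm$^{-1}$), the
  inverse bath-memory time. The bath correlation function is a single
  exponential $C_k(t) = (2\lambda_k k_B T - i\lambda_k\gamma_k)
  e^{-\gamma_k t}$ — the high-temperature limit, with no Matsubara
  corrections.
* $T$, the temperature (default 77 K, the spectroscopy condition;
  77–347 K covers the physiological range of the thermophilic host).

Delivery of the excitation to the reaction centre is modelled as an
anticommutator drain $-r_\mathrm{trap}\{|j\rangle\langle j|,\cdot\}$ on
sites 3 and 4 with $r_\mathrm{trap} = 1$ ps$^{-1}$; the trace of $\rho$
decreases accordingly (the lost weight is the delivered excitation). No
explicit reaction-centre sink state is modelled.

The default initial condition is the dephased entry state through site
8, $\rho(0) = \sum_k |\langle\epsilon_k|8\rangle|^2
|\epsilon_k\rangle\langle\epsilon_k|$ with $|\epsilon_k\rangle$ the
excitonic eigenvectors — the Förster-resonance-motivated preparation. It
commutes with $H_S$, so all subsequent dynamics is bath- and
trap-driven. Localized preparations $|k\rangle\langle k|$ with
$k \in \{1, 6, 8\}$ (the baseplate-facing pigments) are also provided.

## Units and the inverse-temperature convention

Energies are quoted in wavenumbers and converted internally to angular
frequencies, $\omega = 2\pi c\,\tilde\nu$ with $c = 0.0299792458$ cm/ps,
so that $\hbar = 1$ and time is in picoseconds;
$k_B = 0.69503480\ \mathrm{cm^{-1}/K}$. The inverse temperature is
$\beta = 1/(k_B T)$ throughout. This convention is forced by dimensional
consistency of the hierarchy: the anticommutator-to-commutator ratio of
the bath down-coupling is $\gamma_k/(2 k_B T) = \beta\hbar\gamma_k/2$,
which is dimensionless only with $\beta$ an inverse energy.

## The hierarchy and its coefficient convention

`assemble_heom_generator()` builds, for every multi-index $n$ with
$\sum_k n_k \le D$,

$$\dot\rho_n = -i[H_S + \textstyle\sum_k \lambda_k V_k, \rho_n]
 - \textstyle\sum_k n_k\gamma_k \rho_n
 - r_\mathrm{trap}\textstyle\sum_{j\in\{3,4\}}\{V_j,\rho_n\}
 + i\textstyle\sum_k [V_k, \rho_{n_k^+}]
 + i\textstyle\sum_k n_k\big(2\lambda_k k_B T\,[V_k, \rho_{n_k^-}]
   - i\lambda_k\gamma_k\{V_k, \rho_{n_k^-}\}\big),$$

with $V_k = |k\rangle\langle k|$. This is the standard unscaled
high-temperature Drude–Lorentz hierarchy: the physical state is the
$n = 0$ member, terms that would reach beyond depth $D$ are dropped (no
time-local terminator), and the down-coupling coefficients are exactly
the real and imaginary parts of the correlation amplitude. Alternative
normalisations that move a factor between the up- and down-couplings
leave $\rho_S$ invariant only when the *product* of the two coefficients
is preserved; a variant sometimes written with a prefactor
$\lambda_k/(\beta\hbar^2\gamma_k)$ multiplying the whole coupling
bracket does not preserve that product and corresponds to a physically
weaker bath. We implement the standard form, for which the package
verifies an exact oracle: for an uncoupled site pair with a bath on one
site, the coherence decays as
$\exp[-(2\lambda k_B T/\gamma^2)(\gamma t - 1 + e^{-\gamma t})]$, and
the propagated result matches it to $10^{-14}$.

Every term of the generator preserves Hermiticity of the full stack, and
with $r_\mathrm{trap} = 0$ the trace of $\rho_S$ is conserved exactly
(the commutators are traceless and the level-0 damping vanishes); both
properties are asserted in the test suite at $10^{-8}$.

## Numerics

* **Integrator.** Classical fixed-step 4th-order Runge–Kutta with
  $\delta t = 10^{-4}$ ps, storing every $10^{-3}$ ps. A fixed step
  makes runs bit-reproducible; halving the step changes stored
  populations by under $10^{-6}$ in the tests. Divergence (non-finite
  state) aborts with the failing step in the message.
* **Two engines, one generator.** The generator exists both as an
  explicit sparse matrix (the superoperator–supervector form,
  $\mathrm{vec}(A\rho B) = (B^T \otimes A)\mathrm{vec}\rho$ with
  column-major vectorization) and as a structured evaluator that applies
  the dense 8×8 commutator per auxiliary and the row/column-wise
  hierarchy couplings directly. They agree to $10^{-12}$ on random
  problems; the structured path is roughly an order of magnitude faster
  and is the default.
* **Stabilisation.** The mean site energy is subtracted from the
  diagonal before propagation (a global phase; recorded as
  `offset_cm1` in the metadata). Stored frames are symmetrized to their
  Hermitian part by default (`symmetrize = FALSE` exposes the raw
  integrator output, which the suite checks stays Hermitian to
  $10^{-8}$).
* **Depth truncation.** The hierarchy depth default is $D = 4$ (495
  auxiliaries). Our own convergence measurement at the default
  parameters (77 K, $\lambda = 35$ cm$^{-1}$) finds the maximal
  population difference between depths shrinking by roughly a factor 7
  per level ($|D4{-}D5| \approx 3\times10^{-3}$,
  $|D5{-}D6| \approx 4\times10^{-4}$ on a 1 ps window), so depth-4
  populations carry an absolute error near the $10^{-3}$ level; users
  needing $10^{-4}$ accuracy at these parameters should run $D = 6$ or
  deeper. The depth-convergence test in the suite documents this
  honestly rather than asserting a tighter claim than the
  implementation attains.
* **Entropy conventions.** All entropies are base-2 (bits) with
  $0\log 0 \equiv 0$; eigenvalues below $10^{-12}$ are treated as exact
  zeros, and negative eigenvalues within the truncation tolerance
  $-10^{-6}$ are clipped for entropy computations only.

# The measures

The bipartition catalog orders the $2^7 - 1 = 127$ splits of the eight
sites by the size of the smaller side (counts 8, 28, 56, 35;
complementary half-splits deduplicated keeping the side containing site
1, lexicographic within each order). Two conventions deserve note:

* The **negativity** across a cut is defined as
  $E^N_{A|B} = \sqrt{\sum_{i\in A,j\in B} C_{ij}^2}$ (root of the summed
  squared pairwise concurrences), so that the logarithmic negativity
  $\log_2(1 + E^N)$ of a coherent two-site (Bell-like) pair split by the
  cut equals exactly 1, the canonical value. Without the root the
  Bell-pair value would not normalise.
* The **relative-entropy measure** is implemented as the relative
  entropy of coherence $S(\mathrm{diag}\,\rho) - S(\rho)$, which is
  non-negative, vanishes exactly on incoherent states, and measures the
  information stored in the coherences. A literal unweighted sum
  $-\sum_i \log_2 \rho_{ii} - S(\rho)$ is unbounded and sign-indefinite
  on generic mixed states and is not implemented.

The Meyer–Wallach measure $\frac1N\sum_k 4\rho_{kk}(1-\rho_{kk})$
depends only on populations; on the single-excitation manifold its
maximum is $7/16$, attained exactly at uniform populations. It is a
population-spreading indicator as much as an entanglement one — a known
deficiency which is why the suite does not expect it to vanish on
diagonal states.

# Geometric entanglement

For a pure $m$-qubit state the closest-product-state overlap is found by
alternating single-qubit updates (each sets one factor to the normalized
partial inner product with the others), which is monotone in the
overlap; 100 random restarts and a $10^{-6}$ stop tolerance are the
defaults. Closed forms validate it: product states give 1, a two-qubit
state of concurrence $C$ gives $(1+\sqrt{1-C^2})/2$, the three-qubit W
state gives $4/9$, and the value is invariant under per-site phase
changes.

For mixed states $\Lambda(\rho) = \max_{\sigma\in S} F(\rho,\sigma)$ is
maximized over the convex set $S$ of fully separable states.
$F(\rho,\cdot)$ is concave, so we use conditional-gradient (Frank–Wolfe)
ascent: the *Uhlmann step* forms
$T = \sqrt\rho\,(\sqrt\rho\,\sigma\sqrt\rho)^{-1/2}\sqrt\rho$, the
gradient direction of the fidelity at the current $\sigma$ (eigenvalues
floored at $10^{-14}$ for the inverse root); the *product step*
maximizes $\langle\phi|T|\phi\rangle$ over product states by alternating
closed-form single-qubit eigenvector updates; an exact line search mixes
the new product state into the ensemble. Concavity yields the
optimality certificate
$F^\* \le F + \sqrt F(\max_\phi\langle\phi|T|\phi\rangle - \sqrt F)$,
which is the stopping rule. Because conditional-gradient convergence has
a slow tail, each restart ends with a polish phase: exponentiated-
gradient re-optimization of the mixing weights and coordinate ascent on
every member's single-qubit factors. One restart is deterministic
(closest product states of the eigenvectors of $\rho$, weighted by
eigenvalues — near-optimal for separable inputs); the rest are random.
The fidelity is monotone non-decreasing within a restart, and the
returned value is the best over restarts with the seed recorded.
Validation: constructed separable mixtures reach $\Lambda = 1$ within
$10^{-4}$, pure inputs agree with the pure-state route to $10^{-6}$, and
the Bell-state/white-noise mixture at weight one half reproduces the
two-qubit closed form $(1+\sqrt{1-C^2})/2$ with $C = 1/4$ to $10^{-3}$.

Three-site reductions $\rho_{\{j,k,\ell\}}$ map the selected site
populations and their mutual coherences into a 3-qubit state (first
listed site = least significant qubit); populations of unselected sites
and any trapped weight accumulate in the all-ground population, so the
reduction always has unit trace.

# State-transference tracking

All $8! = 40{,}320$ site permutations are enumerated lexicographically
(constant-time unranking via the factorial number system). The
permutation action is $(i,j) \mapsto (\pi(i), \pi(j))$; since the
literature does not fix the direction and the asymptotically dominant
permutation depends on it, the transpose (inverse) convention is an
explicit option. For each sampled frame the Uhlmann fidelity against the
unit-trace reference is computed for every permutation with
$\sqrt{\rho_\mathrm{ref}}$ precomputed once; ties break to the lowest
ordinal, so a permutation-invariant frame reports the identity.
Trace-deficient frames are compared as stored — the trapped weight
lowers all fidelities alike. The default analysis stride samples every
10th stored frame; the dense landscape export refuses to allocate more
than a configurable cell budget.

# Synthetic data

`random_exciton_hamiltonian()` emulates the statistical shape of
published FMO site Hamiltonians: site energies
$\sim N(12{,}400, 100^2)$ cm$^{-1}$ and couplings
$J_{ij} \sim N(0, (50\,e^{-|i-j|/2})^2)$ cm$^{-1}$. This reproduces the
scales — near-degenerate diagonal, distance-decaying couplings — but
not the specific correlated geometry of a real monomer (the strong 1–2,
4–5, 5–6 pairs), so tests passing on synthetic matrices demonstrate
correctness of the algorithms, not biological fidelity of any particular
realization. The remaining generators (W states, random product states,
separable mixtures with their generating ensemble as a separability
certificate, Ginibre densities, the closed-form dimer Rabi oracle) exist
to give every optimizer and propagator an input with a known answer.

## Provenance of the packaged Hamiltonians

The two matrices under `inst/extdata/` are labelled `_synthetic` because
they are stand-in reconstructions compiled from published excitonic
models of the respective species (a structure-based eight-site
*P. aestuarii* model; a spectroscopy-fitted seven-site *C. tepidum* core
extended by the structure-based eighth site). Published
parameterisations of these complexes disagree at the tens of cm$^{-1}$
level in site energies, and downstream quantities are sensitive to this:
the site-8 weight of the dephased entry state and the localisation of
individual eigenvectors shift at the level of several percent between
parameterisations. Results computed from the packaged matrices should
therefore be read as representative of the model class, not as tied to
one specific published fit.

# Problem sizes used by the test suite

The suite runs at desk scale by design: closed-form oracles use 2–4-site
systems with depths up to 25 (pure dephasing) where exact results exist;
the 8-site depth-convergence check uses a 1 ps window at the default
step; the permutation sweep is verified exhaustively at 4 sites (24
permutations) against a brute-force loop and run once at full 8-site
width. Full 15 ps production runs across the temperature grid are hours
of single-core work and are left to users; the pipeline functions
(`simulate_fmo()`, `measure_trajectory()`, `geometric_series()`,
`transfer_track()`) are the supported interface for them, with the
JSON/CSV stores for caching between stages.

# Known limitations

* The single-exponential high-temperature bath is quantitatively
  strained at 77 K, where $\beta\hbar\gamma \approx 0.9$ is not small;
  low-temperature (Matsubara) corrections are out of scope.
* Depth $D = 4$ leaves population errors near $10^{-3}$ at the default
  parameters (see above).
* The mixed-state $\Lambda$ optimizer certifies optimality only through
  the concavity gap at its final ensemble; it is a lower bound
  in principle, though every closed-form case tested is met to
  $10^{-4}$ or better.
* The permutation sweep is exhaustive by construction; no heuristic
  search is provided for larger site counts, where $N!$ growth makes
  the approach infeasible.
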