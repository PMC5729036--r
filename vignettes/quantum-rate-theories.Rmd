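---
title: "Quantum rate theories for kinetic isotope effects: models, estimators, and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantum rate theories for kinetic isotope effects}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(kinst)
```

# The problem and the model hierarchy

A thermally activated reaction with a barrier has a classical
transition-state-theory (TST) rate
$k_{TST} = (2\pi\hbar\beta)^{-1}(Q^\ddagger/Q_r)e^{-\beta V^\ddagger}$.
Quantum nuclear effects enter in two ways: zero-point energy, which
shifts the effective barrier, and tunneling, which can accelerate the
rate by many orders of magnitude at low temperature.  Both are probed
experimentally through kinetic isotope effects (KIEs), ratios
$k_A/k_B$ of isotopologue rates at the same temperature, in which
potential-surface errors largely cancel.

`kinst` implements four levels of theory on pluggable model surfaces,
with exact one-dimensional quantum oracles as referees:

1. **Eyring TST with the Wigner correction**
   $\kappa = 1 + (\hbar\beta\bar\omega)^2/24$, where $\bar\omega$ is the
   magnitude of the barrier's imaginary frequency.  Valid above the
   crossover temperature $T_c = \hbar\bar\omega/(2\pi k_B)$.
2. **Ring-polymer semiclassical instanton (SCI)** below $T_c$: the rate
   is dominated by the periodic orbit on the inverted potential,
   discretized as a cyclic polymer of $N$ beads at a stationary point of
   the Euclidean action.
3. **Quantum instanton (QI)**: a quantum TST built from zero-time
   properties of flux–flux and delta–delta correlation functions,
   evaluated by path-integral Monte Carlo (PIMC); the natural tool for
   KIEs because the ratio factorizes into separately estimable pieces.
4. **Exact references**: Numerov scattering, sinc-DVR diagonalization,
   spectral and finite-Trotter evaluations of all QI ingredients.

Internally $\hbar = k_B = 1$; the user picks mass/length/energy scales.
Spectroscopic converters (`convert_energy()`, `thermal_state()`,
`kinst_constants`) cover cm$^{-1}$, kcal/mol, kJ/mol, eV and kelvin.

# The stated world: model surfaces as synthetic data

There are no external datasets.  The "data" of every test are model
surfaces constructed in code:

* the symmetric **Eckart barrier** $V = V_0\,\mathrm{sech}^2(x/a)$,
  whose thermal tunneling correction depends only on the quantumness
  $\alpha = \pi a\sqrt{2 m V_0}/\hbar$ and on $b = \beta/\beta_c$ with
  $\beta_c = \alpha/V_0$.  The benchmark family is $\alpha = 12$
  (an H + H$_2$-like degree of quantumness) at
  $b \in \{0.5, 1, 2, 4, 8\}$, with mass doubling at fixed $\beta$
  defining the benchmark KIE.  These choices, and the printed reference
  values the acceptance suite reproduces, are fixed once and not tuned.
* **quartic double wells**
  $V = B(x^2 - x_0^2)^2/x_0^4$ for tunneling splittings.  The default
  test well ($B = 10$, $x_0 = 2$, $m = 1$) puts the doublet deep below
  the barrier ($B/\hbar\omega \approx 2.2$), the regime where the kink
  formula is expected to be accurate to $\sim$10–20%.
* **separable barrier-plus-harmonic** models
  $V(x, y) = V_{1d}(x) + \tfrac12 m\,\omega(x)^2 y^2$ for
  vibrationally adiabatic (ZPE-corrected barrier) constructions, and
* a **two-dimensional Morse-superposition proton-transfer form** in the
  donor–acceptor distance $R$ and proton progression coordinate
  $\rho = (r - r_0)/(R - R_0)$ ($r_0 = 0.8$, $R_0 = 1.6$): a symmetric
  double-Morse in $\rho$ plus a Morse in $R$.  The published
  parametrization of this family is not openly available, so the
  parameters are user-supplied and the defaults are labelled synthetic;
  only structural facts (donor/acceptor symmetry, domain, double-well
  profile) are asserted about it.

What a green test establishes is therefore correctness of the *methods*
on analytically controllable worlds — not agreement with any molecular
experiment.  Features of real systems deliberately absent: multi-well
anharmonic coupling, rotations with symmetry numbers beyond user input,
non-separable multidimensional tunneling pathways, and solvents.

# Exact Eckart physics

The transmission probability

$$P(\epsilon) = \frac{\cosh(2\alpha\sqrt\epsilon) - 1}
  {\cosh(2\alpha\sqrt\epsilon) + \cosh\sqrt{4\alpha^2 - \pi^2}},
  \qquad \epsilon = E/V_0,$$

requires $\alpha > \pi/2$ and is evaluated in log space.  The exact
tunneling correction is the Boltzmann integral
$\kappa = \beta V_0 e^{\beta V_0}\int_0^\infty P\,e^{-\beta V_0\epsilon}
d\epsilon$, computed in the variable $u = \sqrt\epsilon$ after locating
the integrand peak on a coarse log grid, so corrections of order
$10^{32}$ never overflow.  Mass doubling maps
$(\alpha, b) \to (\sqrt2\alpha, b/\sqrt2)$ and contributes the classical
free-particle factor $\sqrt2$, giving
$\mathrm{KIE} = \sqrt2\,\kappa(\alpha, b)/\kappa(\sqrt2\alpha, b/\sqrt2)$.

A point worth recording: the small-$\beta$ expansion of this exact
$\kappa$ at *fixed* $\alpha$ is **not** purely the Wigner term.
Numerically, $\kappa - 1 \approx (1.64/\alpha)\,b + (2\pi b)^2/24$: a
term linear in $\beta$ survives because $P(E)$ for a finite barrier is
not antisymmetric about $E = V_0$ (for a parabolic top it is, and the
linear term vanishes; it also vanishes as $\alpha \to \infty$).  The
Wigner identity is therefore asserted where both terms are within the
tested band ($b \le 0.05$ at $\alpha = 12$); at $b = 0.1$ the deviation
is 1.3%.

# Ring-polymer instanton

The discretized Euclidean action of a cyclic path with step
$\eta = \beta\hbar/N$ is

$$S = \sum_{i=1}^N\Big[\sum_d \frac{m_d (z_{i+1,d} - z_{i,d})^2}{2\eta}
 + \eta V(z_i)\Big].$$

`optimize_instanton()` starts from beads spread as a cosine between the
classical turning points (amplitude from the parabolic estimate
$\epsilon^* = 1/b_{\rm eff}^2$) and applies capped-step Newton
iterations to $\nabla S = 0$.  A full eigenvector-following saddle
search was considered and found unnecessary on the supported (1-D and
separable) models, where this structured guess always converges to the
correct index-1 stationary point; that simplification is a deliberate
design choice.  The converged signature is verified: exactly one
negative eigenvalue, and a time-translation mode whose magnitude must
fall below $10^{-5}\lambda_{\max}$.  The looseness of that threshold is
not arbitrary: the discrete action only respects *bead-shift* symmetry,
so the continuous-translation mode is zero only to $O(1/N^2)$
(measured: $3\times10^{-6}\lambda_{\max}$ at $N = 32$, shrinking
quadratically).

The rate is the steepest-descent fluctuation formula

$$k\,Q_r = \frac{\ell}{\beta\hbar}
  \Big(\prod_d \frac{m_d}{\eta}\Big)^{N/2}(2\pi\hbar)^{-1/2}
  \big|{\det}'S''\big|^{-1/2} e^{-S/\hbar},$$

with the zero mode replaced by its orbit length
$\ell = \beta\hbar\,|\dot z|$ and $\det'$ running over the remaining
modes (magnitude of the single negative one included).  On the Eckart
barrier this reproduces the closed-form steepest-descent result
$\kappa_{SCI} = 2\sqrt{\pi\alpha/b}\;e^{\alpha(b + 1/b - 2)}$ to
$10^{-3}$ relative at $N = 256$, and `converge_beads()` doubles $N$
(interpolating paths) until the $O(1/N^2)$ tail is below tolerance,
finishing with a Richardson extrapolation.  For separable surfaces the
transverse reactant modes are divided out with the *same* $N$-bead
discretization, so constant transverse frequencies cancel identically —
the property test for multidimensional bookkeeping.

Ground-state splittings of symmetric double wells use the kink on a
linear polymer with ends fixed in the two minima:

$$\Delta = 2\hbar\sqrt{\frac{S_0}{2\pi\hbar\,m\,\eta}}
  \left[\frac{\det M_0}{\det' M_K}\right]^{1/2} e^{-S_K/\hbar},$$

where $M_K$ ($M_0$) is the interior-bead Hessian around the kink (around
the chain resting in one well), $\det'$ drops the quasi-zero translation
mode, and $S_0 = \oint m\dot x^2 d\tau$.  The total imaginary time is
doubled until $\Delta$ is stable at 1% (the zero-temperature limit).
Asymmetric wells are refused — the formula assumes degenerate minima.
Against the DVR oracle the splitting is accurate to $\sim$7–13% on the
test wells, improving with barrier depth, while isotope *ratios* of
splittings are an order of magnitude more accurate — the semiclassical
prefactor error largely cancels between masses.

# Quantum instanton by path-integral Monte Carlo

The QI rate uses only zero-time information:

$$k\,Q_r = \frac{\sqrt\pi\,\hbar}{2\,\Delta H}\,C_{ff}(0), \qquad
\Delta H = \hbar\sqrt{\frac{G''(0)}{2\,G(0)}},\quad
G(u) = \mathrm{Tr}\big[\Delta_a e^{-(\beta/2-u)H}\Delta_b
e^{-(\beta/2+u)H}\big],$$

with dividing surfaces $\Delta_{a,b}$ at a stationary point of
$C_{dd}(0) = G(0)$.  This prefactor convention was fixed by an analytic
free-particle calculation: at high temperature the expression
overestimates the classical rate by exactly $\sqrt{\pi/2} \approx 1.25$,
matching the known numerical statement for this approximation (the
factor cancels between isotopologues, which is why no ad hoc correction
is applied by default).

**Discretization.** $\beta$ splits into $P$ slices; beads 0 and $P/2$
are frozen on the dividing surfaces.  Two factorizations are supported:
Lie-Trotter ($O(P^{-2})$) and Suzuki-Chin ($O(P^{-4})$), the latter with
bead weights $4/3$ (pair centres) and $2/3$ (pair ends) and a gradient
term $(\varepsilon^3/9m)|V'|^2$ on centre beads.  Those coefficients
were fixed on the exact Gaussian determinant of the discrete harmonic
oscillator, where the measured convergence slopes are $-2.0$ and
$-4.0$.  With pinned beads, $P$ must be divisible by 4 so the pins land
on pair ends.

**Sampling.** Staging (free-particle bridge) resampling of bead
segments with Metropolis acceptance on the potential action; segment
length auto-tuned during burn-in to keep acceptance in a healthy band;
whole-chain translations for closed (reactant) rings.  The RNG is a
fully specified splitmix64 + Box–Muller stream, so a seed reproduces
results bit-for-bit on any platform.  Equilibration is enforced by a
two-sample drift test on $\langle V\rangle$; errors are blocked standard
errors with at least 20 blocks.

**Estimators.**

* $C_{ff}(0)/C_{dd}(0) = -\langle(x_{P-1} - x_1)(x_{P/2-1} -
  x_{P/2+1})\rangle/(2\hbar\varepsilon)^2$ — the discrete velocity
  correlator of the beads adjacent to the pins, derived by letting the
  flux operators differentiate the adjoining short-time kernels.
* $\Delta H^2 = \tfrac{\hbar^2}{2}(2/P)^2[\langle(E_1 - E_2)^2\rangle -
  \langle\sum_i de_i/d\varepsilon\rangle]$, from distributing the
  imaginary-time displacement $u$ uniformly over the slices of each half
  polymer; $E_{1,2}$ are thermodynamic half-polymer energy estimators.
* mass derivatives $d\ln Z/d\ln m$ in thermodynamic
  ($P/2 - \sum m\Delta x^2/2\hbar^2\varepsilon$) and virial form (the
  latter from rescaling fluctuations about the pinned-reference path;
  its variance is an order of magnitude lower at large $P$).  The
  virial forms are available for Lie-Trotter; $\Delta H$ and the flux
  correlator are implemented in thermodynamic form only, a documented
  scope decision — at the $P \le 128$ used here their variance is
  manageable.

Every estimator is validated against a deterministic **finite-$P$
oracle** (`qi_finite_p()`): dense matrix products of the same
short-time propagators on a position grid, which isolates the pure
discretization error of each factorization from Monte Carlo noise.
That oracle is also how the Trotter number is chosen
(`choose_trotter()`: double $P$ until the correction moves < 1%), and
how the "Suzuki-Chin needs fewer beads than Lie-Trotter" pattern is
asserted without hardware-dependent timing claims.

**Dividing surfaces.** For symmetric barriers the search runs along the
stretch $(\xi_a,\xi_b) = (-\xi, \xi)$ with the pin-gradient estimator
$d\ln C_{dd}/d\xi$: a Robbins–Monro ascent with decreasing steps,
followed by a polish phase that probes the gradient at five points and
solves the fitted linear model for its root.  Below crossover the
stationary point sits near the instanton turning points; above it the
iteration collapses to $\xi = 0$.

**Absolute rates and KIEs.** The absolute $C_{dd}(0)$ is anchored to its
free-particle closed form by thermodynamic integration in a
potential-switching parameter $\lambda$ (Gauss–Legendre nodes, default
8).  The KIE is assembled as the factorized product
$(Q_r^B/Q_r^A)(\Delta H^B/\Delta H^A)(C_{dd}^A/C_{dd}^B)
\big[(C_{ff}/C_{dd})^A/(C_{ff}/C_{dd})^B\big]$ with each isotopologue at
its *own* optimized surfaces.  The $C_{dd}$ ratio comes from
thermodynamic integration over the geometric mass path
$m(\lambda) = m_A^{1-\lambda}m_B^\lambda$ (5 nodes) with the dividing
surfaces sliding linearly between the two optima; the integrand carries
the explicit pin-motion term $(d\xi/d\lambda)\,d\ln C_{dd}/d\xi$, which
makes the path integral exact for the sliding path rather than relying
on stationarity.  (An earlier variant that re-optimized noisy pins at
each node biased the ratio by tens of percent; the sliding-path form
reproduces the grid oracle to better than 1%.)  Statistical errors
propagate in quadrature in log space.

# Tunable parameters that matter

| Parameter | Meaning | Default | Why |
|---|---|---|---|
| `N` (beads) | SCI Trotter number | doubled from 64–128 until 1% | error is $O(1/N^2)$; Richardson applied |
| `P` (Trotter) | QI slices | from `choose_trotter()` at 1% | deterministic, noise-free selection |
| `sweeps` | PIMC production | $10^4$–$10^5$ | flux-correlator variance dominates |
| `ti_nodes` | Gauss–Legendre nodes | 8 ($\lambda$), 5 (mass) | integrands smooth; checked vs oracle |
| `zero_mode_tol` | translation-mode gate | $10^{-5}\lambda_{\max}$ | $O(1/N^2)$ symmetry breaking |
| quadrature `rel_tol` | exact-$\kappa$ integrals | $10^{-10}$ | two-tolerance consistency check |
| DVR grid | oracle resolution | 2048 points, box doubled on failure | eigenvalue convergence verified |

# Known limitations

* PIMC sampling requires a built-in compiled kernel (Eckart, harmonic,
  quartic double well, free particle); arbitrary R-level surfaces are
  supported by every deterministic method but not by the sampler.
* $\Delta H$ and flux estimators are Lie-Trotter; Suzuki-Chin is
  available for sampling, partition-function and mass-TI channels, and
  for the full correction through the deterministic finite-$P$ route.
* The 2-D proton-transfer surface is a structural stand-in with
  synthetic default parameters; quantities that depend on the published
  parametrization of that force field (or on external fitted surfaces,
  or on solvated models) are out of scope — see `kinst_limitations`.
* Rotational partition functions use the classical rigid rotor with
  user-supplied inertia and symmetry numbers; no automatic symmetry
  detection.
* The dividing-surface search exploits barrier symmetry; general
  asymmetric two-parameter saddle searches are not implemented.
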