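# kinst

Quantum rate theories and kinetic isotope effects (KIEs) for
barrier-crossing reactions, at desk scale.

When a hydrogen atom transfers through a potential barrier, classical
transition-state theory (TST) misses two quantum effects that dominate the
rate at low temperature: zero-point energy and tunneling.  The standard
experimental probe of these effects is the KIE — the ratio of rate
constants of two isotopologues, `KIE = k_light / k_heavy` — because most
systematic errors cancel in the ratio.  `kinst` implements the hierarchy
of theories used to compute such rates and KIEs, each validated against
exact one-dimensional quantum references:

* **Eyring TST + Wigner correction** — harmonic/rigid-rotor partition
  functions with the shallow-tunneling factor
  `kappa = 1 + (hbar * beta * omega_bar)^2 / 24`, valid above the
  crossover temperature `Tc = hbar * omega_bar / (2 pi kB)` (`omega_bar`
  is the magnitude of the barrier's imaginary frequency).
* **Ring-polymer semiclassical instanton (SCI)** — below `Tc`, the rate is
  dominated by a periodic orbit in the inverted potential.  Its discrete
  representation is a cyclic chain of `N` beads at the stationary point of
  the Euclidean action `S`; the rate follows from `exp(-S/hbar)` and the
  fluctuation determinant, with the zero (time-translation) mode traded
  for the orbit length.  The same machinery gives ground-state tunneling
  splittings of symmetric double wells from the kink instanton.
* **Quantum instanton (QI)** — a quantum TST using only zero-time
  information of flux-flux and delta-delta correlation functions,
  `k Qr = sqrt(pi) hbar C_ff(0) / (2 DeltaH)`, with the two dividing
  surfaces at the stationary point of `C_dd(0)`.  Everything is evaluated
  by path-integral Monte Carlo: staging moves, thermodynamic and virial
  estimators, Lie-Trotter and fourth-order Suzuki-Chin factorizations,
  and thermodynamic integration over particle mass for direct KIE ratios.
* **Exact 1-D references** — Numerov scattering transmission, Boltzmann
  integration of `P(E)`, a sinc-DVR eigensolver, and dense-grid /
  finite-Trotter QI quantities, used as oracles throughout the tests.

The canonical benchmark is the symmetric Eckart barrier
`V(x) = V0 sech^2(x/a)`, parametrized by the quantumness
`alpha = pi a sqrt(2 m V0) / hbar` and the reduced inverse temperature
`b = beta/beta_c` with `beta_c = alpha/V0`; `alpha = 12` models an
H + H2-like transfer, and doubling the particle mass at fixed `beta`
defines the benchmark KIE.  Internally `hbar = kB = 1`.

## Worked example

Tunneling corrections `kappa = k/k_TST` for the Eckart barrier with
`alpha = 12` at twice the crossover inverse temperature (`b = 2`):

```r
library(kinst)
surface <- make_eckart(alpha = 12)       # V0 = m = 1, beta_c = 12
state   <- thermal_state(beta = 24)      # b = beta/beta_c = 2

exact_rate_from_transmission(surface, state)
#> <rate_result> method = exact, k = 1.07475e-09, kappa = 4293.06

sci <- converge_beads(surface, state, tol = 0.002, N0 = 128)
sci$rate
#> <rate_result> method = sci, k = 8.76978e-10, kappa = 3503.06
sci$record
#>     N        S    kappa
#> 1 128 17.99842 3508.010
#> 2 256 17.99960 3504.296

eckart_kie_exact(12, 2)                  # exact mass-doubling KIE
#> [1] 57.01397
```

The exact quantum rate exceeds classical TST by 4.3e3 here — deep
tunneling — and the instanton captures it to 18% (3.50e3), converging as
`1/N^2` in the bead number (the `record` column).  The quantum instanton
at `b = 1` by Monte Carlo:

```r
qi <- qi_kappa_mc(surface, thermal_state(beta = 12), P = 64,
                  sweeps = 5e4, seed = 1)
qi
#> <rate_result> method = qi, k = 5.93103e-07, kappa = 7.27821 (+/- 5.1e-08)
```

(exact value 6.16: the QI overestimate above crossover approaches the
known `sqrt(pi/2) ~ 1.25` factor).  Tunneling splitting of a symmetric
quartic double well against the DVR oracle:

```r
dw <- make_double_well(barrier = 10, separation = 4)
tunneling_splitting(dw)
#> <splitting_result> delta = 0.000282494 (well omega = 4.472)
diff(dvr_levels(dw, 2, xlim = c(-5, 5), n = 1024)[1:2])
#> [1] 0.0002576712
```

a 10% semiclassical error that shrinks for deeper wells, while isotope
*ratios* of splittings are much more accurate (a few percent).

## Command line

```sh
inst/cli/kinst table2 --alpha 12 --b 0.5,1,2,4,8 --seed 1 --out bench
inst/cli/kinst rate --b 2,4 --beads 512 --out rates --dump-path path.xyz
inst/cli/kinst splitting --barrier 10 --separation 4 --out split
```

Runs are configured by JSON (`read_run_config()` / `run_config()`),
seeded deterministically, and emit a TSV table plus a JSON provenance
bundle; out-of-regime cells (SCI above crossover) are marked and logged,
mirroring the ellipsis convention of benchmark tables.

## Scope

Quantities that require external fitted potential-energy surfaces, an
unpublished force-field parametrization, hardware-dependent timings, or
a solvated simulation stack are deliberately out of scope; see
`kinst_limitations` and the methods vignette
(`vignettes/quantum-rate-theories.Rmd`).
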