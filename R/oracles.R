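
# Exact 1-D quantum references.  These are numerically converged benchmark
# routes, independent of the approximate rate theories they validate:
# a sinc-DVR eigensolver, Numerov scattering transmission, Boltzmann
# integration of P(E), dense-grid quantum-instanton quantities (spectral),
# and finite-Trotter propagator products for factorization studies.

.sinc_kinetic <- function(n, dx, m) {
  j <- outer(seq_len(n), seq_len(n), "-")
  ifelse(j == 0, pi^2 / 3, 2 * (-1)^j / j^2) / (2 * m * dx^2)
}

.sinc_derivative <- function(n, dx) {
  j <- outer(seq_len(n), seq_len(n), "-")
  ifelse(j == 0, 0, (-1)^j / (j * dx))
}

#' Bound-state levels by sinc-DVR diagonalization
#'
#' Lowest eigenvalues of the 1-D Hamiltonian on a uniform grid with the
#' Colbert-Miller sinc-DVR kinetic operator.  Convergence is verified by a
#' refinement pass (`n` doubled); failure to agree within `tol` doubles the
#' box and grid once more before erroring.
#'
#' @param surface bound 1-D `potential_surface`.
#' @param n_states number of levels returned.
#' @param xlim length-2 box; defaults to `surface$domain` when present.
#' @param n grid points.
#' @param tol relative convergence tolerance on the returned levels.
#' @param check verify grid convergence (set `FALSE` for speed in sweeps).
#' @return numeric vector of eigenvalues, ascending.
#' @export
#' @examples
#' h <- make_harmonic(omega = 2)
#' dvr_levels(h, 3, xlim = c(-6, 6), n = 256)   # 1, 3, 5
dvr_levels <- function(surface, n_states = 10, xlim = NULL, n = 2048,
                       tol = 1e-8, check = TRUE) {
  stopifnot(surface$dim == 1)
  if (is.null(xlim)) xlim <- surface$domain[1, ]
  if (is.null(xlim)) stop("xlim required (no surface domain)", call. = FALSE)
  solve1 <- function(n, xlim) {
    x <- seq(xlim[1], xlim[2], length.out = n)
    V <- vapply(x, surface$energy, numeric(1))
    H <- .sinc_kinetic(n, x[2] - x[1], surface$masses[1]) + diag(V)
    sort(eigen(H, symmetric = TRUE, only.values = TRUE)$values)[1:n_states]
  }
  e1 <- solve1(n, xlim)
  if (!check) return(e1)
  e2 <- solve1(2 * n, xlim)
  scale <- pmax(abs(e2), max(abs(e2)) * 1e-3)
  if (max(abs(e1 - e2) / scale) > tol) {
    xlim3 <- 1.5 * xlim
    e3 <- solve1(2 * n, xlim3)
    if (max(abs(e2 - e3) / scale) > tol)
      stop("DVR levels not converged under grid/box refinement",
           call. = FALSE)
    return(e3)
  }
  e2
}

#' Numerical barrier transmission by Numerov propagation
#'
#' Integrates the stationary Schroedinger equation across the barrier with
#' the Numerov scheme, imposing a purely outgoing wave on the product side
#' and decomposing the wavefunction into incoming/reflected plane waves on
#' the reactant side.  Requires the potential to reach its asymptotes at
#' the box edges (checked against `asym_tol`).
#'
#' @param surface 1-D `potential_surface` with \eqn{V \to 0} as
#'   \eqn{|x| \to \infty}.
#' @param E energies (> 0), vectorized.
#' @param L half box size; default from the surface's model width.
#' @param n grid points (odd preferred); convergence is verified by step
#'   halving.
#' @param asym_tol largest allowed `|V|` at the box edge, relative to the
#'   barrier height.
#' @param tol relative step-halving convergence tolerance (loosen for
#'   potentials with discontinuities, where Numerov degrades to low
#'   order locally).
#' @return transmission probabilities in `[0, 1]`.
#' @export
numerical_transmission <- function(surface, E, L = NULL, n = 8001,
                                   asym_tol = 1e-6, tol = 1e-4) {
  stopifnot(surface$dim == 1)
  if (is.null(L)) {
    a <- surface$meta$a %||% 1
    L <- 12 * a
  }
  m <- surface$masses[1]
  Vmax <- surface$energy(0)
  edge <- max(abs(surface$energy(-L)), abs(surface$energy(L)))
  if (edge > asym_tol * abs(Vmax))
    stop(sprintf("domain error: |V| at box edge is %.2e of the barrier; %s",
                 edge / abs(Vmax), "enlarge L"), call. = FALSE)
  one <- function(E1, n) {
    if (E1 < 1e-6 * max(abs(Vmax), 1e-6))
      return(c(T = 0, R = 1))              # deep sub-barrier: no flux
    x <- seq(-L, L, length.out = n)
    h <- x[2] - x[1]
    k <- sqrt(2 * m * E1)
    Vx <- vapply(x, surface$energy, numeric(1))
    f <- 2 * m * (Vx - E1)               # psi'' = f psi
    w <- 1 - h^2 * f / 12                # Numerov auxiliary
    psi <- complex(length.out = n)
    psi[n] <- exp(1i * k * x[n])
    psi[n - 1] <- exp(1i * k * x[n - 1])
    for (i in (n - 1):2) {
      psi[i - 1] <- ((12 - 10 * w[i]) * psi[i] - w[i + 1] * psi[i + 1]) /
        w[i - 1]
    }
    # match psi = A e^{ikx} + B e^{-ikx} on the two leftmost points
    e1 <- exp(1i * k * x[1]); e2 <- exp(1i * k * x[2])
    det <- e1 * Conj(e2) - Conj(e1) * e2
    A <- (psi[1] * Conj(e2) - psi[2] * Conj(e1)) / det
    B <- (psi[2] * e1 - psi[1] * e2) / det
    c(T = 1 / Mod(A)^2, R = Mod(B)^2 / Mod(A)^2)
  }
  res <- vapply(E, function(E1) {
    p1 <- one(E1, n)
    p2 <- one(E1, 2 * n - 1)
    if (abs(p1[1] - p2[1]) > 1e-6 + tol * p2[1]) {
      p3 <- one(E1, 4 * n - 3)
      if (abs(p2[1] - p3[1]) > 1e-6 + tol * p3[1])
        stop("transmission not converged under step halving", call. = FALSE)
      return(p3)
    }
    p2
  }, numeric(2))
  structure(res["T", ], reflection = res["R", ])
}

#' Exact thermal rate from the transmission probability
#'
#' \deqn{k\,Q_r = \frac{1}{2\pi\hbar}\int_0^\infty P(E)\,e^{-\beta E}\,dE}
#' for a 1-D scattering system with the reactant as a free particle per
#' unit length, together with the tunneling correction
#' \eqn{\kappa = k/k_{TST}} against the classical 1-D flux
#' \eqn{(2\pi\hbar\beta)^{-1} e^{-\beta V^\ddagger}}.  The integral is
#' evaluated in log space (the Eckart `b = 8` table entry is of order
#' \eqn{10^{32}}).
#'
#' @param surface 1-D `potential_surface` (barrier with zero asymptotes).
#' @param state a [thermal_state()].
#' @param transmission function `P(E)`; defaults to the analytic Eckart
#'   formula when the surface is an Eckart barrier, otherwise to
#'   [numerical_transmission()] (slower).
#' @param rel_tol quadrature tolerance.
#' @return a `rate_result` with `k_qr` (\eqn{k\,Q_r}), `kappa`,
#'   `method = "exact"`.
#' @export
exact_rate_from_transmission <- function(surface, state,
                                         transmission = NULL,
                                         rel_tol = 1e-9) {
  beta <- state$beta
  Vb <- surface$energy(0)
  if (is.null(transmission)) {
    if (identical(surface$meta$model, "eckart")) {
      alpha <- surface$meta$alpha; V0 <- surface$meta$V0
      transmission <- function(E) eckart_transmission(E / V0, alpha)
      ltrans <- function(E) eckart_transmission(E / V0, alpha, log = TRUE)
    } else {
      transmission <- function(E) numerical_transmission(surface, E)
      ltrans <- function(E) log(pmax(transmission(E), 1e-300))
    }
  } else {
    ltrans <- function(E) log(pmax(transmission(E), 1e-300))
  }
  # integrate in u = sqrt(E); locate the integrand peak on a coarse grid
  # so the rescaled integrand never overflows
  lnf <- function(u) log(2 * u) + ltrans(u^2) - beta * u^2
  ug <- exp(seq(log(1e-4), log(10 * sqrt(Vb + 10 / beta)), length.out = 200))
  lg <- vapply(ug, lnf, numeric(1))
  us <- ug[which.max(lg)]
  M <- max(lg)
  f <- function(u) exp(lnf(u) - M)
  # analytic high-energy tail with P ~ 1: integral of 2u e^{-beta u^2}
  # beyond u_hi contributes e^{-beta u_hi^2}/beta
  u_hi <- sqrt(max(4 * Vb, us^2) + 25 / beta)
  I <- integrate(f, 0, us, rel.tol = rel_tol, subdivisions = 400L)$value +
    integrate(f, us, u_hi, rel.tol = rel_tol, subdivisions = 400L)$value +
    exp(-beta * u_hi^2 - M) / beta
  ln_kqr <- M + log(I) - log(2 * pi)        # hbar = 1
  ln_ktst <- -log(2 * pi * beta) - beta * Vb
  rate_result(k = exp(ln_kqr), kappa = exp(ln_kqr - ln_ktst),
              method = "exact", log_k = ln_kqr)
}

# ---- dense-grid quantum-instanton quantities (spectral route) ----------

#' Exact quantum-instanton ingredients on a DVR grid
#'
#' Computes the zero-time delta-delta correlation \eqn{C_{dd}(0)}, the
#' flux-flux over delta-delta ratio \eqn{C_{ff}(0)/C_{dd}(0)}, and the
#' energy variance \eqn{\Delta H} for dividing surfaces pinned at
#' `xi_a`, `xi_b`, from the spectral representation of
#' \eqn{e^{-\beta H/2}} on a sinc-DVR grid.  This is the deterministic
#' oracle used to validate the path-integral Monte Carlo estimators.
#'
#' \eqn{\Delta H} uses \eqn{\Delta H = \hbar\sqrt{G''(0)/2G(0)}} with
#' \eqn{G(u) = \mathrm{Tr}[\Delta_a e^{-(\beta/2 - u)H} \Delta_b
#' e^{-(\beta/2 + u)H}]}, which in the eigenbasis becomes a weighted sum
#' over \eqn{(E_n - E_m)^2}.
#'
#' @param surface 1-D `potential_surface`.
#' @param state a [thermal_state()].
#' @param xi_a,xi_b dividing-surface positions.
#' @param L half box, `n` grid points.
#' @return list with `cdd`, `cff`, `cff_over_cdd`, `dH`, `k_qr`
#'   (\eqn{\sqrt\pi\,\hbar\,C_{ff}(0) / 2\Delta H}), `kappa` (ratio to the
#'   classical 1-D TST flux), and the spectral pieces.
#' @export
qi_grid_quantities <- function(surface, state, xi_a, xi_b, L = NULL,
                               n = 600) {
  stopifnot(surface$dim == 1)
  beta <- state$beta
  m <- surface$masses[1]
  if (is.null(L)) {
    a <- surface$meta$a %||% 1
    L <- max(9 * a, 4 * sqrt(beta / m))
  }
  x <- seq(-L, L, length.out = n)
  dx <- x[2] - x[1]
  V <- vapply(x, surface$energy, numeric(1))
  H <- .sinc_kinetic(n, dx, m) + diag(V)
  ee <- eigen(H, symmetric = TRUE)
  E <- ee$values
  psi <- ee$vectors / sqrt(dx)            # continuum-normalized on grid
  dpsi <- .sinc_derivative(n, dx) %*% ee$vectors / sqrt(dx)
  idx <- function(xi) which.min(abs(x - xi))
  ia <- idx(xi_a); ib <- idx(xi_b)
  w <- exp(-beta * (E - min(E)) / 2)      # shift for stability
  shift <- exp(-beta * min(E))            # total weight e^{-beta En} pairs
  v <- w * psi[ia, ] * psi[ib, ]
  cdd <- sum(v)^2 * shift
  SE <- sum(v * E); SE2 <- sum(v * E^2); S0 <- sum(v)
  dH2 <- (SE2 * S0 - SE^2) / S0^2
  dH <- sqrt(max(dH2, 0))
  A <- (outer(psi[ia, ], dpsi[ia, ]) - outer(dpsi[ia, ], psi[ia, ])) / (2 * m)
  B <- (outer(psi[ib, ], dpsi[ib, ]) - outer(dpsi[ib, ], psi[ib, ])) / (2 * m)
  cff <- -sum(outer(w, w) * A * t(B)) * shift
  k_qr <- sqrt(pi) / (2 * dH) * cff
  Vb <- max(V)
  ln_ktst <- -log(2 * pi * beta) - beta * Vb
  list(cdd = cdd, cff = cff, cff_over_cdd = cff / cdd, dH = dH,
       k_qr = k_qr, kappa = k_qr / exp(ln_ktst), x = x, grid_E = E)
}

#' Stationary dividing surfaces on the grid (symmetric barriers)
#'
#' Scans \eqn{C_{dd}(0)} along the symmetric stretch
#' \eqn{(\xi_a, \xi_b) = (-\xi, \xi)} and returns the stationary point
#' used by the quantum instanton: the maximum along the stretch, which
#' separates towards the instanton turning points below crossover and
#' collapses to \eqn{\xi = 0} above it.
#'
#' @inheritParams qi_grid_quantities
#' @param xi_max scan limit; defaults to three barrier widths.
#' @return list `xi` (optimal half separation) and the scan table.
#' @export
qi_grid_saddle <- function(surface, state, L = NULL, n = 600,
                           xi_max = NULL) {
  a <- surface$meta$a %||% 1
  if (is.null(xi_max)) xi_max <- 3.2 * a
  beta <- state$beta
  m <- surface$masses[1]
  if (is.null(L)) L <- max(9 * a, 4 * sqrt(beta / m))
  x <- seq(-L, L, length.out = n)
  dx <- x[2] - x[1]
  V <- vapply(x, surface$energy, numeric(1))
  H <- .sinc_kinetic(n, dx, m) + diag(V)
  ee <- eigen(H, symmetric = TRUE)
  E <- ee$values
  psi <- ee$vectors / sqrt(dx)
  w <- exp(-beta * (E - min(E)) / 2)
  xs <- seq(0, xi_max, by = dx)
  fv <- vapply(xs, function(xi) {
    ia <- which.min(abs(x + xi)); ib <- which.min(abs(x - xi))
    sum(w * psi[ia, ] * psi[ib, ])^2
  }, numeric(1))
  i <- which.max(fv)
  xi <- xs[i]
  if (i > 1 && i < length(xs)) {          # parabolic refinement in log Cdd
    y <- log(fv[(i - 1):(i + 1)])
    num <- (y[1] - y[3]) * dx / (2 * (y[1] - 2 * y[2] + y[3]))
    if (is.finite(num) && abs(num) < dx) xi <- xi + num
  }
  list(xi = max(xi, 0), scan = data.frame(xi = xs, cdd_rel = fv / max(fv)))
}

# ---- finite-Trotter propagator products (factorization studies) --------

.mat_pow <- function(B, k) {
  R <- diag(nrow(B))
  while (k > 0) {
    if (k %% 2 == 1) R <- R %*% B
    B <- B %*% B
    k <- k %/% 2
  }
  R
}

#' Quantum-instanton correction at finite Trotter number (deterministic)
#'
#' Evaluates the finite-\eqn{P} discretized \eqn{C_{dd}}, \eqn{C_{ff}} and
#' \eqn{\Delta H} by dense matrix products of short-time propagators,
#' for either the Lie-Trotter or the Suzuki-Chin factorization.  This
#' exposes the pure discretization error of each factorization free of
#' Monte Carlo noise; it is the oracle behind the \eqn{P^{-2}} vs
#' \eqn{P^{-4}} convergence checks and validates the PIMC estimators at
#' matching \eqn{P}.
#'
#' \eqn{\Delta H} uses a five-point stencil on
#' \eqn{G(u)}, distributing \eqn{u} uniformly over the imaginary-time
#' steps of each half polymer; \eqn{C_{ff}/C_{dd}} uses the discrete
#' velocity correlator
#' \eqn{-\langle (x_{P-1} - x_1)(x_{P/2-1} - x_{P/2+1})\rangle /
#' (2\hbar\varepsilon)^2}.
#'
#' @inheritParams qi_grid_quantities
#' @param P Trotter number (even; divisible by 4 for Suzuki-Chin).
#' @param factorization `"lie-trotter"` or `"suzuki-chin"`.
#' @return list with `cdd`, `cff_over_cdd`, `dH`, `k_qr`, `kappa`.
#' @export
qi_finite_p <- function(surface, state, xi_a, xi_b, P,
                        factorization = c("lie-trotter", "suzuki-chin"),
                        L = NULL, n = 400) {
  factorization <- match.arg(factorization)
  stopifnot(surface$dim == 1, P %% 2 == 0)
  if (factorization == "suzuki-chin" && P %% 4 != 0)
    stop("suzuki-chin with pinned beads requires P divisible by 4",
         call. = FALSE)
  beta <- state$beta; m <- surface$masses[1]
  a <- surface$meta$a %||% 1
  if (is.null(L)) L <- max(8 * a, 4 * sqrt(beta / m))
  x <- seq(-L, L, length.out = n); dx <- x[2] - x[1]
  V <- vapply(x, surface$energy, numeric(1))
  Vp <- vapply(x, function(z) surface_gradient(surface, z)[1], numeric(1))
  eps <- beta / P
  ns <- P / 2                               # slices per half polymer
  sc <- factorization == "suzuki-chin"
  # per-bead action weights: interior beads of each half (index j within
  # the half; parity is the global parity since P/2 is even for SC) and
  # the pinned beads (full weight, split between the two adjoining halves)
  uw <- function(epsh, odd) {
    if (!sc) return(epsh * V)
    if (odd) (4 / 3) * epsh * V + (epsh^3 / 9) * Vp^2 / m
    else (2 / 3) * epsh * V
  }
  half_chain <- function(epsh, with_x = FALSE) {
    K <- sqrt(m / (2 * pi * epsh)) *
      exp(-m * outer(x, x, "-")^2 / (2 * epsh)) * dx
    d_odd <- exp(-uw(epsh, TRUE))
    d_even <- exp(-uw(epsh, FALSE))
    DoK <- d_odd * K; DeK <- d_even * K     # diag(d) %*% K
    # chain: K (D1 K)(D2 K)...(D_{ns-1} K); bead ns-1 is odd (ns even
    # for SC), interior run D1..D_{ns-2} alternates odd/even
    mid <- if (!sc) .mat_pow(DoK, ns - 2)
           else .mat_pow(DoK %*% DeK, (ns - 2) %/% 2)
    last <- DoK
    W <- K %*% mid %*% last
    if (!with_x) return(list(W = W))
    X <- diag(x)
    list(W = W,
         N1 = K %*% X %*% mid %*% last,      # x at bead 1
         N2 = K %*% mid %*% X %*% last,      # x at bead ns-1
         mid = mid, K = K, last = last, X = X)
  }
  ia <- which.min(abs(x - xi_a)); ib <- which.min(abs(x - xi_b))
  pin_w <- function(epsh, xi) {
    # full bead weight at a pin (even bead for SC)
    vv <- surface$energy(xi)
    if (!sc) exp(-epsh * vv) else exp(-(2 / 3) * epsh * vv)
  }
  # G(u): first half at eps1 = (beta/2 - u)/ns, second at eps2
  Gu <- function(u) {
    e1 <- (beta / 2 - u) / ns; e2 <- (beta / 2 + u) / ns
    W1 <- half_chain(e1)$W; W2 <- half_chain(e2)$W
    # each pin receives half its bead weight from each adjoining half
    W1[ia, ib] * W2[ib, ia] / dx^2 *
      pin_w(e1, xi_a)^0.5 * pin_w(e2, xi_a)^0.5 *
      pin_w(e1, xi_b)^0.5 * pin_w(e2, xi_b)^0.5
  }
  G0 <- Gu(0)
  du <- beta / 40
  G2 <- (-Gu(2 * du) + 16 * Gu(du) - 30 * G0 + 16 * Gu(-du) -
           Gu(-2 * du)) / (12 * du^2)
  dH <- sqrt(max(G2 / (2 * G0), 0))
  # velocity correlator from the beads adjacent to the pins; the two
  # halves are independent open chains given the pins, and share the same
  # transfer matrices (weights depend on parity only)
  hc <- half_chain(eps, with_x = TRUE)
  N12 <- hc$K %*% hc$X %*% hc$mid %*% hc$X %*% hc$last
  W1 <- hc$W[ia, ib];  W2 <- hc$W[ib, ia]
  m1 <- hc$N1[ia, ib] / W1    # <x_1>         (half 1: a -> b)
  m2 <- hc$N2[ia, ib] / W1    # <x_{P/2-1}>
  m3 <- hc$N1[ib, ia] / W2    # <x_{P/2+1}>   (half 2: b -> a)
  m4 <- hc$N2[ib, ia] / W2    # <x_{P-1}>
  xx1 <- N12[ia, ib] / W1     # <x_1 x_{P/2-1}>
  xx2 <- N12[ib, ia] / W2     # <x_{P/2+1} x_{P-1}>
  # <(x_{P-1} - x_1)(x_{P/2-1} - x_{P/2+1})>; cross-half terms factorize
  prod_mean <- m4 * m2 - xx2 - xx1 + m1 * m3
  cff_over_cdd <- -prod_mean / (2 * eps)^2
  cdd <- G0
  k_qr <- sqrt(pi) / (2 * dH) * cff_over_cdd * cdd
  Vb <- max(V)
  kappa <- k_qr / exp(-log(2 * pi * beta) - beta * Vb)
  list(cdd = cdd, cff_over_cdd = cff_over_cdd, dH = dH, k_qr = k_qr,
       kappa = kappa, P = P, factorization = factorization)
}

#' Discrete harmonic-oscillator partition function (exact determinant)
#'
#' The \eqn{P}-bead partition function of a harmonic oscillator is a
#' Gaussian integral evaluated here in closed form,
#' \eqn{Q_P = (m/\varepsilon)^{P/2} \det(A)^{-1/2}} with \eqn{A} the
#' cyclic spring matrix plus the factorization's diagonal bead weights.
#' Because no spatial grid is involved, the deviation from the continuum
#' \eqn{Q = [2\sinh(\beta\hbar\omega/2)]^{-1}} is purely the
#' factorization's discretization error: \eqn{O(P^{-2})} for Lie-Trotter
#' and \eqn{O(P^{-4})} for Suzuki-Chin.
#'
#' @param omega,m oscillator frequency and mass.
#' @param beta inverse temperature.
#' @param P Trotter number (even for Suzuki-Chin).
#' @param factorization `"lie-trotter"` or `"suzuki-chin"`.
#' @return the discrete partition function.
#' @export
harmonic_q_discrete <- function(omega, m, beta, P,
                                factorization = c("lie-trotter",
                                                  "suzuki-chin")) {
  factorization <- match.arg(factorization)
  eps <- beta / P
  i <- 0:(P - 1)
  if (factorization == "lie-trotter") {
    w <- rep(1, P); d <- rep(0, P)
  } else {
    if (P %% 2 != 0) stop("suzuki-chin needs even P", call. = FALSE)
    w <- ifelse(i %% 2 == 1, 4 / 3, 2 / 3)
    d <- ifelse(i %% 2 == 1, 1 / 9, 0)
  }
  # bead potential u_i = w_i eps (m w^2/2) x^2 + d_i eps^3 (m w^4) x^2
  cdiag <- 2 * m / eps + w * eps * m * omega^2 +
    2 * d * eps^3 * m * omega^4
  A <- matrix(0, P, P)
  diag(A) <- cdiag
  ip <- c(2:P, 1)
  A[cbind(1:P, ip)] <- A[cbind(1:P, ip)] - m / eps
  A[cbind(ip, 1:P)] <- A[cbind(ip, 1:P)] - m / eps
  ev <- eigen(A, symmetric = TRUE, only.values = TRUE)$values
  exp(0.5 * P * log(m / eps) - 0.5 * sum(log(ev)))
}
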