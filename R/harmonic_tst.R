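
# Classical Eyring TST with harmonic/rigid-rotor partition functions, the
# Wigner shallow-tunneling correction, crossover temperature, effective
# (ZPE-corrected) barriers and KIE bookkeeping.

#' Rate result container
#'
#' @param k rate constant.  For 1-D scattering systems the stored value is
#'   the flux \eqn{k\,Q_r} with the reactant normalized per unit length,
#'   which is the convention in which tunneling corrections and KIEs are
#'   dimensionless.
#' @param kappa tunneling correction \eqn{k/k_{TST}}.
#' @param method one of `"eyring"`, `"wigner"`, `"sci"`, `"qi"`, `"exact"`.
#' @param stat_error statistical standard error (0 for deterministic
#'   methods).
#' @param components optional named list of partition-function factors
#'   (`trans`, `rot`, `vib`, `exp_action`) used by [kie_decomposition()].
#' @param log_k optionally, \eqn{\log k} carried for deep-tunneling
#'   magnitudes.
#' @return object of class `rate_result`.
#' @export
rate_result <- function(k, kappa = 1, method = "eyring", stat_error = 0,
                        components = NULL, log_k = NULL) {
  if (!is.na(k) && k <= 0) stop("rate must be > 0", call. = FALSE)
  structure(list(k = k, kappa = kappa, method = method,
                 stat_error = stat_error, components = components,
                 log_k = log_k %||% log(k)),
            class = "rate_result")
}

#' @export
print.rate_result <- function(x, ...) {
  cat(sprintf("<rate_result> method = %s, k = %.6g, kappa = %.6g%s\n",
              x$method, x$k, x$kappa,
              if (x$stat_error > 0) sprintf(" (+/- %.2g)", x$stat_error)
              else ""))
  invisible(x)
}

#' Crossover temperature
#'
#' \eqn{T_c = \hbar\bar\omega / (2\pi k_B)} with \eqn{\bar\omega} the
#' magnitude of the barrier's imaginary frequency.  Below \eqn{T_c} deep
#' tunneling dominates and the semiclassical instanton exists.
#'
#' @param omega_bar barrier frequency magnitude (> 0).  In reduced units a
#'   frequency; with `energy_unit = "cm-1"` a wavenumber.
#' @param energy_unit `"reduced"` (returns a reduced temperature) or
#'   `"cm-1"` (returns kelvin via the second radiation constant).
#' @return crossover temperature.
#' @export
#' @examples
#' crossover_temperature(1463, "cm-1")   # ~ 335 K
crossover_temperature <- function(omega_bar, energy_unit = "reduced") {
  if (!is.numeric(omega_bar) || any(omega_bar <= 0))
    stop("omega_bar must be > 0", call. = FALSE)
  switch(energy_unit,
         "reduced" = omega_bar / (2 * pi),
         "cm-1" = omega_bar * kinst_constants$c2_cm_K / (2 * pi),
         stop("energy_unit must be 'reduced' or 'cm-1'", call. = FALSE))
}

#' Wigner tunneling correction
#'
#' \eqn{\kappa = 1 + (\hbar\beta\bar\omega)^2/24}: the leading shallow
#' tunneling correction multiplying the Eyring rate, exact to
#' \eqn{O(\beta^2)} against the full quantum correction of a smooth
#' barrier.
#'
#' @param omega_bar barrier frequency magnitude (> 0).
#' @param state a [thermal_state()] (its `beta` must be expressed in units
#'   consistent with `omega_bar`).
#' @return \eqn{\kappa \ge 1}.
#' @export
wigner_correction <- function(omega_bar, state) {
  if (any(omega_bar <= 0)) stop("omega_bar must be > 0", call. = FALSE)
  1 + (state$beta * omega_bar)^2 / 24
}

.q_vib_quantum <- function(omegas, beta) {
  # harmonic quantum vibrational partition function, ZPE measured from the
  # local potential minimum
  prod(1 / (2 * sinh(beta * omegas / 2)))
}

#' Eyring transition-state-theory rate
#'
#' \deqn{k_{TST} = \frac{1}{2\pi\hbar\beta}\,\frac{Q^\ddagger}{Q_r}\,
#'   e^{-\beta V^\ddagger}}
#' with harmonic quantum vibrational partition functions (measured from
#' each stationary point), classical rigid-rotor rotation (optional,
#' via user-supplied moments of inertia and symmetry numbers in
#' `rot_reactant` / `rot_ts`), and classical translation.  For a 1-D
#' scattering system the reactant is a free particle normalized per unit
#' length, so the returned `k` is the flux \eqn{k\,Q_r =
#' (2\pi\hbar\beta)^{-1} e^{-\beta V^\ddagger}} and tunneling corrections
#' against it are the dimensionless table convention.
#'
#' @param reactant a `stationary_point` (all modes real), or `NULL` for a
#'   free 1-D reactant.
#' @param ts a `stationary_point` classified as a first-order saddle.
#' @param state a [thermal_state()].
#' @param surface the surface (for masses).
#' @param wigner multiply by the Wigner correction.
#' @param rot_reactant,rot_ts optional lists `list(inertia =, sigma =)`
#'   for classical rigid-rotor factors.
#' @return a `rate_result` with partition-function `components`.
#' @export
eyring_rate <- function(reactant = NULL, ts, state, surface,
                        wigner = FALSE, rot_reactant = NULL,
                        rot_ts = NULL) {
  if (!inherits(ts, "stationary_point") || ts$type != "saddle")
    stop("invalid transition state: need a first-order saddle",
         call. = FALSE)
  beta <- state$beta
  ev <- ts$hessian_eigenvalues
  omega_bar <- sqrt(-min(ev))
  w_ts <- sqrt(ev[ev > sqrt(.Machine$double.eps)])
  q_vib_ts <- .q_vib_quantum(w_ts, beta)
  if (is.null(reactant)) {
    # free 1-D (or separable with asymptotically free reaction coordinate):
    # reactant per unit length; transverse modes must be supplied through
    # `reactant` for multi-D surfaces, so here dim must be 1
    q_vib_r <- 1
    Vb <- ts$energy
  } else {
    if (any(reactant$hessian_eigenvalues < 0))
      stop("reactant has imaginary modes", call. = FALSE)
    q_vib_r <- .q_vib_quantum(sqrt(reactant$hessian_eigenvalues), beta)
    Vb <- ts$energy - reactant$energy
  }
  q_rot <- function(rot) {
    if (is.null(rot)) return(1)
    inertia <- rot$inertia; sigma <- rot$sigma %||% 1
    if (length(inertia) == 1) return(2 * inertia / (beta * sigma))
    sqrt(pi * prod(2 * inertia / beta)) / sigma
  }
  comp <- list(trans = 1, rot = q_rot(rot_ts) / q_rot(rot_reactant),
               vib = q_vib_ts / q_vib_r, exp_action = exp(-beta * Vb))
  k <- (1 / (2 * pi * beta)) * comp$trans * comp$rot * comp$vib *
    comp$exp_action
  kap <- 1
  meth <- "eyring"
  if (wigner) {
    kap <- wigner_correction(omega_bar, state)
    k <- k * kap
    meth <- "wigner"
  }
  rate_result(k = k, kappa = kap, method = meth, components = comp)
}

#' Effective (zero-point-corrected) barrier
#'
#' Bare barrier plus the difference of harmonic zero-point energies
#' between transition state and reactant minimum:
#' \eqn{V_{eff} = V^\ddagger + ZPE(TS) - ZPE(min)}.  This is the quantity
#' controlling Eyring rates and tunneling-splitting magnitudes.
#'
#' @param barrier bare barrier height (e.g. cm\eqn{^{-1}}).
#' @param zpe_min zero-point energy at the reactant minimum.
#' @param zpe_ts zero-point energy at the transition state (transferring
#'   mode excluded).
#' @return effective barrier in the input unit.
#' @export
#' @examples
#' effective_barrier(1517, 14255, 12970)   # 232
#' effective_barrier(1430, 14853, 13980)   # 557
effective_barrier <- function(barrier, zpe_min, zpe_ts) {
  if (any(c(barrier, zpe_min, zpe_ts) < 0))
    stop("all entries must be >= 0", call. = FALSE)
  barrier + zpe_ts - zpe_min
}

#' Translational KIE factor from masses
#'
#' For a bimolecular reaction X + M the translational contribution to the
#' KIE of substituting X (mass `m_light`) by its isotope (mass `m_heavy`)
#' is \eqn{(\mu_{heavy}/\mu_{light})^{3/2}} with \eqn{\mu} the reduced
#' mass against the unchanged partner M; it is temperature independent.
#'
#' @param m_light,m_heavy isotope masses.
#' @param m_partner mass of the unchanged reaction partner.
#' @param d dimensionality of the relative translation (3 for gas phase).
#' @return dimensionless factor.
#' @export
#' @examples
#' kie_translation_factor(1.008, 2.014, 16.043)   # ~ 2.59 (H/D + CH4)
kie_translation_factor <- function(m_light, m_heavy, m_partner, d = 3) {
  .check_pos(m_light = m_light, m_heavy = m_heavy, m_partner = m_partner)
  mu_l <- m_light * m_partner / (m_light + m_partner)
  mu_h <- m_heavy * m_partner / (m_heavy + m_partner)
  (mu_h / mu_l)^(d / 2)
}

#' Multiplicative KIE decomposition
#'
#' Splits the KIE \eqn{k_A/k_B} into translational, rotational,
#' vibrational and exponential-action factors from the per-factor
#' partition-function components of two rate results; the product of the
#' four factors equals the total KIE to round-off.
#'
#' @param result_A,result_B `rate_result` objects carrying `components`
#'   (light isotopologue first).
#' @return object of class `kie_breakdown`: factors `trans`, `rot`,
#'   `vib`, `exp_action` and `total`.
#' @export
kie_decomposition <- function(result_A, result_B) {
  for (r in list(result_A, result_B))
    if (is.null(r$components))
      stop("incomplete result: per-factor components missing",
           call. = FALSE)
  f <- lapply(c("trans", "rot", "vib", "exp_action"), function(nm) {
    ca <- result_A$components[[nm]]; cb <- result_B$components[[nm]]
    if (is.null(ca) || is.null(cb))
      stop("incomplete result: component `", nm, "` missing", call. = FALSE)
    ca / cb
  })
  names(f) <- c("trans", "rot", "vib", "exp_action")
  structure(c(f, list(total = f$trans * f$rot * f$vib * f$exp_action)),
            class = "kie_breakdown")
}

#' @export
print.kie_breakdown <- function(x, ...) {
  cat(sprintf(
    "<kie_breakdown> trans %.3g x rot %.3g x vib %.3g x exp %.3g = %.4g\n",
    x$trans, x$rot, x$vib, x$exp_action, x$total))
  invisible(x)
}

#' KIE from activation free energies
#'
#' \eqn{k_A/k_B = e^{-\beta(\Delta F_A^\ddagger - \Delta F_B^\ddagger)}}.
#'
#' @param dF_A,dF_B activation free energies (consistent energy unit,
#'   matching `state$energy_unit`).
#' @param state a [thermal_state()].
#' @return dimensionless KIE.
#' @export
#' @examples
#' st <- thermal_state(300, energy_unit = "kcal/mol")
#' kie_from_free_energies(1.018, 2.293, st)   # ~ 8.48
kie_from_free_energies <- function(dF_A, dF_B, state) {
  exp(-state$beta * (dF_A - dF_B))
}

#' Zero-point-energy-corrected potential profile
#'
#' Tabulates \eqn{V_{corr}(x) = V(x) + \sum_i \hbar\omega_i(x)/2} over a
#' grid of the reaction coordinate, summing the transverse harmonic
#' zero-point energies and excluding the reaction-coordinate mode itself.
#' Grid points where a transverse frequency comes out imaginary are kept
#' in the table and flagged, not silently dropped.
#'
#' @param surface a separable surface from [make_separable()], or a 2-D
#'   surface (transverse curvature from the Hessian component orthogonal
#'   to `coord`).
#' @param grid numeric vector of reaction-coordinate values (1-D grid) or
#'   a data.frame of grid points for 2-D surfaces.
#' @param coord index of the reaction coordinate (2-D case).
#' @return data.frame with columns `x` (or the 2-D coordinates), `V`,
#'   `zpe`, `V_corrected`, `flagged`.
#' @export
zpe_corrected_profile <- function(surface, grid, coord = 1) {
  if (identical(surface$meta$model, "separable")) {
    modes <- surface$meta$modes
    base <- surface$meta$base
    rows <- lapply(grid, function(x) {
      w <- vapply(modes, function(md) md$omega(x), numeric(1))
      flagged <- any(w <= 0)          # negative omega = imaginary mode
      zpe <- sum(w[w > 0]) / 2
      V <- base$energy(x)
      data.frame(x = x, V = V, zpe = zpe, V_corrected = V + zpe,
                 flagged = flagged)
    })
    return(do.call(rbind, rows))
  }
  if (surface$dim == 2) {
    stopifnot(is.data.frame(grid), ncol(grid) == 2)
    tv <- 3 - coord
    rows <- lapply(seq_len(nrow(grid)), function(i) {
      z <- as.numeric(grid[i, ])
      H <- surface_hessian(surface, z)
      c_t <- H[tv, tv]                 # transverse curvature
      flagged <- c_t <= 0
      w <- sqrt(max(c_t, 0) / surface$masses[tv])
      V <- surface$energy(z)
      cbind(grid[i, , drop = FALSE],
            data.frame(V = V, zpe = w / 2, V_corrected = V + w / 2,
                       flagged = flagged))
    })
    return(do.call(rbind, rows))
  }
  stop("zpe_corrected_profile needs a separable or 2-D surface",
       call. = FALSE)
}
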