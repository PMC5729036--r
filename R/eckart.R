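
# Closed-form physics of the symmetric Eckart barrier in the dimensionless
# (alpha, b = beta/beta_c) parametrization, with V0 = m = 1 implied:
# the thermal tunneling correction kappa = k/k_TST depends on (alpha, b)
# only, and mass doubling maps (alpha, b) -> (sqrt(2) alpha, b/sqrt(2))
# at fixed physical beta.

#' Eckart transmission probability
#'
#' \deqn{P(\epsilon) = \frac{\cosh(2\alpha\sqrt\epsilon) - 1}
#'   {\cosh(2\alpha\sqrt\epsilon) + \cosh\sqrt{4\alpha^2 - \pi^2}}}
#' with \eqn{\epsilon = E/V_0} the reduced energy.  Valid for
#' \eqn{\alpha > \pi/2}; computed in log space so that \eqn{\alpha
#' \sqrt\epsilon} of several hundred does not overflow.
#'
#' @param eps reduced energies (>= 0), vectorized.
#' @param alpha dimensionless quantumness (> pi/2).
#' @param log return \eqn{\log P} instead of \eqn{P}.
#' @return transmission probabilities in `[0, 1)`.
#' @export
#' @examples
#' eckart_transmission(1, 12)       # at the barrier top
eckart_transmission <- function(eps, alpha, log = FALSE) {
  if (alpha <= pi / 2)
    stop("unsupported regime: alpha must exceed pi/2", call. = FALSE)
  if (any(eps < 0)) stop("eps must be >= 0", call. = FALSE)
  cc <- 2 * alpha * sqrt(eps)
  d <- sqrt(4 * alpha^2 - pi^2)
  M <- pmax(cc, d)
  lnum <- log(exp(cc - M) + exp(-cc - M) - 2 * exp(-M))
  lden <- log(exp(cc - M) + exp(-cc - M) + exp(d - M) + exp(-d - M))
  lp <- ifelse(eps == 0, -Inf, lnum - lden)
  if (log) lp else exp(lp)
}

#' Exact quantum tunneling correction for the Eckart barrier
#'
#' Boltzmann integration of the analytic transmission probability over the
#' one-dimensional classical TST flux:
#' \deqn{\kappa(\alpha, b) = \beta V_0\, e^{\beta V_0} \int_0^\infty
#'   P(\epsilon)\, e^{-\beta V_0 \epsilon}\, d\epsilon, \qquad
#'   \beta V_0 = b\,\alpha.}
#' Quadrature runs in the variable \eqn{u = \sqrt\epsilon} with the
#' integrand rescaled by its peak value, so deep-tunneling corrections of
#' order \eqn{10^{32}} are evaluated without overflow.
#'
#' @param alpha quantumness (> pi/2).
#' @param b reduced inverse temperature \eqn{\beta/\beta_c} (> 0),
#'   vectorized.
#' @param rel_tol quadrature tolerance; the result is additionally checked
#'   against a half-tolerance pass and an error is raised if the two
#'   disagree by more than `10 * rel_tol`.
#' @param log return \eqn{\log\kappa}.
#' @return tunneling correction \eqn{\kappa \ge 1}.
#' @export
#' @examples
#' eckart_kappa_exact(12, 1)        # ~ 6.16
eckart_kappa_exact <- function(alpha, b, rel_tol = 1e-10, log = FALSE) {
  one <- function(b1) {
    bv <- b1 * alpha
    lnf <- function(u) log(2 * u) + eckart_transmission(u^2, alpha,
                                                        log = TRUE) - bv * u^2
    # locate the integrand peak on a coarse log grid (near u = 1/b in the
    # deep-tunneling regime, near u ~ 1/sqrt(bv) classically)
    ug <- exp(seq(log(1e-4), log(10 * (1 / b1 + 1 / sqrt(bv) + 1)),
                  length.out = 300))
    lg <- vapply(ug, lnf, numeric(1))
    us <- ug[which.max(lg)]
    M <- max(lg)
    f <- function(u) exp(lnf(u) - M)
    quad <- function(tol) {
      integrate(f, 0, us, rel.tol = tol, subdivisions = 400L)$value +
        integrate(f, us, Inf, rel.tol = tol, subdivisions = 400L)$value
    }
    I <- quad(rel_tol)
    I2 <- quad(rel_tol * 2)
    if (abs(I - I2) > 10 * rel_tol * abs(I))
      stop(sprintf("quadrature accuracy %.2e not reached", abs(I / I2 - 1)),
           call. = FALSE)
    log(bv) + bv + M + log(I)
  }
  lk <- vapply(b, one, numeric(1))
  if (log) lk else exp(lk)
}

#' Exact mass-doubling KIE for the Eckart barrier
#'
#' Doubling the particle mass without changing \eqn{V(x)} scales
#' \eqn{\alpha \to \sqrt2\,\alpha} and \eqn{\beta_c \to \sqrt2\,\beta_c};
#' at fixed physical \eqn{\beta} the heavy system sits at reduced inverse
#' temperature \eqn{b/\sqrt2}.  The KIE is
#' \deqn{\mathrm{KIE} = \sqrt2\; \frac{\kappa(\alpha, b)}
#'   {\kappa(\sqrt2\,\alpha,\, b/\sqrt2)},}
#' where \eqn{\sqrt2} is the classical 1-D TST mass factor (free-particle
#' reactant partition function per unit length scales as \eqn{\sqrt m}).
#'
#' @inheritParams eckart_kappa_exact
#' @param mass_factor ratio \eqn{m_{heavy}/m_{light}} (default 2).
#' @return the kinetic isotope effect (> 1 for normal mass ordering).
#' @export
#' @examples
#' eckart_kie_exact(12, 1)          # ~ 3.48
eckart_kie_exact <- function(alpha, b, mass_factor = 2, rel_tol = 1e-10) {
  s <- sqrt(mass_factor)
  exp(0.5 * log(mass_factor) +
        eckart_kappa_exact(alpha, b, rel_tol, log = TRUE) -
        eckart_kappa_exact(s * alpha, b / s, rel_tol, log = TRUE))
}

#' Closed-form semiclassical instanton correction for the Eckart barrier
#'
#' Steepest-descent evaluation of the thermal rate over the semiclassical
#' transmission \eqn{P_{sc} = e^{-W(E)/\hbar}} with the Eckart abbreviated
#' action \eqn{W(E)/\hbar = 2\alpha(1 - \sqrt\epsilon)} gives, for
#' \eqn{T < T_c} (i.e. \eqn{b > 1}),
#' \deqn{\kappa_{SCI}(\alpha, b) = 2\sqrt{\pi\alpha/b}\;
#'   e^{\alpha(b + 1/b - 2)}.}
#' Used as the independent oracle for the numerical ring-polymer instanton.
#'
#' @inheritParams eckart_kappa_exact
#' @param log return the logarithm.
#' @return \eqn{\kappa_{SCI}}; `NA` with a warning for `b <= 1` (the
#'   instanton does not exist above crossover).
#' @export
sci_kappa_eckart <- function(alpha, b, log = FALSE) {
  lk <- ifelse(b > 1,
               log(2) + 0.5 * (log(pi) + log(alpha) - log(b)) +
                 alpha * (b + 1 / b - 2),
               NA_real_)
  if (anyNA(lk)) warning("SCI undefined at or above crossover (b <= 1)")
  if (log) lk else exp(lk)
}

#' @rdname sci_kappa_eckart
#' @param mass_factor isotope mass ratio.
#' @export
sci_kie_eckart <- function(alpha, b, mass_factor = 2) {
  s <- sqrt(mass_factor)
  exp(0.5 * log(mass_factor) + sci_kappa_eckart(alpha, b, log = TRUE) -
        sci_kappa_eckart(s * alpha, b / s, log = TRUE))
}
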