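
# Quantum-instanton thermal rates and direct KIE ratios by path-integral
# Monte Carlo.  The rate uses only zero-time information:
#   k Qr = sqrt(pi) hbar Cff(0) / (2 dH),
# with the dividing surfaces at the stationary point of Cdd(0).  Absolute
# Cdd(0) is anchored to its free-particle closed form by thermodynamic
# integration in the potential-switching parameter lambda; isotope ratios
# of Cdd(0) and Qr come from thermodynamic integration over mass.

.block_stats <- function(x, nblocks = 25) {
  n <- length(x)
  nblocks <- min(nblocks, n)
  bs <- floor(n / nblocks)
  if (bs < 1) stop("too few samples for blocking", call. = FALSE)
  bm <- vapply(seq_len(nblocks), function(b)
    mean(x[((b - 1) * bs + 1):(b * bs)]), numeric(1))
  list(mean = mean(bm), se = sd(bm) / sqrt(nblocks), nblocks = nblocks)
}

.surface_kernel <- function(surface) {
  k <- surface$kernel
  if (is.null(k))
    stop("PIMC sampling needs a built-in kernel surface ",
         "(eckart / harmonic / double well / free)", call. = FALSE)
  k
}

#' Sample constrained or closed ring-polymer path ensembles
#'
#' Runs the compiled staging PIMC sampler on a built-in 1-D surface and
#' returns per-sweep estimator accumulations.  In the `"pinned"` topology
#' beads 0 and P/2 are frozen at the two dividing surfaces (the
#' delta-delta constrained ensemble); `"closed"` samples the unconstrained
#' cyclic polymer.  Identical seeds give bit-identical streams.
#'
#' @param surface a built-in kernel `potential_surface` (or `kernel =
#'   list(code = 0)` for a free particle).
#' @param state a [thermal_state()].
#' @param P Trotter number (beads); even, and divisible by 4 for
#'   Suzuki-Chin with pins.
#' @param sweeps production sweeps; each sweep proposes staging moves
#'   covering every free bead once on average.
#' @param burn equilibration sweeps (discarded), with acceptance
#'   auto-tuning of the staging segment length.
#' @param seed integer RNG seed (determinism contract).
#' @param topology `"pinned"` or `"closed"`.
#' @param xi_a,xi_b pinned bead positions (pinned topology) or the
#'   initial bead location (closed).
#' @param factorization `"lie-trotter"` or `"suzuki-chin"`.
#' @param lambda potential scaling in `[0, 1]` (thermodynamic
#'   integration).
#' @param seg initial staging segment length.
#' @param tune auto-tune `seg` during burn-in.
#' @return object of class `qi_ensemble`: the per-sweep sample matrix and
#'   all controls.  A warning is raised if the tuned acceptance rate
#'   leaves `[0.15, 0.9]`.
#' @export
pimc_sample <- function(surface, state, P, sweeps = 2e4, burn = 2e3,
                        seed = 1, topology = c("pinned", "closed"),
                        xi_a = 0, xi_b = 0,
                        factorization = c("lie-trotter", "suzuki-chin"),
                        lambda = 1, seg = 16, tune = TRUE) {
  topology <- match.arg(topology)
  factorization <- match.arg(factorization)
  if (P < 4 || P %% 2 != 0) stop("P must be even and >= 4", call. = FALSE)
  kern <- .surface_kernel(surface)
  res <- pimc_core(kern$code, as.numeric(kern$params), lambda, as.integer(P),
                   state$beta, surface$masses[1],
                   topology == "pinned", xi_a, xi_b,
                   as.integer(sweeps), as.integer(burn), as.integer(seg),
                   as.numeric(seed), factorization == "suzuki-chin", tune)
  if (!is.na(res$acceptance) &&
      (res$acceptance < 0.15 || res$acceptance > 0.9))
    warning(sprintf("staging acceptance %.2f outside [0.15, 0.9]",
                    res$acceptance))
  structure(list(samples = res$samples, acceptance = res$acceptance,
                 seg = res$seg, eps = res$eps, P = P, beta = state$beta,
                 m = surface$masses[1], topology = topology,
                 xi_a = xi_a, xi_b = xi_b, lambda = lambda,
                 factorization = factorization, seed = seed,
                 surface = surface),
            class = "qi_ensemble")
}

.equilibration_check <- function(x) {
  # two-sample drift test on <V>: first vs second half of the stream
  n <- length(x)
  h1 <- x[1:(n %/% 2)]; h2 <- x[(n %/% 2 + 1):n]
  s1 <- .block_stats(h1, 20); s2 <- .block_stats(h2, 20)
  drift <- abs(s1$mean - s2$mean) / sqrt(s1$se^2 + s2$se^2 + 1e-300)
  drift < 5
}

#' Estimate quantum-instanton quantities from a pinned ensemble
#'
#' Computes \eqn{C_{ff}(0)/C_{dd}(0)} from the discrete velocity
#' correlator of the beads adjacent to the pins, and \eqn{\Delta H} from
#' the imaginary-time-displacement derivative of the delta-delta
#' correlation function:
#' \deqn{\Delta H^2 = \frac{\hbar^2}{2}\Big(\frac{2}{P}\Big)^2
#'   \left[\langle (E_1 - E_2)^2 \rangle - \Big\langle \sum_i
#'   \frac{de_i}{d\varepsilon} \Big\rangle\right],}
#' where \eqn{E_{1,2}} are the thermodynamic energy estimators of the two
#' half polymers.  All errors are blocked standard errors with at least
#' 20 blocks.  The `"virial"` estimator switches the average-energy and
#' mass-derivative channels to their virial forms (lower variance at
#' large P); \eqn{\Delta H} itself always uses the thermodynamic form.
#'
#' @param ensemble a pinned [pimc_sample()] result.
#' @param estimator `"thermodynamic"` or `"virial"`.
#' @param nblocks number of error-bar blocks.
#' @return object of class `qi_estimate` with entries `cff_over_cdd`,
#'   `dH`, `avg_V`, `dlnC_dlnm` (mass-derivative estimator), each a
#'   `c(value, se)` pair, plus controls.
#' @export
estimate_qi_quantities <- function(ensemble,
                                   estimator = c("thermodynamic",
                                                 "virial"),
                                   nblocks = 25) {
  estimator <- match.arg(estimator)
  stopifnot(inherits(ensemble, "qi_ensemble"))
  if (ensemble$topology != "pinned")
    stop("QI quantities need the pinned (delta-delta) topology",
         call. = FALSE)
  s <- ensemble$samples
  P <- ensemble$P; eps <- ensemble$eps; m <- ensemble$m
  if (!.equilibration_check(s[, "sumV"]))
    stop("equilibration error: drift test on <V> failed", call. = FALSE)
  nh <- P / 2
  E1 <- nh / (2 * eps) - s[, "spr1"] / (2 * eps^2) + s[, "sv1"]
  E2 <- nh / (2 * eps) - s[, "spr2"] / (2 * eps^2) + s[, "sv2"]
  dEde <- -P / (2 * eps^2) + (s[, "spr1"] + s[, "spr2"]) / eps^3
  h2 <- (2 / P)^2 * ((E1 - E2)^2 - dEde) / 2
  bh <- .block_stats(h2, nblocks)
  dH2 <- bh$mean
  if (dH2 <= 0) stop("non-positive Delta-H^2 estimate; increase sweeps",
                     call. = FALSE)
  dH <- sqrt(dH2)
  dH_se <- bh$se / (2 * dH)
  bv <- .block_stats(-s[, "vprod"] / (2 * eps)^2, nblocks)
  avgV <- .block_stats(s[, "sumV"] / P, nblocks)   # direct either way
  # mass-derivative estimator d ln Cdd / d ln m (virial form for
  # Lie-Trotter only; the Suzuki-Chin gradient term adds +sumG to the
  # thermodynamic form since it scales as 1/m)
  if (estimator == "thermodynamic" ||
      ensemble$factorization == "suzuki-chin") {
    gm <- P / 2 - (s[, "spr1"] + s[, "spr2"]) / (2 * eps)
    if (ensemble$factorization == "suzuki-chin")
      gm <- gm + s[, "sumG"]
  } else {
    dr2 <- P * ((ensemble$xi_b - ensemble$xi_a) / nh)^2
    gm <- 1 - m * dr2 / (2 * eps) + (eps / 2) * s[, "vir"]
  }
  bm <- .block_stats(gm, nblocks)
  structure(list(
    cff_over_cdd = c(value = bv$mean, se = bv$se),
    dH = c(value = dH, se = dH_se),
    avg_V = c(value = avgV$mean, se = avgV$se),
    dlnC_dlnm = c(value = bm$mean, se = bm$se),
    estimator = estimator, P = P, beta = ensemble$beta,
    factorization = ensemble$factorization, seed = ensemble$seed,
    acceptance = ensemble$acceptance, nblocks = bh$nblocks),
    class = "qi_estimate")
}

#' @export
print.qi_estimate <- function(x, ...) {
  cat(sprintf(
    "<qi_estimate> P = %d  Cff/Cdd = %.5g (%.2g)  dH = %.5g (%.2g)\n",
    x$P, x$cff_over_cdd[1], x$cff_over_cdd[2], x$dH[1], x$dH[2]))
  invisible(x)
}

#' Optimize the quantum-instanton dividing surfaces
#'
#' Stochastic (Robbins-Monro) search for the stationary point of the
#' Monte-Carlo-estimated \eqn{C_{dd}(0)} landscape.  For symmetric
#' barriers the search runs along the symmetric stretch
#' \eqn{(\xi_a, \xi_b) = (-\xi, \xi)} with the pin-gradient estimator
#' \eqn{d\ln C_{dd}/d\xi = -\langle \partial U/\partial \xi_b -
#' \partial U/\partial \xi_a\rangle}, projected to \eqn{\xi \ge 0};
#' above crossover the iteration collapses to \eqn{\xi = 0}.
#'
#' @param surface built-in kernel surface.
#' @param state a [thermal_state()].
#' @param P Trotter number.
#' @param iters Robbins-Monro iterations.
#' @param sweeps_per_iter sweeps per gradient estimate.
#' @param seed RNG seed.
#' @param xi0 starting half separation (default: instanton turning-point
#'   estimate below crossover, 0 above).
#' @param symmetric exploit the barrier symmetry (only supported mode).
#' @return list with `xi_a`, `xi_b`, the iteration `trace` and the final
#'   gradient estimate.
#' @export
optimize_dividing_surfaces <- function(surface, state, P = 64,
                                       iters = 30,
                                       sweeps_per_iter = 400, seed = 1,
                                       xi0 = NULL, symmetric = TRUE) {
  if (!symmetric)
    stop("only the symmetric-stretch search is implemented",
         call. = FALSE)
  a <- surface$meta$a %||% 1
  beta <- state$beta
  # barrier frequency from the actual Hessian and masses (metadata may be
  # stale after an isotope substitution)
  curv <- -surface_hessian(surface, 0)[1, 1]
  om <- sqrt(max(curv, 1e-12) / surface$masses[1])
  if (is.null(xi0)) {
    b_eff <- beta * om / (2 * pi)
    xi0 <- if (b_eff > 1) {
      eps_star <- 1 / b_eff^2
      f <- function(x) surface$energy(x) - eps_star * surface$energy(0)
      tryCatch(uniroot(f, c(1e-6, 20 * a))$root, error = function(e) a)
    } else 0.2 * a
  }
  # phase 1: Robbins-Monro ascent with decreasing step
  xi <- xi0
  trace <- NULL
  g <- NA
  for (k in seq_len(iters)) {
    en <- pimc_sample(surface, state, P, sweeps = sweeps_per_iter,
                      burn = max(200, sweeps_per_iter %/% 4),
                      seed = seed + 7 * k, topology = "pinned",
                      xi_a = -xi, xi_b = xi)
    g <- mean(en$samples[, "gpin"])
    step <- 0.25 * a / (1 + k / 6)
    xi_new <- max(xi + step * tanh(g * a / 20), 0)
    trace <- rbind(trace, data.frame(iter = k, xi = xi, grad = g,
                                     phase = 1))
    xi <- xi_new
  }
  xi_hat <- mean(trace$xi[max(1, iters - 9):iters])
  # phase 2: probe the gradient around the coarse estimate and solve the
  # fitted linear model g(xi) = 0 (the stationarity condition)
  probes <- seq(max(xi_hat - 0.5 * a, 0), xi_hat + 0.5 * a,
                length.out = 5)
  gp <- vapply(seq_along(probes), function(i) {
    en <- pimc_sample(surface, state, P, sweeps = 4 * sweeps_per_iter,
                      burn = sweeps_per_iter,
                      seed = seed + 5003 + 13 * i, topology = "pinned",
                      xi_a = -probes[i], xi_b = probes[i])
    mean(en$samples[, "gpin"])
  }, numeric(1))
  trace <- rbind(trace, data.frame(iter = seq_along(probes), xi = probes,
                                   grad = gp, phase = 2))
  fit <- lm(gp ~ probes)
  slope <- coef(fit)[2]
  xi_hat <- if (is.finite(slope) && slope < 0) {
    -coef(fit)[1] / slope                 # root of the descending fit
  } else xi_hat
  xi_hat <- max(min(xi_hat, max(probes) + 0.5 * a), 0)
  if (xi_hat < 0.05 * a) xi_hat <- 0      # collapse to the barrier top
  list(xi_a = -xi_hat, xi_b = xi_hat, trace = trace, grad = g)
}

#' Thermodynamic integration of the absolute delta-delta correlation
#'
#' \eqn{\ln[C_{dd}(0) / C_{dd}^{free}(0)] = -\int_0^1 d\lambda\,
#' \langle dU/d\lambda \rangle_\lambda} by Gauss-Legendre quadrature in
#' the potential-switching parameter, anchored to the analytic
#' free-particle value
#' \eqn{C_{dd}^{free} = (m/\pi\beta\hbar^2)\,
#' e^{-2 m (\xi_b - \xi_a)^2 / (\beta\hbar^2)}}.
#'
#' @inheritParams pimc_sample
#' @param nodes Gauss-Legendre node count.
#' @param sweeps,burn MC controls per node.
#' @return list with `ln_cdd` (log of the absolute \eqn{C_{dd}(0)}),
#'   `se`, and the per-node table.
#' @export
cdd_absolute_ti <- function(surface, state, P, xi_a, xi_b, nodes = 8,
                            sweeps = 2e4, burn = 2e3, seed = 1,
                            factorization = "lie-trotter") {
  gl <- .gauss_legendre01(nodes)
  beta <- state$beta; m <- surface$masses[1]
  eps <- beta / P
  tab <- NULL
  I <- 0; varI <- 0
  for (i in seq_len(nodes)) {
    lam <- gl$x[i]
    en <- pimc_sample(surface, state, P, sweeps = sweeps, burn = burn,
                      seed = seed + 101 * i, topology = "pinned",
                      xi_a = xi_a, xi_b = xi_b,
                      factorization = factorization, lambda = lam)
    s <- en$samples
    if (factorization == "suzuki-chin") {
      dudl <- (s[, "sumUw"] - s[, "sumG"]) / lam + 2 * s[, "sumG"] / lam
    } else {
      dudl <- s[, "sumUw"] / lam
    }
    b <- .block_stats(dudl, 25)
    I <- I + gl$w[i] * b$mean
    varI <- varI + (gl$w[i] * b$se)^2
    tab <- rbind(tab, data.frame(lambda = lam, dUdl = b$mean,
                                 se = b$se))
  }
  ln_free <- log(m / (pi * beta)) - 2 * m * (xi_b - xi_a)^2 / beta
  list(ln_cdd = ln_free - I, se = sqrt(varI), nodes = tab,
       ln_cdd_free = ln_free)
}

.gauss_legendre01 <- function(n) {
  # Golub-Welsch on [-1, 1], mapped to [0, 1]
  if (n == 1) return(list(x = 0.5, w = 1))
  k <- seq_len(n - 1)
  b <- k / sqrt(4 * k^2 - 1)
  J <- matrix(0, n, n)
  J[cbind(k, k + 1)] <- b; J[cbind(k + 1, k)] <- b
  e <- eigen(J, symmetric = TRUE)
  x <- e$values
  w <- 2 * e$vectors[1, ]^2
  ord <- order(x)
  list(x = (x[ord] + 1) / 2, w = w[ord] / 2)
}

#' Partition-function and correlation ratios by mass integration
#'
#' \eqn{\ln[Z(m_B)/Z(m_A)] = \ln(m_B/m_A) \int_0^1 d\lambda\,
#' \langle d\ln Z/d\ln m\rangle_{m(\lambda)}} along the geometric mass
#' path \eqn{m(\lambda) = m_A^{1-\lambda} m_B^{\lambda}}, where `Z` is
#' either the pinned \eqn{C_{dd}(0)} (`target = "cdd"`) or the closed
#' reactant partition function (`target = "qr"`, bound systems).  For a
#' free 1-D reactant the closed form \eqn{(m_B/m_A)^{1/2}} is returned
#' directly.
#'
#' @inheritParams cdd_absolute_ti
#' @param m_A,m_B endpoint masses (> 0).
#' @param target `"cdd"` or `"qr"`.
#' @param estimator `"thermodynamic"` or `"virial"` mass-derivative
#'   estimator.
#' @param free treat the reactant as a free particle (analytic result).
#' @param xi_path optional `c(xi_start, xi_end)`: slide the symmetric
#'   dividing surfaces linearly along the mass path (`target = "cdd"`).
#'   The integrand then carries the explicit pin-motion term
#'   \eqn{(d\xi/d\lambda)\, d\ln C_{dd}/d\xi} from the pin-gradient
#'   estimator, making the integral exact for the sliding path.
#' @return list with `ln_ratio`, `se`, per-node table.
#' @export
mass_ti_ratio <- function(surface, state, m_A, m_B, P, xi_a = 0,
                          xi_b = 0, target = c("cdd", "qr"), nodes = 5,
                          sweeps = 2e4, burn = 2e3, seed = 1,
                          estimator = "thermodynamic", free = FALSE,
                          xi_path = NULL) {
  target <- match.arg(target)
  .check_pos(m_A = m_A, m_B = m_B)
  if (m_A == m_B) return(list(ln_ratio = 0, se = 0, nodes = NULL))
  if (free && target == "qr")
    return(list(ln_ratio = 0.5 * log(m_B / m_A), se = 0, nodes = NULL,
                analytic = TRUE))
  gl <- .gauss_legendre01(nodes)
  lr <- log(m_B / m_A)
  I <- 0; varI <- 0; tab <- NULL
  for (i in seq_len(nodes)) {
    lam <- gl$x[i]
    mm <- m_A^(1 - lam) * m_B^lam
    surf_m <- surface; surf_m$masses <- mm
    xa <- xi_a; xb <- xi_b
    dxi <- 0
    if (!is.null(xi_path) && target == "cdd") {
      # dividing surfaces slide linearly between the two isotopologues'
      # optima; the explicit pin-motion term (dxi/dlambda) d ln Cdd/d xi
      # makes the path integral exact for any smooth pin path
      xi_i <- (1 - lam) * xi_path[1] + lam * xi_path[2]
      xa <- -xi_i; xb <- xi_i
      dxi <- xi_path[2] - xi_path[1]
    }
    en <- pimc_sample(surf_m, state, P, sweeps = sweeps, burn = burn,
                      seed = seed + 211 * i,
                      topology = if (target == "cdd") "pinned"
                                 else "closed",
                      xi_a = xa, xi_b = xb)
    s <- en$samples
    eps <- en$eps
    if (target == "cdd") {
      if (estimator == "virial") {
        dr2 <- P * ((xb - xa) / (P / 2))^2
        g <- lr * (1 - mm * dr2 / (2 * eps) + (eps / 2) * s[, "vir"])
      } else {
        g <- lr * (P / 2 - (s[, "spr1"] + s[, "spr2"]) / (2 * eps))
      }
      if (dxi != 0) g <- g + dxi * s[, "gpin"]
    } else {
      g <- lr * (if (estimator == "virial") 0.5 + (eps / 2) * s[, "vir"]
                 else P / 2 - (s[, "spr1"] + s[, "spr2"]) / (2 * eps))
    }
    b <- .block_stats(g, 25)
    I <- I + gl$w[i] * b$mean
    varI <- varI + (gl$w[i] * b$se)^2
    tab <- rbind(tab, data.frame(lambda = lam, mass = mm,
                                 xi = xb, dlnZ_dlambda = b$mean,
                                 se = b$se))
  }
  list(ln_ratio = I, se = sqrt(varI), nodes = tab)
}

#' Assemble the quantum-instanton rate
#'
#' \deqn{k_{QI}\,Q_r = \frac{\sqrt{\pi}\,\hbar}{2\,\Delta H}\,
#'   \frac{C_{ff}(0)}{C_{dd}(0)}\; C_{dd}(0),}
#' with the pieces supplied as a [estimate_qi_quantities()] result plus
#' the absolute \eqn{\ln C_{dd}} from [cdd_absolute_ti()].  No ad hoc
#' high-temperature correction is applied (the \eqn{\sqrt{\pi/2}}
#' overestimate cancels in KIEs); `high_t_correction = TRUE` divides it
#' out.
#'
#' @param quantities a `qi_estimate`.
#' @param state a [thermal_state()].
#' @param ln_cdd absolute \eqn{\ln C_{dd}(0)} (and `ln_cdd_se`).
#' @param barrier barrier height used for the tunneling-correction
#'   reference flux.
#' @param ln_cdd_se statistical error of `ln_cdd`.
#' @param high_t_correction divide out \eqn{\sqrt{\pi/2}}.
#' @return a `rate_result` (`k` is \eqn{k\,Q_r}; `stat_error` is the
#'   standard error of `k`), `method = "qi"`.
#' @export
qi_rate <- function(quantities, state, ln_cdd, barrier,
                    ln_cdd_se = 0, high_t_correction = FALSE) {
  stopifnot(inherits(quantities, "qi_estimate"))
  beta <- state$beta
  fv <- quantities$cff_over_cdd
  if (fv[1] <= 0)
    stop("incomplete result: non-positive Cff/Cdd", call. = FALSE)
  ln_k <- 0.5 * log(pi) - log(2) - log(quantities$dH[1]) +
    log(fv[1]) + ln_cdd
  if (high_t_correction) ln_k <- ln_k - 0.5 * log(pi / 2)
  rel2 <- (fv[2] / fv[1])^2 + (quantities$dH[2] / quantities$dH[1])^2 +
    ln_cdd_se^2
  ln_ktst <- -log(2 * pi * beta) - beta * barrier
  rate_result(k = exp(ln_k), kappa = exp(ln_k - ln_ktst), method = "qi",
              stat_error = exp(ln_k) * sqrt(rel2), log_k = ln_k)
}

#' Quantum-instanton tunneling correction, end to end
#'
#' Full pipeline on a built-in barrier surface: optimize the dividing
#' surfaces, estimate \eqn{C_{ff}/C_{dd}} and \eqn{\Delta H}, anchor the
#' absolute \eqn{C_{dd}} by potential-switching TI, and assemble
#' \eqn{\kappa_{QI} = k_{QI}/k_{TST}}.
#'
#' @inheritParams pimc_sample
#' @param xi optional fixed half separation of the dividing surfaces
#'   (skips the stochastic optimization).
#' @param ti_nodes Gauss-Legendre nodes for the absolute-\eqn{C_{dd}} TI.
#' @param opt_iters,opt_sweeps dividing-surface search controls.
#' @return a `rate_result` with attributes `xi` and `quantities`.
#' @export
qi_kappa_mc <- function(surface, state, P = 64, sweeps = 5e4,
                        burn = 5e3, seed = 1, xi = NULL, ti_nodes = 8,
                        opt_iters = 25, opt_sweeps = 400) {
  if (is.null(xi)) {
    opt <- optimize_dividing_surfaces(surface, state, P = min(P, 64),
                                      iters = opt_iters,
                                      sweeps_per_iter = opt_sweeps,
                                      seed = seed)
    xi <- opt$xi_b
  }
  en <- pimc_sample(surface, state, P, sweeps = sweeps, burn = burn,
                    seed = seed, topology = "pinned", xi_a = -xi,
                    xi_b = xi)
  q <- estimate_qi_quantities(en)
  ti <- cdd_absolute_ti(surface, state, P, -xi, xi, nodes = ti_nodes,
                        sweeps = max(sweeps %/% 2, 5e3),
                        burn = burn, seed = seed + 5000)
  r <- qi_rate(q, state, ti$ln_cdd, barrier = surface$energy(0),
               ln_cdd_se = ti$se)
  attr(r, "xi") <- xi
  attr(r, "quantities") <- q
  attr(r, "ti") <- ti
  r
}

#' Quantum-instanton kinetic isotope effect (direct ratio route)
#'
#' Computes the KIE of substituting mass `m_A` by `m_B` at fixed
#' \eqn{\beta} as the product of ratios
#' \deqn{\frac{k_A}{k_B} = \frac{Q_r(B)}{Q_r(A)}
#'   \frac{\Delta H(B)}{\Delta H(A)}
#'   \frac{C_{dd}^{(A)}(0)}{C_{dd}^{(B)}(0)}
#'   \frac{C_{ff}^{(A)}(0)/C_{dd}^{(A)}(0)}
#'        {C_{ff}^{(B)}(0)/C_{dd}^{(B)}(0)},}
#' with \eqn{\Delta H} and \eqn{C_{ff}/C_{dd}} from direct constrained
#' sampling of each isotopologue at its own optimized dividing surfaces,
#' the \eqn{C_{dd}} ratio from thermodynamic integration over mass with
#' the surfaces sliding linearly between the two optima (the pin-motion
#' term is integrated explicitly via the pin-gradient estimator),
#' and the free-particle reactant ratio \eqn{\sqrt{m_B/m_A}}.
#' Statistical errors are propagated in quadrature in log space.
#'
#' @inheritParams qi_kappa_mc
#' @param m_A,m_B isotope masses (light, heavy).
#' @param ti_nodes mass-TI nodes.
#' @param xi_A,xi_B optional fixed half separations for the two
#'   isotopologues (skip the stochastic surface searches).
#' @param estimator `"thermodynamic"` or `"virial"` for the
#'   mass-derivative channel of the thermodynamic integration.
#' @return list with `kie`, `se`, and the factor breakdown.
#' @export
qi_kie <- function(surface, state, m_A, m_B, P = 64, sweeps = 5e4,
                   burn = 5e3, seed = 1, xi_A = NULL, xi_B = NULL,
                   ti_nodes = 5, opt_iters = 25, opt_sweeps = 400,
                   estimator = "thermodynamic") {
  surf_A <- surface; surf_A$masses <- m_A
  surf_B <- surface; surf_B$masses <- m_B
  opt_xi <- function(surf, sd) {
    optimize_dividing_surfaces(surf, state, P = min(P, 64),
                               iters = opt_iters,
                               sweeps_per_iter = opt_sweeps,
                               seed = sd)$xi_b
  }
  if (is.null(xi_A)) xi_A <- opt_xi(surf_A, seed)
  if (is.null(xi_B)) xi_B <- opt_xi(surf_B, seed + 101)
  qa <- estimate_qi_quantities(pimc_sample(
    surf_A, state, P, sweeps = sweeps, burn = burn, seed = seed,
    topology = "pinned", xi_a = -xi_A, xi_b = xi_A), estimator)
  qb <- estimate_qi_quantities(pimc_sample(
    surf_B, state, P, sweeps = sweeps, burn = burn, seed = seed + 17,
    topology = "pinned", xi_a = -xi_B, xi_b = xi_B), estimator)
  ti <- mass_ti_ratio(surface, state, m_A, m_B, P, target = "cdd",
                      nodes = ti_nodes, sweeps = sweeps %/% 2,
                      burn = burn, seed = seed + 31,
                      estimator = estimator, xi_path = c(xi_A, xi_B))
  ln_qr <- 0.5 * log(m_B / m_A)          # free 1-D reactant
  ln_kie <- ln_qr + log(qb$dH[1] / qa$dH[1]) - ti$ln_ratio +
    log(qa$cff_over_cdd[1] / qb$cff_over_cdd[1])
  rel2 <- (qa$cff_over_cdd[2] / qa$cff_over_cdd[1])^2 +
    (qb$cff_over_cdd[2] / qb$cff_over_cdd[1])^2 +
    (qa$dH[2] / qa$dH[1])^2 + (qb$dH[2] / qb$dH[1])^2 + ti$se^2
  list(kie = exp(ln_kie), se = exp(ln_kie) * sqrt(rel2),
       xi = c(A = xi_A, B = xi_B),
       factors = list(qr_ratio = exp(ln_qr),
                      dH_ratio = qb$dH[1] / qa$dH[1],
                      cdd_ratio = exp(-ti$ln_ratio),
                      flux_ratio = qa$cff_over_cdd[1] /
                        qb$cff_over_cdd[1]),
       quantities = list(A = qa, B = qb))
}

#' Choose the Trotter number at a target discretization error
#'
#' Uses the deterministic finite-\eqn{P} propagator products
#' ([qi_finite_p()]) to find the smallest `P` (doubling from `P0`) whose
#' tunneling correction differs from the next doubling by less than
#' `tol`.  This isolates the factorization's discretization error from
#' Monte Carlo noise.
#'
#' @inheritParams qi_finite_p
#' @param P0 starting Trotter number.
#' @param tol relative tolerance (default 1%).
#' @param Pmax cap.
#' @return list with `P` and the convergence table.
#' @export
choose_trotter <- function(surface, state, xi_a, xi_b,
                           factorization = "lie-trotter", P0 = 8,
                           tol = 0.01, Pmax = 1024, n = 300) {
  P <- if (factorization == "suzuki-chin") max(P0, 8) else P0
  tab <- NULL
  k_prev <- NULL
  repeat {
    k <- qi_finite_p(surface, state, xi_a, xi_b, P, factorization,
                     n = n)$kappa
    tab <- rbind(tab, data.frame(P = P, kappa = k))
    if (!is.null(k_prev) && abs(k / k_prev - 1) < tol)
      return(list(P = P, record = tab))
    k_prev <- k
    P <- 2 * P
    if (P > Pmax)
      stop("Trotter convergence not reached by P = ", Pmax,
           call. = FALSE)
  }
}
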