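
# Ring-polymer (semiclassical) instanton: discretized Euclidean action,
# saddle-point optimization in the extended bead space, the fluctuation
# determinant rate below crossover, and ground-state tunneling splittings
# from the kink instanton on a linear polymer.

#' Ring-polymer path
#'
#' A cyclic chain of `N` bead configurations discretizing an imaginary
#' time interval \eqn{\beta\hbar} with equal steps
#' \eqn{\eta = \beta\hbar/N}.
#'
#' @param beads numeric vector (1-D) or `N x dim` matrix of bead
#'   positions.
#' @param beta inverse temperature.
#' @return object of class `ring_polymer_path` with fields `beads`, `N`,
#'   `beta`, `eta`; `S` and `hessian_eigenvalues` are attached after
#'   optimization.
#' @export
ring_polymer_path <- function(beads, beta) {
  if (is.null(dim(beads))) beads <- matrix(beads, ncol = 1)
  structure(list(beads = beads, N = nrow(beads), beta = beta,
                 eta = beta / nrow(beads), S = NULL,
                 hessian_eigenvalues = NULL),
            class = "ring_polymer_path")
}

#' @export
print.ring_polymer_path <- function(x, ...) {
  cat(sprintf("<ring_polymer_path> N = %d, beta = %g%s\n", x$N, x$beta,
              if (!is.null(x$S)) sprintf(", S = %.6g", x$S) else ""))
  invisible(x)
}

#' Discretized Euclidean action of a cyclic path
#'
#' \deqn{S = \sum_{i=1}^{N} \left[\sum_d \frac{m_d (z_{i+1,d} -
#'   z_{i,d})^2}{2\eta} + \eta V(z_i)\right], \qquad \eta =
#'   \beta\hbar/N,}
#' with cyclic indexing \eqn{z_{N+1} \equiv z_1}.  `action_gradient()`
#' and `action_hessian()` return the analytic derivatives assembled from
#' the surface derivatives.
#'
#' @param path a [ring_polymer_path()].
#' @param surface a `potential_surface` matching the path dimension.
#' @return the action (energy x time in \eqn{\hbar = 1} units).
#' @export
discretized_action <- function(path, surface) {
  z <- path$beads; eta <- path$eta
  ip <- c(2:path$N, 1)
  spring <- sum(sweep((z[ip, , drop = FALSE] - z)^2, 2, surface$masses,
                      "*")) / (2 * eta)
  pot <- eta * sum(apply(z, 1, surface$energy))
  spring + pot
}

#' @rdname discretized_action
#' @export
action_gradient <- function(path, surface) {
  z <- path$beads; eta <- path$eta; N <- path$N
  ip <- c(2:N, 1); im <- c(N, 1:(N - 1))
  g_spring <- sweep(2 * z - z[ip, , drop = FALSE] - z[im, , drop = FALSE],
                    2, surface$masses, "*") / eta
  g_pot <- t(apply(z, 1, function(x) surface_gradient(surface, x)))
  if (surface$dim == 1) g_pot <- matrix(g_pot, ncol = 1)
  g_spring + eta * g_pot
}

#' @rdname discretized_action
#' @export
action_hessian <- function(path, surface) {
  z <- path$beads; eta <- path$eta; N <- path$N; d <- surface$dim
  n <- N * d                       # bead-major ordering: (bead, dof)
  H <- matrix(0, n, n)
  idx <- function(i, k) (i - 1) * d + k
  for (i in seq_len(N)) {
    ipp <- if (i == N) 1 else i + 1
    Vh <- surface_hessian(surface, z[i, ])
    for (k in seq_len(d)) {
      for (l in seq_len(d))
        H[idx(i, k), idx(i, l)] <- H[idx(i, k), idx(i, l)] + eta * Vh[k, l]
      mk <- surface$masses[k]
      H[idx(i, k), idx(i, k)] <- H[idx(i, k), idx(i, k)] + 2 * mk / eta
      H[idx(i, k), idx(ipp, k)] <- H[idx(i, k), idx(ipp, k)] - mk / eta
      H[idx(ipp, k), idx(i, k)] <- H[idx(ipp, k), idx(i, k)] - mk / eta
    }
  }
  H
}

.instanton_guess <- function(surface, beta, N) {
  # spread beads between the classical turning points of the inverted
  # barrier at the energy whose (parabolic-estimate) period matches beta
  sp <- find_stationary_points(surface,
                             guesses = list(rep(0, surface$dim)))[[1]]
  if (sp$type != "saddle" && surface$dim == 1)
    sp <- find_stationary_points(surface, guesses = c(-0.5, 0, 0.5))[[1]]
  omega_bar <- sp$frequencies[which.min(sp$hessian_eigenvalues)]
  b_eff <- beta * omega_bar / (2 * pi)
  Vsp <- sp$energy
  Estar <- Vsp * min(1 / b_eff^2, 0.9)
  f1 <- function(x) surface$energy(c(x, rep(0, surface$dim - 1))) - Estar
  a_scale <- surface$meta$a %||% 1
  xr <- uniroot(f1, c(sp$x[1] + 1e-8, sp$x[1] + 50 * a_scale))$root
  xl <- uniroot(f1, c(sp$x[1] - 50 * a_scale, sp$x[1] - 1e-8))$root
  mid <- (xr + xl) / 2; amp <- (xr - xl) / 2
  z <- matrix(0, N, surface$dim)
  z[, 1] <- mid + amp * cos(2 * pi * (0:(N - 1)) / N)
  list(z = z, sp = sp, omega_bar = omega_bar)
}

#' Optimize a ring-polymer instanton
#'
#' Newton search for the stationary point of the discretized action in
#' the extended bead space, starting from beads spread along the unstable
#' mode between the classical turning points.  After convergence the
#' eigenvalue signature is verified: exactly one negative eigenvalue and
#' one numerically zero (imaginary-time translation) mode.
#'
#' @param surface a `potential_surface`.
#' @param state a [thermal_state()] with \eqn{T < T_c}.
#' @param N bead count (even).
#' @param guess optional starting bead matrix (e.g. an interpolated
#'   coarser path).
#' @param grad_tol convergence threshold on the action gradient norm.
#' @param max_iter Newton cap.
#' @param zero_mode_tol the translation mode must satisfy
#'   \eqn{|\lambda| <} `zero_mode_tol` \eqn{\times \lambda_{max}}; the
#'   discrete action breaks continuous time translation at \eqn{O(1/N^2)},
#'   so the residual magnitude shrinks with the bead number.
#' @return an optimized `ring_polymer_path` carrying `S`, `S0` (the
#'   abbreviated action \eqn{\oint m\dot x^2 d\tau}),
#'   `hessian_eigenvalues` and the saddle-point data.
#' @export
optimize_instanton <- function(surface, state, N = 256, guess = NULL,
                               grad_tol = 1e-10, max_iter = 200,
                               zero_mode_tol = 1e-5) {
  beta <- state$beta
  stopifnot(N %% 2 == 0)
  gs <- .instanton_guess(surface, beta, N)
  omega_bar <- gs$omega_bar
  Tc <- crossover_temperature(omega_bar)
  if (1 / beta >= Tc) {
    warning(sprintf(
      "T >= Tc (%.4g >= %.4g): instanton collapses; returning the saddle",
      1 / beta, Tc))
    z <- matrix(rep(gs$sp$x, each = N), N, surface$dim)
    p <- ring_polymer_path(z, beta)
    p$S <- discretized_action(p, surface)
    p$S0 <- 0
    p$collapsed <- TRUE
    p$saddle <- gs$sp
    return(p)
  }
  z <- guess %||% gs$z
  if (is.null(dim(z))) z <- matrix(z, ncol = 1)
  p <- ring_polymer_path(z, beta)
  scale_cap <- (surface$meta$a %||% 1) * 0.5
  for (it in seq_len(max_iter)) {
    g <- action_gradient(p, surface)
    gn <- sqrt(sum(g^2))
    if (gn < grad_tol) break
    H <- action_hessian(p, surface)
    step <- tryCatch(solve(H, -as.numeric(t(g))),
                     error = function(e) -as.numeric(t(g)))
    mx <- max(abs(step))
    if (mx > scale_cap) step <- step * scale_cap / mx
    p$beads <- p$beads + matrix(step, p$N, surface$dim, byrow = TRUE)
  }
  if (gn >= grad_tol)
    stop(sprintf("instanton optimization did not converge (|g| = %.2e)",
                 gn), call. = FALSE)
  H <- action_hessian(p, surface)
  lam <- sort(eigen(H, symmetric = TRUE, only.values = TRUE)$values)
  # the time-translation mode is the eigenvalue of smallest magnitude;
  # it must be numerically zero, and exactly one other mode negative
  izero <- which.min(abs(lam))
  thr <- zero_mode_tol * max(abs(lam))
  nneg <- sum(lam[-izero] < 0)
  if (nneg != 1 || abs(lam[izero]) > thr)
    stop(sprintf(
      "saddle-index error: %d negative modes, |zero mode| = %.2e (thr %.2e)",
      nneg, abs(lam[izero]), thr), call. = FALSE)
  ipn <- c(2:p$N, 1)
  p$S <- discretized_action(p, surface)
  p$S0 <- sum(sweep((p$beads[ipn, , drop = FALSE] - p$beads)^2, 2,
                    surface$masses, "*")) / p$eta
  p$hessian_eigenvalues <- lam
  p$zero_mode_threshold <- thr
  p$saddle <- gs$sp
  p$collapsed <- FALSE
  p
}

.q_harm_polymer <- function(omega, m, beta, N) {
  # N-bead discretized harmonic partition function: (m/eta)^{N/2} det^-1/2
  eta <- beta / N
  k <- 0:(N - 1)
  lam <- (m / eta) * (2 - 2 * cos(2 * pi * k / N)) + eta * m * omega^2
  exp(0.5 * N * log(m / eta) - 0.5 * sum(log(lam)))
}

#' Semiclassical instanton rate from an optimized path
#'
#' Steepest-descent rate in the discretized ring-polymer space:
#' \deqn{k\,Q_r = \frac{\ell}{\beta\hbar}\,
#'   \Big(\prod_d \frac{m_d}{\eta}\Big)^{N/2} (2\pi\hbar)^{-1/2}
#'   \,\big|{\det}' \mathbf{S}''\big|^{-1/2}\, e^{-S/\hbar},}
#' where \eqn{\ell = \beta\hbar\,|\dot{\mathbf z}|} is the zero-mode
#' (time-translation) length replacing the single numerically zero
#' eigenvalue, and \eqn{\det'} runs over all other modes with the
#' magnitude of the single negative eigenvalue.  For multi-dimensional
#' separable systems the transverse reactant modes are divided out with
#' the same `N`-bead discretization so that constant transverse
#' frequencies cancel identically.
#'
#' The tunneling correction compares against the classical 1-D TST flux
#' \eqn{(2\pi\hbar\beta)^{-1} e^{-\beta V^\ddagger}}.
#'
#' @param path optimized `ring_polymer_path` (valid signature required).
#' @param surface the surface.
#' @param reactant_omegas transverse harmonic frequencies of the reactant
#'   (default: evaluated from separable-surface mode profiles in the
#'   reactant asymptote; empty for 1-D).
#' @param reactant_x reaction coordinate at which reactant transverse
#'   frequencies are evaluated (separable surfaces).
#' @return a `rate_result` (`k` is \eqn{k\,Q_r} in the per-unit-length
#'   reactant convention, `method = "sci"`) with `components` exposing
#'   the action exponential and vibrational factor for KIE decomposition.
#' @export
instanton_rate <- function(path, surface, reactant_omegas = NULL,
                           reactant_x = NULL) {
  if (isTRUE(path$collapsed))
    stop("collapsed path: instanton rate undefined at T >= Tc",
         call. = FALSE)
  lam <- path$hessian_eigenvalues
  if (is.null(lam)) stop("path is not optimized", call. = FALSE)
  izero <- which.min(abs(lam))
  if (abs(lam[izero]) > path$zero_mode_threshold)
    stop("ill-conditioned prefactor: zero mode magnitude above threshold",
         call. = FALSE)
  beta <- path$beta; eta <- path$eta; N <- path$N
  ipn <- c(2:N, 1)
  dz <- path$beads[ipn, , drop = FALSE] - path$beads
  ell <- beta * sqrt(sum((dz / eta)^2))
  ln_det <- sum(log(abs(lam[-izero])))
  ln_kqr <- log(ell / beta) - 0.5 * log(2 * pi) +
    0.5 * N * sum(log(surface$masses / eta)) - 0.5 * ln_det - path$S
  # transverse reactant modes (same discretization -> exact cancellation
  # for constant transverse frequency)
  if (is.null(reactant_omegas) &&
      identical(surface$meta$model, "separable")) {
    xr <- reactant_x %||% (-50 * (surface$meta$base$meta$a %||% 1))
    reactant_omegas <- vapply(surface$meta$modes,
                              function(md) md$omega(xr), numeric(1))
  }
  if (!is.null(reactant_omegas) && length(reactant_omegas) > 0) {
    mm <- surface$masses[-1]
    for (j in seq_along(reactant_omegas))
      ln_kqr <- ln_kqr - log(.q_harm_polymer(reactant_omegas[j], mm[j],
                                             beta, N))
  }
  Vb <- path$saddle$energy
  ln_ktst <- -log(2 * pi * beta) - beta * Vb
  rate_result(k = exp(ln_kqr), kappa = exp(ln_kqr - ln_ktst),
              method = "sci", log_k = ln_kqr,
              components = list(trans = 1, rot = 1,
                                vib = exp(ln_kqr + path$S) ,
                                exp_action = exp(-path$S)))
}

#' Converge the instanton rate in the bead number
#'
#' Doubles `N` until successive tunneling corrections agree within
#' `tol` (relative), interpolating each converged path as the next
#' starting guess.  The discretization error is \eqn{O(1/N^2)}, so a
#' Richardson extrapolation of the last two rates is reported as well.
#'
#' @param surface,state as in [optimize_instanton()].
#' @param tol relative convergence tolerance (default 1%).
#' @param N0 starting bead count.
#' @param Nmax cap; exceeding it raises a convergence error carrying the
#'   trace.
#' @param richardson extrapolate assuming \eqn{1/N^2} error.
#' @param ... passed to [instanton_rate()].
#' @return list with `rate` (a `rate_result`), `path`, and `record`
#'   (data.frame of N, S, kappa).
#' @export
converge_beads <- function(surface, state, tol = 0.01, N0 = 64,
                           Nmax = 4096, richardson = TRUE, ...) {
  N <- N0
  guess <- NULL
  rec <- NULL
  prev <- NULL
  repeat {
    p <- optimize_instanton(surface, state, N, guess = guess)
    r <- instanton_rate(p, surface, ...)
    rec <- rbind(rec, data.frame(N = N, S = p$S, kappa = r$kappa))
    if (!is.null(prev) &&
        abs(r$log_k - prev$rate$log_k) < log1p(tol)) {
      lk <- r$log_k
      if (richardson)
        lk <- r$log_k + (r$log_k - prev$rate$log_k) / 3  # O(1/N^2)
      out <- rate_result(k = exp(lk),
                         kappa = r$kappa * exp(lk - r$log_k),
                         method = "sci", log_k = lk,
                         components = r$components)
      return(list(rate = out, path = p, record = rec))
    }
    prev <- list(rate = r)
    if (2 * N > Nmax) {
      e <- simpleError(sprintf("bead convergence not reached by N = %d",
                               N))
      e$data <- rec
      stop(e)
    }
    # interpolate beads to 2N as next guess
    z <- p$beads
    zi <- matrix(0, 2 * N, ncol(z))
    zi[seq(1, 2 * N, by = 2), ] <- z
    zn <- z[c(2:N, 1), , drop = FALSE]
    zi[seq(2, 2 * N, by = 2), ] <- (z + zn) / 2
    guess <- zi
    N <- 2 * N
  }
}

#' Ground-state tunneling splitting from the kink instanton
#'
#' For a symmetric double well the splitting of the lowest doublet is
#' computed from a linear-polymer kink spanning a long imaginary time
#' \eqn{T}:
#' \deqn{\Delta = 2\hbar\,\sqrt{\frac{S_0}{2\pi\hbar\, m\, \eta}}\;
#'   \left[\frac{\det M_{0}}{\det' M_{K}}\right]^{1/2} e^{-S_K/\hbar},}
#' where \eqn{M_K} (\eqn{M_0}) is the action Hessian over interior beads
#' around the kink (around the bead chain resting in one well),
#' \eqn{\det'} drops the quasi-zero translation mode, \eqn{S_K} is the
#' kink action and \eqn{S_0 = \oint m \dot x^2 d\tau} its abbreviated
#' form.  \eqn{T} is doubled until \eqn{\Delta} is stable within `tol`
#' (the zero-temperature limit).
#'
#' @param surface a symmetric 1-D double well (degenerate minima within
#'   `degeneracy_tol`).
#' @param N beads in the linear polymer.
#' @param Ttot initial imaginary-time span; default \eqn{20/\omega}.
#' @param tol relative convergence tolerance for the \eqn{T}-doubling.
#' @param degeneracy_tol largest tolerated energy difference of the two
#'   minima, relative to the barrier.
#' @return object of class `splitting_result`: fields `delta`, `S0`,
#'   `S_kink`, and the convergence `record`.
#' @export
tunneling_splitting <- function(surface, N = 800, Ttot = NULL, tol = 0.01,
                                degeneracy_tol = 1e-8) {
  stopifnot(surface$dim == 1)
  m <- surface$masses[1]
  sps <- find_stationary_points(
    surface, guesses = c(-(surface$meta$x0 %||% 1), 0,
                         surface$meta$x0 %||% 1))
  mins <- Filter(function(p) p$type == "minimum", sps)
  if (length(mins) < 2)
    stop("double well required: found fewer than two minima",
         call. = FALSE)
  mins <- mins[order(vapply(mins, function(p) p$x[1], numeric(1)))]
  xL <- mins[[1]]$x[1]; xR <- mins[[2]]$x[1]
  barrier <- surface$energy((xL + xR) / 2) - mins[[1]]$energy
  if (abs(mins[[1]]$energy - mins[[2]]$energy) >
      degeneracy_tol * max(barrier, 1))
    stop("asymmetric wells: the kink splitting formula does not apply",
         call. = FALSE)
  Vmin <- mins[[1]]$energy
  omega <- sqrt(surface_hessian(surface, xL)[1, 1] / m)
  if (is.null(Ttot)) Ttot <- 20 / omega
  one <- function(Ttot, N) {
    eta <- Ttot / N
    tau <- (1:(N - 1)) * eta
    x <- xL + (xR - xL) / 2 * (1 + tanh(0.5 * omega * (tau - Ttot / 2)))
    for (it in 1:300) {
      xl <- c(xL, x[-(N - 1)]); xr <- c(x[-1], xR)
      g <- m * (2 * x - xl - xr) / eta +
        eta * vapply(x, function(z) surface_gradient(surface, z), numeric(1))
      if (sqrt(sum(g^2)) < 1e-11) break
      Vpp <- vapply(x, function(z) surface_hessian(surface, z)[1, 1],
                    numeric(1))
      H <- matrix(0, N - 1, N - 1)
      diag(H) <- 2 * m / eta + eta * Vpp
      id2 <- cbind(1:(N - 2), 2:(N - 1))
      H[id2] <- H[id2] - m / eta; H[id2[, 2:1]] <- H[id2[, 2:1]] - m / eta
      s <- solve(H, -g)
      mx <- max(abs(s)); cap <- 0.3 * (xR - xL)
      if (mx > cap) s <- s * cap / mx
      x <- x + s
    }
    full <- c(xL, x, xR)
    S <- sum(m * diff(full)^2 / (2 * eta)) +
      eta * sum(vapply(x, surface$energy, numeric(1)) - Vmin) +
      eta * (surface$energy(xL) + surface$energy(xR) - 2 * Vmin) / 2
    S0 <- sum(m * diff(full)^2 / eta)
    Vpp <- vapply(x, function(z) surface_hessian(surface, z)[1, 1],
                  numeric(1))
    H <- matrix(0, N - 1, N - 1)
    diag(H) <- 2 * m / eta + eta * Vpp
    id2 <- cbind(1:(N - 2), 2:(N - 1))
    H[id2] <- H[id2] - m / eta; H[id2[, 2:1]] <- H[id2[, 2:1]] - m / eta
    lamK <- sort(eigen(H, symmetric = TRUE, only.values = TRUE)$values)
    H0 <- H; diag(H0) <- 2 * m / eta + eta * surface_hessian(surface,
                                                             xL)[1, 1]
    lam0 <- eigen(H0, symmetric = TRUE, only.values = TRUE)$values
    ln_ratio <- sum(log(lam0)) - sum(log(lamK[-1]))
    2 * sqrt(S0 / (2 * pi * m * eta)) * exp(0.5 * ln_ratio - S)
  }
  rec <- NULL
  d_prev <- NULL
  for (rep in 1:6) {
    d <- one(Ttot, N)
    rec <- rbind(rec, data.frame(Ttot = Ttot, N = N, delta = d))
    if (!is.null(d_prev) && abs(d / d_prev - 1) < tol) break
    d_prev <- d
    Ttot <- 2 * Ttot; N <- 2 * N
  }
  structure(list(delta = d, record = rec, omega_well = omega),
            class = "splitting_result")
}

#' @export
print.splitting_result <- function(x, ...) {
  cat(sprintf("<splitting_result> delta = %.6g (well omega = %.4g)\n",
              x$delta, x$omega_well))
  invisible(x)
}
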