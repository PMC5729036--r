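
# Potential-energy-surface abstraction shared by every rate method.
#
# A surface is a list with the evaluation contract (energy, optionally
# analytic gradient / Hessian), per-degree-of-freedom masses, and an
# optional `kernel` descriptor that lets the compiled PIMC sampler evaluate
# built-in models without calling back into R.

#' Construct a potential-energy surface
#'
#' @param dim number of degrees of freedom.
#' @param masses numeric vector of length `dim` (or scalar, recycled):
#'   mass attached to each coordinate in internal units.
#' @param energy function `f(x)` returning a scalar potential energy;
#'   `x` is a numeric vector of length `dim`.
#' @param gradient optional analytic gradient `g(x)`; finite differences
#'   are used when absent.
#' @param hessian optional analytic Hessian `h(x)`.
#' @param kernel optional list `list(code =, params =)` describing a
#'   compiled built-in potential (used by the PIMC sampler); `NULL` for
#'   pure-R surfaces.
#' @param domain optional `dim x 2` matrix of coordinate bounds.
#' @param meta free-form list of model parameters.
#' @return object of class `potential_surface`.
#' @export
potential_surface <- function(dim, masses, energy, gradient = NULL,
                              hessian = NULL, kernel = NULL, domain = NULL,
                              meta = list()) {
  stopifnot(dim >= 1, is.function(energy))
  masses <- rep_len(as.numeric(masses), dim)
  if (any(!is.finite(masses)) || any(masses <= 0))
    stop("masses must be positive and finite", call. = FALSE)
  structure(list(dim = dim, masses = masses, energy = energy,
                 gradient = gradient, hessian = hessian, kernel = kernel,
                 domain = domain, meta = meta),
            class = "potential_surface")
}

#' @export
print.potential_surface <- function(x, ...) {
  cat(sprintf("<potential_surface> dim = %d, model = %s\n", x$dim,
              if (!is.null(x$meta$model)) x$meta$model else "custom"))
  invisible(x)
}

#' Evaluate a surface
#'
#' `surface_energy()` evaluates the potential; `surface_gradient()` and
#' `surface_hessian()` use analytic derivatives when the surface provides
#' them and central finite differences (step `h`, \eqn{O(h^2)}) otherwise.
#'
#' @param surface a [potential_surface()].
#' @param x coordinates (length `dim`).
#' @param h finite-difference step used when no analytic derivative exists.
#' @return energy scalar / gradient vector / symmetric Hessian matrix.
#' @export
surface_energy <- function(surface, x) surface$energy(as.numeric(x))

#' @rdname surface_energy
#' @export
surface_gradient <- function(surface, x, h = 1e-4) {
  if (!is.null(surface$gradient)) return(surface$gradient(as.numeric(x)))
  x <- as.numeric(x)
  vapply(seq_along(x), function(i) {
    e <- replace(numeric(length(x)), i, h)
    (surface$energy(x + e) - surface$energy(x - e)) / (2 * h)
  }, numeric(1))
}

#' @rdname surface_energy
#' @export
surface_hessian <- function(surface, x, h = 1e-4) {
  if (!is.null(surface$hessian)) {
    H <- surface$hessian(as.numeric(x))
    return((H + t(H)) / 2)
  }
  x <- as.numeric(x); n <- length(x)
  H <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in i:n) {
    ei <- replace(numeric(n), i, h); ej <- replace(numeric(n), j, h)
    H[i, j] <- H[j, i] <-
      (surface$energy(x + ei + ej) - surface$energy(x + ei - ej) -
       surface$energy(x - ei + ej) + surface$energy(x - ei - ej)) / (4 * h^2)
  }
  H
}

.check_pos <- function(...) {
  a <- list(...)
  for (nm in names(a))
    if (!is.numeric(a[[nm]]) || length(a[[nm]]) != 1 || !is.finite(a[[nm]]) ||
        a[[nm]] <= 0)
      stop(sprintf("parameter `%s` must be a positive finite scalar", nm),
           call. = FALSE)
  invisible(TRUE)
}

#' Symmetric Eckart barrier
#'
#' \eqn{V(x) = V_0\,\mathrm{sech}^2(x/a)}.  The degree of quantumness is
#' \eqn{\alpha = \pi a \sqrt{2 m V_0}/\hbar} and the inverse crossover
#' temperature \eqn{\beta_c = \alpha/V_0}.  Either the width `a` or
#' `alpha` may be specified; with `V0 = m = 1` fixing `alpha` fixes `a`.
#'
#' @param V0 barrier height (> 0).
#' @param a barrier width (> 0); mutually exclusive with `alpha`.
#' @param m particle mass (> 0).
#' @param alpha dimensionless quantumness (> pi/2 for the closed-form
#'   transmission probability to apply).
#' @return a `potential_surface` whose `meta` carries `V0`, `a`, `m`,
#'   `alpha`, `beta_c` and the barrier frequency `omega_bar`
#'   \eqn{= \sqrt{2 V_0/(m a^2)}}.
#' @export
#' @examples
#' s <- make_eckart(alpha = 12)
#' s$meta$beta_c            # = alpha / V0 = 12
make_eckart <- function(V0 = 1, a = NULL, m = 1, alpha = NULL) {
  .check_pos(V0 = V0, m = m)
  if (is.null(a) && is.null(alpha))
    stop("give one of `a` or `alpha`", call. = FALSE)
  if (is.null(a)) {
    .check_pos(alpha = alpha)
    a <- alpha / (pi * sqrt(2 * m * V0))
  } else {
    .check_pos(a = a)
    alpha <- pi * a * sqrt(2 * m * V0)
  }
  sech2 <- function(u) 1 / cosh(u)^2
  en <- function(x) V0 * sech2(x[1] / a)
  gr <- function(x) -2 * V0 / a * tanh(x[1] / a) * sech2(x[1] / a)
  # V'' = 2 V0/a^2 sech^2(u) (3 tanh^2 u - 1)
  he <- function(x) {
    u <- x[1] / a; t2 <- tanh(u)^2
    matrix(2 * V0 / a^2 * sech2(u) * (3 * t2 - 1), 1, 1)
  }
  potential_surface(
    dim = 1, masses = m, energy = en, gradient = gr, hessian = he,
    kernel = list(code = 1L, params = c(V0, a)),
    meta = list(model = "eckart", V0 = V0, a = a, m = m, alpha = alpha,
                beta_c = alpha / V0,
                omega_bar = sqrt(2 * V0 / (m * a^2))))
}

#' Symmetric quartic double well
#'
#' \eqn{V(x) = B\,(x^2 - x_0^2)^2 / x_0^4} with \eqn{x_0 =}
#' `separation/2`: two degenerate minima at \eqn{\pm x_0} separated by a
#' barrier of height `barrier` at the origin.  The harmonic frequency at
#' either minimum is \eqn{\omega = \sqrt{8 B/(m x_0^2)}}.
#'
#' @param barrier barrier height \eqn{B > 0}.
#' @param separation distance between the two minima (> 0).
#' @param m particle mass.
#' @return a `potential_surface` with `meta$omega_well` set.
#' @export
make_double_well <- function(barrier, separation, m = 1) {
  .check_pos(barrier = barrier, separation = separation, m = m)
  x0 <- separation / 2
  en <- function(x) barrier * (x[1]^2 - x0^2)^2 / x0^4
  gr <- function(x) 4 * barrier * x[1] * (x[1]^2 - x0^2) / x0^4
  he <- function(x) matrix(4 * barrier * (3 * x[1]^2 - x0^2) / x0^4, 1, 1)
  potential_surface(
    dim = 1, masses = m, energy = en, gradient = gr, hessian = he,
    kernel = list(code = 3L, params = c(barrier, x0)),
    meta = list(model = "double_well", barrier = barrier, x0 = x0, m = m,
                omega_well = sqrt(8 * barrier / (m * x0^2))))
}

#' Harmonic well (test fixture)
#'
#' \eqn{V(x) = \tfrac12 m \omega^2 (x - x_c)^2}; used as an analytic
#' reference for estimator and factorization checks.
#'
#' @param omega harmonic frequency (> 0).
#' @param m mass.
#' @param center well position.
#' @return a `potential_surface`.
#' @export
make_harmonic <- function(omega, m = 1, center = 0) {
  .check_pos(omega = omega, m = m)
  en <- function(x) 0.5 * m * omega^2 * (x[1] - center)^2
  gr <- function(x) m * omega^2 * (x[1] - center)
  he <- function(x) matrix(m * omega^2, 1, 1)
  potential_surface(
    dim = 1, masses = m, energy = en, gradient = gr, hessian = he,
    kernel = list(code = 2L, params = c(m * omega^2, center)),
    meta = list(model = "harmonic", omega = omega, m = m, center = center))
}

#' Separable barrier-plus-harmonic surface
#'
#' \eqn{V(x, y_1, \dots) = V_{1d}(x) + \sum_i \tfrac12 m_i
#' \omega_i(x)^2 y_i^2}: a one-dimensional profile with transverse
#' harmonic modes whose frequencies may depend on the reaction coordinate
#' (a vibrationally adiabatic model).
#'
#' @param surface_1d a one-dimensional `potential_surface`.
#' @param transverse list of modes, each `list(omega =, mass =)` where
#'   `omega` is either a positive constant or a function of `x`.
#' @return a `potential_surface` of dimension `1 + length(transverse)`.
#' @export
make_separable <- function(surface_1d, transverse) {
  stopifnot(inherits(surface_1d, "potential_surface"), surface_1d$dim == 1)
  modes <- lapply(transverse, function(tr) {
    m <- tr$mass %||% surface_1d$masses[1]
    om <- tr$omega
    omf <- if (is.function(om)) om else function(x) om
    list(mass = m, omega = omf)
  })
  nt <- length(modes)
  # a non-positive omega(x) encodes an imaginary transverse frequency
  # (omega^2 <= 0): invalid where the energy is requested
  wcheck <- function(x) {
    w <- vapply(modes, function(md) md$omega(x), numeric(1))
    if (any(w <= 0))
      stop("invalid separable model: transverse omega^2 <= 0 at x = ", x,
           call. = FALSE)
    w
  }
  en <- function(z) {
    x <- z[1]; y <- z[-1]
    w <- wcheck(x)
    mm <- vapply(modes, `[[`, numeric(1), "mass")
    surface_1d$energy(x) + sum(0.5 * mm * w^2 * y^2)
  }
  gr <- function(z, h = 1e-5) {
    x <- z[1]; y <- z[-1]
    w <- wcheck(x)
    mm <- vapply(modes, `[[`, numeric(1), "mass")
    dwdx <- vapply(modes, function(md) {
      (md$omega(x + h) - md$omega(x - h)) / (2 * h)
    }, numeric(1))
    gx <- surface_gradient(surface_1d, x)[1] + sum(mm * w * dwdx * y^2)
    c(gx, mm * w^2 * y)
  }
  potential_surface(
    dim = 1 + nt,
    masses = c(surface_1d$masses[1],
               vapply(modes, `[[`, numeric(1), "mass")),
    energy = en, gradient = gr,
    meta = list(model = "separable", base = surface_1d, modes = modes))
}

#' Two-dimensional Morse-superposition proton-transfer surface
#'
#' A donor-acceptor proton-transfer model in the heavy-atom distance
#' \eqn{R} (donor-acceptor) and proton distance \eqn{r} (donor-H), using
#' the progression coordinate \eqn{\rho = (r - r_0)/(R - R_0)} with
#' \eqn{r_0 = 0.8}, \eqn{R_0 = 1.6} (lengths in the same unit as `R`,
#' conventionally angstrom).  The planar (linear hydrogen bond) branch is
#' \deqn{V(R, \rho) = D_R (1 - e^{-b_R (R - R_e)})^2 +
#'   f\,[M(\rho) + M(1 - \rho)], \quad M(u) = D_p (1 - e^{-b_p (u -
#'   \rho_0)})^2,}
#' a superposition of Morse potentials that is symmetric under
#' \eqn{\rho \to 1 - \rho} (donor/acceptor exchange).  The published
#' parametrization of this family is not reproducible from openly printed
#' values, so all Morse parameters are user supplied; the defaults give a
#' synthetic barrier-forming example.  A quadratic bend term
#' `k_bend * theta^2` is added on the `theta != 0` branch when requested.
#'
#' @param params named list with entries `DR`, `bR`, `Re` (heavy-atom
#'   Morse), `Dp`, `bp`, `rho0` (proton Morse pair), optional `f`
#'   (coupling scale, default 1), `k_bend` and `theta` (default 0: planar
#'   branch), `r0`, `R0` (progression-coordinate reference lengths),
#'   `masses` (length 2).
#' @return a 2-D `potential_surface` in \eqn{(R, r)}; evaluation outside
#'   \eqn{\rho \in [0, 1]} is a domain error.
#' @export
make_mmpt_2d <- function(params = list()) {
  p <- modifyList(list(DR = 60, bR = 1.5, Re = 2.6, Dp = 40, bp = 4,
                       rho0 = 0.25, f = 1, k_bend = 0, theta = 0,
                       r0 = 0.8, R0 = 1.6, masses = c(12, 1)), params)
  .check_pos(DR = p$DR, bR = p$bR, Re = p$Re, Dp = p$Dp, bp = p$bp)
  morse <- function(u) p$Dp * (1 - exp(-p$bp * (u - p$rho0)))^2
  en <- function(z) {
    R <- z[1]; r <- z[2]
    if (R <= p$R0) stop("domain error: R <= R0", call. = FALSE)
    rho <- (r - p$r0) / (R - p$R0)
    if (rho < 0 || rho > 1)
      stop(sprintf("domain error: rho = %.3f outside [0, 1]", rho),
           call. = FALSE)
    v <- p$DR * (1 - exp(-p$bR * (R - p$Re)))^2 +
      p$f * (morse(rho) + morse(1 - rho))
    if (p$theta != 0) v <- v + p$k_bend * p$theta^2
    v
  }
  potential_surface(dim = 2, masses = p$masses, energy = en,
                    meta = c(list(model = "mmpt2d"), p))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Locate and classify stationary points
#'
#' Newton refinement of \eqn{\nabla V = 0} from each guess, classification
#' from the mass-weighted Hessian spectrum, and merging of duplicates
#' within `dedup_tol` (mass-weighted distance).
#'
#' @param surface a `potential_surface`.
#' @param guesses numeric vector (1-D) or list/matrix of starting points.
#' @param grad_tol convergence threshold on the gradient norm.
#' @param max_iter Newton iteration cap; exceeding it is an error carrying
#'   the last iterate in its `data` attribute.
#' @param dedup_tol merge threshold for duplicate stationary points.
#' @return list of `stationary_point` objects, each with fields `x`,
#'   `energy`, `hessian_eigenvalues` (mass-weighted), `frequencies`
#'   (\eqn{\omega_i = \sqrt{|\lambda_i|}}; the entry for a negative
#'   eigenvalue is the barrier frequency magnitude \eqn{\bar\omega}), and
#'   `type` (`"minimum"`, `"saddle"` for index 1, else `"higher-order"`).
#' @export
find_stationary_points <- function(surface, guesses, grad_tol = 1e-9,
                                   max_iter = 100, dedup_tol = 1e-6) {
  if (is.numeric(guesses) && is.null(dim(guesses)))
    guesses <- if (surface$dim == 1) as.list(guesses) else list(guesses)
  if (is.matrix(guesses)) guesses <- asplit(guesses, 1)
  sm <- sqrt(surface$masses)
  pts <- list()
  for (g in guesses) {
    x <- as.numeric(g)
    ok <- FALSE
    for (it in seq_len(max_iter)) {
      gr <- surface_gradient(surface, x)
      if (sqrt(sum(gr^2)) < grad_tol) { ok <- TRUE; break }
      H <- surface_hessian(surface, x)
      step <- tryCatch(solve(H, -gr), error = function(e) -gr)
      ns <- sqrt(sum(step^2))
      if (ns > 1) step <- step / ns          # damp far from convergence
      x <- x + step
    }
    if (!ok) {
      e <- simpleError(sprintf(
        "stationary-point search did not converge in %d iterations", max_iter))
      e$data <- list(last = x, grad_norm = sqrt(sum(gr^2)))
      stop(e)
    }
    H <- surface_hessian(surface, x)
    Hm <- H / outer(sm, sm)                  # mass-weighted
    ev <- eigen(Hm, symmetric = TRUE, only.values = TRUE)$values
    nneg <- sum(ev < -grad_tol^(1/2))
    pts[[length(pts) + 1]] <- structure(list(
      x = x, energy = surface$energy(x), hessian_eigenvalues = ev,
      frequencies = sqrt(abs(ev)),
      type = if (nneg == 0) "minimum" else if (nneg == 1) "saddle"
             else "higher-order"),
      class = "stationary_point")
  }
  # dedup by mass-weighted distance
  keep <- list()
  for (p in pts) {
    dup <- any(vapply(keep, function(q)
      sqrt(sum((sm * (p$x - q$x))^2)) < dedup_tol, logical(1)))
    if (!dup) keep[[length(keep) + 1]] <- p
  }
  keep
}

#' @export
print.stationary_point <- function(x, ...) {
  cat(sprintf("<stationary_point> %s at (%s), V = %.6g\n", x$type,
              paste(signif(x$x, 6), collapse = ", "), x$energy))
  invisible(x)
}

#' Export bead positions or stationary points in XYZ format
#'
#' One frame per bead (or point); the comment line carries the potential
#' energy.  Coordinates beyond three dimensions are truncated; missing
#' dimensions are zero-padded.
#'
#' @param coords matrix (frames x dim) or a `ring_polymer_path`.
#' @param surface surface used to evaluate the comment-line energy.
#' @param file output path.
#' @param symbol atom label written on each line.
#' @return `file`, invisibly.
#' @export
write_xyz <- function(coords, surface, file, symbol = "X") {
  if (inherits(coords, "ring_polymer_path")) coords <- coords$beads
  if (is.null(dim(coords))) coords <- matrix(coords, ncol = 1)
  con <- file(file, "w"); on.exit(close(con))
  for (i in seq_len(nrow(coords))) {
    xyz <- c(coords[i, ], 0, 0)[1:3]
    writeLines(c("1", sprintf("E = %.10g", surface$energy(coords[i, ])),
                 sprintf("%s %.10f %.10f %.10f", symbol, xyz[1], xyz[2],
                         xyz[3])), con)
  }
  invisible(file)
}

#' Isotope substitution on a surface
#'
#' Returns a copy of the surface with scaled masses and, for built-in
#' models, consistently updated derived metadata (Eckart quantumness
#' \eqn{\alpha \propto \sqrt m}, crossover \eqn{\beta_c}, barrier and
#' well frequencies \eqn{\propto 1/\sqrt m}).
#'
#' @param surface a `potential_surface`.
#' @param mass_factor multiplicative factor on every mass.
#' @return the substituted surface.
#' @export
#' @examples
#' isotopologue(make_eckart(alpha = 12), 2)$meta$alpha   # 12 * sqrt(2)
isotopologue <- function(surface, mass_factor) {
  .check_pos(mass_factor = mass_factor)
  s <- surface
  s$masses <- surface$masses * mass_factor
  r <- sqrt(mass_factor)
  for (nm in c("alpha", "beta_c")) if (!is.null(s$meta[[nm]]))
    s$meta[[nm]] <- s$meta[[nm]] * r
  for (nm in c("omega_bar", "omega_well", "omega")) if (!is.null(s$meta[[nm]]))
    s$meta[[nm]] <- s$meta[[nm]] / r
  if (!is.null(s$meta$m)) s$meta$m <- s$meta$m * mass_factor
  s
}
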