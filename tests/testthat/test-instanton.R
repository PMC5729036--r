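test_that("discretized action: collapsed path, free particle, derivatives", {
  e <- eckart12()
  beta <- 24
  p0 <- ring_polymer_path(rep(0, 64), beta)
  expect_equal(discretized_action(p0, e), beta * 1)   # spring terms vanish
  # free particle: pure spring action for any closed path
  f <- free_particle()
  z <- sin(2 * pi * (0:63) / 64)
  pf <- ring_polymer_path(z, beta)
  eta <- beta / 64
  expect_equal(discretized_action(pf, f),
               sum((z[c(2:64, 1)] - z)^2) / (2 * eta), tolerance = 1e-12)
  # analytic gradient/Hessian of the action vs finite differences
  pz <- ring_polymer_path(0.3 * cos(2 * pi * (0:15) / 16), beta)
  g <- action_gradient(pz, e)
  h <- 1e-6
  for (i in c(1, 7)) {
    zp <- pz; zp$beads[i, 1] <- zp$beads[i, 1] + h
    zm <- pz; zm$beads[i, 1] <- zm$beads[i, 1] - h
    expect_equal(g[i, 1],
                 (discretized_action(zp, e) - discretized_action(zm, e)) /
                   (2 * h), tolerance = 1e-5)
  }
})

test_that("optimized instanton: action, signature, turning points, symmetry", {
  e <- eckart12()
  st <- thermal_state(beta = 24)          # b = 2
  p <- optimize_instanton(e, st, N = 256)
  # analytic Eckart orbit: S = alpha(b + 1/b) = 18, S0 = W = 2 alpha(1-1/b)
  expect_equal(p$S, 18, tolerance = 1e-4)
  expect_equal(p$S0, 12, tolerance = 1e-4)
  lam <- p$hessian_eigenvalues
  expect_equal(sum(lam < -p$zero_mode_threshold), 1)
  expect_equal(sum(abs(lam) <= p$zero_mode_threshold), 1)
  # maximal bead displacement at the classical turning point a*acosh(b)
  expect_equal(max(abs(p$beads)), e$meta$a * acosh(2), tolerance = 1e-3)
  # cyclic relabeling leaves the action invariant
  p2 <- p; p2$beads <- p$beads[c(100:256, 1:99), , drop = FALSE]
  expect_equal(discretized_action(p2, e), p$S, tolerance = 1e-12)
  # above crossover the polymer collapses onto the saddle (with warning)
  expect_warning(pc <- optimize_instanton(e, thermal_state(beta = 6),
                                          N = 32), "collapse")
  expect_true(pc$collapsed)
  expect_equal(pc$S, 6, tolerance = 1e-12)
})

test_that("instanton rate matches the closed-form SCI at b = 2", {
  e <- eckart12()
  st <- thermal_state(beta = 24)
  p <- optimize_instanton(e, st, N = 256)
  r <- instanton_rate(p, e)
  expect_equal(r$kappa, sci_kappa_eckart(12, 2), tolerance = 2e-3)
  expect_error(instanton_rate(ring_polymer_path(rep(0, 8), 24), e),
               "not optimized")
})

test_that("bead convergence decays as 1/N^2 and Richardson sharpens it", {
  e <- eckart12()
  st <- thermal_state(beta = 24)
  cb <- converge_beads(e, st, tol = 0.01, N0 = 32)
  expect_equal(cb$rate$kappa, sci_kappa_eckart(12, 2), tolerance = 5e-3)
  kex <- sci_kappa_eckart(12, 2)
  err <- abs(cb$record$kappa - kex) / kex
  sl <- coef(lm(log(err) ~ log(cb$record$N)))[2]
  expect_equal(unname(sl), -2, tolerance = 0.3)
  # near crossover: small N suffices
  cb2 <- converge_beads(e, thermal_state(beta = 12 * 1.3), tol = 0.01,
                        N0 = 16)
  expect_lte(max(cb2$record$N), 128)
})

test_that("transverse modes cancel on a separable barrier", {
  e <- eckart12()
  sep <- make_separable(e, list(list(omega = 1.3, mass = 1)))
  st <- thermal_state(beta = 24)
  N <- 64
  p1 <- optimize_instanton(e, st, N = N)
  guess2 <- cbind(p1$beads[, 1], 0)
  p2 <- optimize_instanton(sep, st, N = N, guess = guess2)
  r1 <- instanton_rate(p1, e)
  r2 <- instanton_rate(p2, sep)
  expect_equal(r2$log_k, r1$log_k, tolerance = 1e-8)
})

test_that("instanton lowers the activation energy and stays near exact", {
  e <- eckart12()
  for (b in c(1.5, 2, 4)) {
    p <- optimize_instanton(e, thermal_state(beta = 12 * b), N = 128)
    expect_lt(p$S, 12 * b * 1)            # S < beta V0
  }
  # near-crossover overestimate is bounded (< 3x the exact rate)
  for (b in c(1.05, 1.2)) {
    cb <- converge_beads(e, thermal_state(beta = 12 * b), tol = 0.01,
                         N0 = 32)
    ratio <- cb$rate$kappa / eckart_kappa_exact(12, b)
    expect_gt(ratio, 1)
    expect_lt(ratio, 3)
  }
  # deep tunneling: within 25% of exact for b >= 2
  for (b in c(2, 4)) {
    expect_equal(sci_kappa_eckart(12, b) / eckart_kappa_exact(12, b), 1,
                 tolerance = 0.25)
  }
})

test_that("tunneling splitting: DVR agreement, isotopes, asymmetry guard", {
  dw <- deep_well()
  sp <- tunneling_splitting(dw, N = 600)
  dvr <- dvr_levels(dw, 2, xlim = c(-5, 5), n = 512)
  dref <- dvr[2] - dvr[1]
  expect_equal(sp$delta / dref, 1, tolerance = 0.2)
  # heavier mass: smaller splitting; the isotope ratio is closer to the
  # oracle than the absolute values
  dw2 <- isotopologue(dw, 2)
  sp2 <- tunneling_splitting(dw2, N = 600)
  dvr2 <- dvr_levels(dw2, 2, xlim = c(-5, 5), n = 512)
  dref2 <- dvr2[2] - dvr2[1]
  expect_lt(sp2$delta, sp$delta)
  ratio_err <- abs((sp$delta / sp2$delta) / (dref / dref2) - 1)
  abs_err <- abs(sp$delta / dref - 1)
  expect_lt(ratio_err, abs_err)
  # deeper barrier: the semiclassical error shrinks
  dwd <- make_double_well(12, 5)
  spd <- tunneling_splitting(dwd, N = 800)
  dvrd <- dvr_levels(dwd, 2, xlim = c(-6, 6), n = 512)
  expect_lt(abs(spd$delta / (dvrd[2] - dvrd[1]) - 1), abs_err + 0.02)
  # splitting agrees with the WKB asymptote within its validity regime
  m <- 1; w <- dwd$meta$omega_well
  turn <- uniroot(function(x) dwd$energy(x) - w / 2, c(0, 2.49))$root
  wkb_int <- integrate(function(x)
    sqrt(2 * m * pmax(vapply(x, dwd$energy, numeric(1)) - w / 2, 0)),
    -turn, turn)$value
  wkb <- w / pi * exp(-wkb_int)
  expect_equal(spd$delta / wkb, 1, tolerance = 0.35)
  # asymmetric wells are refused
  tilted <- potential_surface(1, 1, function(x)
    dw$energy(x) + 0.05 * x[1], meta = list(model = "double_well",
                                            x0 = 2))
  expect_error(tunneling_splitting(tilted), "symmetric|asymmetric")
})
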