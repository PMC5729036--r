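test_that("PIMC streams are bit-reproducible under a fixed seed", {
  e <- eckart12()
  st <- thermal_state(beta = 12)
  a <- pimc_sample(e, st, P = 32, sweeps = 500, burn = 100, seed = 9)
  b <- pimc_sample(e, st, P = 32, sweeps = 500, burn = 100, seed = 9)
  expect_identical(a$samples, b$samples)
  d <- pimc_sample(e, st, P = 32, sweeps = 500, burn = 100, seed = 10)
  expect_false(identical(a$samples, d$samples))
  expect_error(pimc_sample(e, st, P = 7), "even")
})

test_that("free-particle pinned ensemble matches closed forms", {
  f <- free_particle()
  st <- thermal_state(beta = 12)
  en <- suppressWarnings(pimc_sample(f, st, P = 32, sweeps = 8000,
                                     burn = 500, seed = 2,
                                     topology = "pinned"))
  q <- estimate_qi_quantities(en)
  # Cff/Cdd = 1/(m beta); dH = sqrt(2)/beta; both within 3 SE
  expect_lt(abs(q$cff_over_cdd[1] - 1 / 12), 3 * q$cff_over_cdd[2])
  expect_lt(abs(q$dH[1] - sqrt(2) / 12), 3 * q$dH[2])
  # mass estimator: d ln Cdd / d ln m = 1 for pins at the same point
  expect_lt(abs(q$dlnC_dlnm[1] - 1), 3 * q$dlnC_dlnm[2])
})

test_that("estimators agree with the finite-P oracle on the barrier", {
  e <- eckart12()
  st <- thermal_state(beta = 12)
  fp <- qi_finite_p(e, st, 0, 0, 32)
  en <- pimc_sample(e, st, P = 32, sweeps = 3e4, burn = 3e3, seed = 21)
  q <- estimate_qi_quantities(en)
  expect_lt(abs(q$cff_over_cdd[1] - fp$cff_over_cdd),
            3 * q$cff_over_cdd[2])
  expect_lt(abs(q$dH[1] - fp$dH), 3 * q$dH[2])
})

test_that("harmonic closed ring: energy estimators and their variances", {
  h <- make_harmonic(omega = 1)
  beta <- 4; P <- 64
  st <- thermal_state(beta = beta)
  en <- pimc_sample(h, st, P = P, sweeps = 2e4, burn = 2e3, seed = 5,
                    topology = "closed")
  s <- en$samples; eps <- en$eps
  # thermodynamic total-energy estimator vs the exact discrete value
  E_th <- 1 / (2 * eps) - s[, "spr1"] / (2 * P * eps^2) + s[, "sumV"] / P
  h2 <- 1e-4
  E_exact <- -(log(harmonic_q_discrete(1, 1, beta + h2, P)) -
                 log(harmonic_q_discrete(1, 1, beta - h2, P))) / (2 * h2)
  # virial total-energy estimator
  E_vi <- 1 / (2 * beta) + s[, "vir"] / (2 * P) + s[, "sumV"] / P
  bt <- kinst:::.block_stats(E_th, 25)
  bv <- kinst:::.block_stats(E_vi, 25)
  expect_lt(abs(bt$mean - E_exact), 3 * bt$se)
  expect_lt(abs(bv$mean - E_exact), 3 * sqrt(bv$se^2 + bt$se^2))
  # virial variance is smaller at large P on the same ensemble
  expect_lt(var(E_vi), var(E_th))
})

test_that("dividing-surface search finds the stationary separation", {
  e <- eckart12()
  o2 <- suppressWarnings(optimize_dividing_surfaces(
    e, thermal_state(beta = 24), P = 64, seed = 4))
  expect_equal(o2$xi_b, 2.75, tolerance = 0.12)
  expect_equal(o2$xi_a, -o2$xi_b)
  o05 <- suppressWarnings(optimize_dividing_surfaces(
    e, thermal_state(beta = 6), P = 32, seed = 4))
  expect_equal(o05$xi_b, 0)
})

test_that("mass thermodynamic integration matches closed forms", {
  st <- thermal_state(beta = 4)
  # trivial: equal masses
  expect_equal(mass_ti_ratio(make_harmonic(1), st, 1, 1, P = 16)$ln_ratio,
               0)
  # free particle in 1-D: analytic sqrt-mass ratio
  fr <- mass_ti_ratio(free_particle(), st, 1, 2, P = 16, target = "qr",
                      free = TRUE)
  expect_equal(fr$ln_ratio, 0.5 * log(2))
  # harmonic oscillator: sinh-form closed expression (thermo and virial)
  h <- make_harmonic(omega = 1)
  ex <- log(sinh(4 / 2) / sinh(4 / sqrt(2) / 2))
  for (est in c("thermodynamic", "virial")) {
    ti <- mass_ti_ratio(h, st, 1, 2, P = 64, target = "qr",
                        sweeps = 2e4, seed = 6, estimator = est)
    expect_lt(abs(ti$ln_ratio - ex), 3 * ti$se + 0.002, label = est)
  }
  # virial beats thermodynamic in variance
  tt <- mass_ti_ratio(h, st, 1, 2, P = 64, target = "qr", sweeps = 1e4,
                      seed = 7)
  tv <- mass_ti_ratio(h, st, 1, 2, P = 64, target = "qr", sweeps = 1e4,
                      seed = 7, estimator = "virial")
  expect_lt(tv$se, tt$se)
})

test_that("absolute Cdd by potential switching matches the oracle", {
  e <- eckart12()
  st <- thermal_state(beta = 12)
  ti <- suppressWarnings(cdd_absolute_ti(e, st, P = 32, 0, 0, nodes = 8,
                                         sweeps = 1e4, burn = 1e3,
                                         seed = 11))
  fp <- qi_finite_p(e, st, 0, 0, 32)
  expect_lt(abs(ti$ln_cdd - log(fp$cdd)), 3 * ti$se + 0.01)
})

test_that("Suzuki-Chin sampling reduces the Trotter bias of mass TI", {
  # at small P the SC mass-TI is much closer to the continuum limit
  h <- make_harmonic(omega = 1)
  st <- thermal_state(beta = 4)
  ex <- log(sinh(2) / sinh(sqrt(2)))   # omega scales as 1/sqrt(m)
  err <- sapply(c("lie-trotter", "suzuki-chin"), function(f) {
    gl <- kinst:::.gauss_legendre01(5)
    I <- 0
    for (i in 1:5) {
      mm <- 2^gl$x[i]
      surf <- make_harmonic(1)       # fixed spring constant k = 1
      surf$masses <- mm
      en <- pimc_sample(surf, st, P = 8, sweeps = 3e4, burn = 3e3,
                        seed = 40 + i, topology = "closed",
                        factorization = f)
      s <- en$samples
      g <- 8 / 2 - (s[, "spr1"] + s[, "spr2"]) / (2 * en$eps)
      if (f == "suzuki-chin") g <- g + s[, "sumG"]
      I <- I + gl$w[i] * mean(g)
    }
    abs(log(2) * I - ex)
  })
  expect_lt(err["suzuki-chin"], err["lie-trotter"])
})

test_that("Trotter selection: Suzuki-Chin needs fewer beads than Trotter", {
  e <- eckart12()
  st <- thermal_state(beta = 24)      # b = 2
  xi <- 2.753
  lt <- choose_trotter(e, st, -xi, xi, "lie-trotter", P0 = 8, n = 250)
  sc <- choose_trotter(e, st, -xi, xi, "suzuki-chin", P0 = 8, n = 250)
  expect_lt(sc$P, lt$P)
})

test_that("QI high-temperature overestimate is the sqrt(pi/2) factor", {
  e <- eckart12()
  st <- thermal_state(beta = 12 * 0.1)        # b = 0.1, far above crossover
  g <- qi_grid_quantities(e, st, 0, 0, L = 40, n = 700)
  ratio <- g$kappa / eckart_kappa_exact(12, 0.1)
  expect_equal(ratio, sqrt(pi / 2), tolerance = 0.03)
  expect_equal(ratio, 1.25, tolerance = 0.03)
})

test_that("identical isotopes give KIE = 1 within statistical error", {
  e <- eckart12()
  st <- thermal_state(beta = 12)
  k <- suppressWarnings(qi_kie(e, st, 1, 1, P = 32, sweeps = 5e3,
                               burn = 500, seed = 3, xi_A = 0, xi_B = 0))
  expect_lt(abs(k$kie - 1), 3 * k$se)
  expect_equal(k$factors$qr_ratio, 1)
  expect_equal(k$factors$cdd_ratio, 1)
})

test_that("factorized KIE equals the ratio of absolute QI rates", {
  e <- eckart12()
  st <- thermal_state(beta = 12)
  kie <- suppressWarnings(qi_kie(e, st, 1, 2, P = 48, sweeps = 4e4,
                                 burn = 4e3, seed = 8, xi_A = 0,
                                 xi_B = 0))
  rH <- suppressWarnings(qi_kappa_mc(e, st, P = 48, sweeps = 4e4,
                                     burn = 4e3, seed = 13, xi = 0,
                                     ti_nodes = 6))
  eD <- isotopologue(e, 2)
  rD <- suppressWarnings(qi_kappa_mc(eD, st, P = 48, sweeps = 4e4,
                                     burn = 4e3, seed = 14, xi = 0,
                                     ti_nodes = 6))
  # k = (k Qr)/Qr with Qr ratio sqrt(2)
  kie_abs <- sqrt(2) * rH$k / rD$k
  se_abs <- kie_abs * sqrt((rH$stat_error / rH$k)^2 +
                             (rD$stat_error / rD$k)^2)
  expect_lt(abs(kie$kie - kie_abs), 3 * sqrt(kie$se^2 + se_abs^2))
})

test_that("equilibration guard rejects a drifting stream", {
  # manufacture an ensemble whose <V> stream drifts strongly
  e <- eckart12()
  st <- thermal_state(beta = 12)
  en <- pimc_sample(e, st, P = 32, sweeps = 2000, burn = 200, seed = 1)
  en$samples[, "sumV"] <- en$samples[, "sumV"] +
    seq(0, 50, length.out = nrow(en$samples))
  expect_error(estimate_qi_quantities(en), "equilibration")
})
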