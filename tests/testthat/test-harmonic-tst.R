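test_that("crossover temperature: linearity, units, Eckart consistency", {
  expect_equal(crossover_temperature(2), 2 * crossover_temperature(1))
  # Eckart in reduced units: 1/Tc = beta_c = alpha / V0
  e <- eckart12()
  expect_equal(1 / crossover_temperature(e$meta$omega_bar), 12,
               tolerance = 1e-12)
  # spectroscopic route: wavenumber -> kelvin via hc/kB
  expect_equal(crossover_temperature(1463, "cm-1"),
               1463 * 1.438777 / (2 * pi), tolerance = 1e-4)
  expect_error(crossover_temperature(-1), "> 0")
})

test_that("Wigner correction: limits, monotonicity, value at crossover", {
  w <- function(b) wigner_correction(1, thermal_state(beta = b))
  expect_equal(w(1e-8), 1, tolerance = 1e-10)
  bs <- seq(0.1, 5, length.out = 20)
  expect_true(all(diff(vapply(bs, w, numeric(1))) > 0))
  expect_true(all(vapply(bs, w, numeric(1)) >= 1))
  # at T = Tc, hbar beta omega = 2 pi
  expect_equal(w(2 * pi), 1 + (2 * pi)^2 / 24)
  # matches the exact Eckart correction at small b to 1%; at alpha = 12
  # a finite-barrier term linear in beta (absent for a parabolic top)
  # limits the agreement, so probe b <= 0.05
  for (b in c(0.02, 0.05)) {
    kap_w <- 1 + (2 * pi * b)^2 / 24      # hbar beta omega_bar = 2 pi b
    expect_equal(kap_w, eckart_kappa_exact(12, b), tolerance = 0.01)
  }
})

test_that("Eyring rate: 1-D flux convention and input validation", {
  e <- eckart12()
  ts <- find_stationary_points(e, 0)[[1]]
  st <- thermal_state(beta = 12)
  r <- eyring_rate(ts = ts, state = st, surface = e)
  expect_equal(r$k, exp(-12) / (2 * pi * 12), tolerance = 1e-12)
  expect_equal(r$kappa, 1)
  rw <- eyring_rate(ts = ts, state = st, surface = e, wigner = TRUE)
  expect_equal(rw$k / r$k, wigner_correction(e$meta$omega_bar, st))
  # exact over Eyring reproduces the benchmark correction (cross-module)
  ex <- exact_rate_from_transmission(e, st)
  expect_signif_equal(ex$k / r$k, 6.16)
  # a minimum is not a transition state
  mn <- find_stationary_points(deep_well(), 2)[[1]]
  expect_error(eyring_rate(ts = mn, state = st, surface = e),
               "saddle")
})

test_that("effective barrier: worked values and linearity", {
  expect_equal(effective_barrier(1517, 14255, 12970), 232)
  expect_equal(effective_barrier(1430, 14853, 13980), 557)
  expect_equal(effective_barrier(1000, 500, 500), 1000)
  # linear in each argument; swapping ZPEs negates the correction
  expect_equal(effective_barrier(0, 100, 300) -
                 effective_barrier(0, 300, 100), 400)
  expect_error(effective_barrier(-1, 0, 0), ">= 0")
})

test_that("translational KIE factor from atomic masses", {
  # H/D + CH4 with standard atomic masses
  expect_equal(signif(kie_translation_factor(1.008, 2.014, 16.043), 3),
               2.59)
})

test_that("KIE decomposition multiplies to the total", {
  mk <- function(tr, rot, vib, ea)
    rate_result(k = tr * rot * vib * ea, components =
                  list(trans = tr, rot = rot, vib = vib,
                       exp_action = ea))
  A <- mk(2.59, 0.67, 0.211, 1.02); B <- mk(1, 1, 1, 1)
  kb <- kie_decomposition(A, B)
  expect_equal(kb$total, kb$trans * kb$rot * kb$vib * kb$exp_action,
               tolerance = 1e-12)
  # the four printed factors multiply to the printed total to rounding
  expect_equal(kb$total, 0.38, tolerance = 0.02)
  idb <- kie_decomposition(A, A)
  expect_equal(unlist(idb[c("trans", "rot", "vib", "exp_action")]),
               c(trans = 1, rot = 1, vib = 1, exp_action = 1))
  expect_error(kie_decomposition(A, rate_result(1)), "incomplete")
})

test_that("KIE from activation free energies (worked rows)", {
  st300 <- thermal_state(300, energy_unit = "kcal/mol")
  expect_equal(kie_from_free_energies(1.018, 2.293, st300), 8.48,
               tolerance = 0.002 * 8.48)
  st1500 <- thermal_state(1500, energy_unit = "kcal/mol")
  expect_equal(kie_from_free_energies(4.581, 5.281, st1500), 1.26,
               tolerance = 0.005 * 1.26)
  expect_equal(kie_from_free_energies(2, 2, st300), 1)
})

test_that("ZPE-corrected profiles: cancellation, adiabatic barrier, mass", {
  e <- eckart12()
  # constant transverse frequency: correction cancels between TS and
  # reactant -> corrected barrier equals bare barrier
  sep_c <- make_separable(e, list(list(omega = 3, mass = 1)))
  grid <- seq(-20, 20, length.out = 81)
  prof <- zpe_corrected_profile(sep_c, grid)
  corr_barrier <- max(prof$V_corrected) - prof$V_corrected[1]
  expect_equal(corr_barrier, max(prof$V) - prof$V[1], tolerance = 1e-9)
  # omega dropping from w_min to w_TS: corrected barrier = V0 + (wTS - wmin)/2
  wmin <- 3; wts <- 2
  om <- function(x) wts + (wmin - wts) * tanh((x / e$meta$a)^2)
  sep_d <- make_separable(e, list(list(omega = om, mass = 1)))
  prof_d <- zpe_corrected_profile(sep_d, grid)
  expect_equal(max(prof_d$V_corrected) - prof_d$V_corrected[1],
               1 + (wts - wmin) / 2, tolerance = 1e-4)
  # doubling the transverse mass scales the ZPE correction by 1/sqrt(2):
  # omega = sqrt(k/m) with the same force constant
  om2 <- function(x) om(x) / sqrt(2)
  sep_m <- make_separable(e, list(list(omega = om2, mass = 2)))
  prof_m <- zpe_corrected_profile(sep_m, grid)
  d1 <- max(prof_d$V_corrected) - prof_d$V_corrected[1] - 1
  d2 <- max(prof_m$V_corrected) - prof_m$V_corrected[1] - 1
  expect_equal(d2, d1 / sqrt(2), tolerance = 1e-5)
  # imaginary transverse frequency is flagged, not dropped
  omb <- function(x) 1 - 2 * exp(-(x / e$meta$a)^2)
  expect_error(make_separable(e, list(list(omega = omb, mass = 1))),
               NA)
  sep_b <- make_separable(e, list(list(omega = function(x)
    sqrt(abs(1 - 2 * exp(-(x / e$meta$a)^2))) *
      sign(1 - 2 * exp(-(x / e$meta$a)^2)), mass = 1)))
  prof_b <- zpe_corrected_profile(sep_b, c(-6, 0, 6))
  expect_true(prof_b$flagged[2])
  expect_false(prof_b$flagged[1])
  expect_equal(nrow(prof_b), 3)
})
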