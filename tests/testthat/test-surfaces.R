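test_that("Eckart barrier: shape, derivatives and derived parameters", {
  s <- eckart12()
  expect_equal(surface_energy(s, 0), 1)                  # sech(0) = 1
  expect_lt(surface_energy(s, 8 * s$meta$a), 1e-6)       # asymptote
  # barrier frequency from the analytic Hessian
  omega_h <- sqrt(-surface_hessian(s, 0)[1, 1] / s$masses[1])
  expect_equal(omega_h, sqrt(2 * 1 / (1 * s$meta$a^2)), tolerance = 1e-12)
  expect_equal(s$meta$beta_c, 12)
  expect_error(make_eckart(V0 = -1, a = 1), "positive")
  expect_error(make_eckart(alpha = 0), "positive")
})

test_that("finite differences agree with analytic derivatives", {
  for (s in list(eckart12(), deep_well())) {
    noderiv <- potential_surface(1, s$masses, s$energy,
                                 meta = s$meta)
    for (x in c(-1.7, 0.3, 2.2)) {
      expect_equal(surface_gradient(noderiv, x),
                   surface_gradient(s, x), tolerance = 1e-6)
      expect_equal(surface_hessian(noderiv, x)[1, 1],
                   surface_hessian(s, x)[1, 1], tolerance = 1e-5)
    }
  }
})

test_that("quartic double well geometry and frequency", {
  dw <- make_double_well(8, 5, m = 2)
  x0 <- 2.5
  expect_equal(surface_energy(dw, x0), 0)
  expect_equal(surface_energy(dw, -x0), 0)
  expect_equal(surface_energy(dw, 0), 8)
  # analytic well frequency vs second derivative at the minimum
  expect_equal(dw$meta$omega_well,
               sqrt(surface_hessian(dw, x0)[1, 1] / 2), tolerance = 1e-12)
})

test_that("separable surfaces: block structure and reduction at y = 0", {
  e <- eckart12()
  sep <- make_separable(e, list(list(omega = 2, mass = 1.5)))
  z <- c(0.7, 0)
  expect_equal(surface_gradient(sep, z)[1], surface_gradient(e, 0.7)[1],
               tolerance = 1e-9)
  H <- surface_hessian(sep, c(0.4, 0.3))
  expect_equal(H[1, 2], 0, tolerance = 1e-6)      # constant omega: no coupling
  expect_equal(H[2, 2], 1.5 * 4, tolerance = 1e-6)
  # saddle of Eckart+harmonic at origin with exactly one negative mode;
  # mass-weighted saddle eigenvalue is -2 V0 / a^2 (m = 1)
  sp <- find_stationary_points(sep, list(c(0.2, 0.1)))[[1]]
  expect_equal(sp$type, "saddle")
  expect_equal(min(sp$hessian_eigenvalues), -2 / e$meta$a^2,
               tolerance = 1e-6)
  # position-dependent omega^2 <= 0 is an invalid model
  bad <- make_separable(e, list(list(omega = function(x) x, mass = 1)))
  expect_error(surface_energy(bad, c(-1, 0.1)), "invalid")
})

test_that("2-D Morse proton-transfer form: symmetry, rho mapping, domain", {
  s <- make_mmpt_2d()
  R <- 2.8
  rho_to_r <- function(rho) 0.8 + rho * (R - 1.6)
  # donor/acceptor symmetry V(R, rho) = V(R, 1 - rho)
  for (rho in c(0.2, 0.35, 0.5)) {
    expect_equal(surface_energy(s, c(R, rho_to_r(rho))),
                 surface_energy(s, c(R, rho_to_r(1 - rho))),
                 tolerance = 1e-10)
  }
  # rho endpoints map to r = r0 and r = R - r0
  expect_silent(surface_energy(s, c(R, 0.8)))
  expect_silent(surface_energy(s, c(R, R - 0.8)))
  expect_error(surface_energy(s, c(R, 0.7)), "domain")
  expect_error(surface_energy(s, c(R, R - 0.7)), "domain")
  # double-well profile in rho at fixed R for barrier-forming parameters
  rg <- seq(0.05, 0.95, length.out = 181)
  v <- vapply(rg, function(p) surface_energy(s, c(R, rho_to_r(p))),
              numeric(1))
  sign_changes <- sum(diff(sign(diff(v))) != 0)
  expect_equal(sign_changes, 3)    # min, max, min
})

test_that("stationary-point search finds, classifies, deduplicates", {
  e <- eckart12()
  pts <- find_stationary_points(e, c(-0.5, 0.2, 0))
  expect_length(pts, 1)                       # duplicates merged
  expect_equal(pts[[1]]$type, "saddle")
  expect_equal(pts[[1]]$x, 0, tolerance = 1e-7)
  expect_equal(pts[[1]]$energy, surface_energy(e, pts[[1]]$x))
  dw <- deep_well()
  pts <- find_stationary_points(dw, c(-2.5, 0.1, 2.4))
  types <- sort(vapply(pts, `[[`, character(1), "type"))
  expect_equal(types, c("minimum", "minimum", "saddle"))
})

test_that("isotopologue rescales masses and derived metadata", {
  s <- isotopologue(eckart12(), 2)
  expect_equal(s$masses, 2)
  expect_equal(s$meta$alpha, 12 * sqrt(2))
  expect_equal(s$meta$beta_c, 12 * sqrt(2))
  expect_equal(s$meta$omega_bar, eckart12()$meta$omega_bar / sqrt(2))
})

test_that("XYZ export writes one frame per point with energies", {
  e <- eckart12()
  f <- withr::local_tempfile(fileext = ".xyz")
  write_xyz(rbind(0, 1, 2), e, f)
  lines <- readLines(f)
  expect_length(lines, 9)
  expect_match(lines[2], "^E = 1")
})
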