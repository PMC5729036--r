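# fixtures built in code; reduced units (hbar = kB = 1) throughout

eckart12 <- function(m = 1) {
  s <- make_eckart(alpha = 12)
  if (m != 1) s <- isotopologue(s, m)
  s
}

free_particle <- function(m = 1) {
  potential_surface(1, m, function(x) 0, gradient = function(x) 0,
                    hessian = function(x) matrix(0, 1, 1),
                    kernel = list(code = 0L, params = c(0, 0)),
                    meta = list(model = "free", a = 1))
}

# deep double well used for splitting checks: barrier/hbar-omega ~ 2.2
deep_well <- function(m = 1) make_double_well(10, 4, m = m)

expect_signif_equal <- function(x, printed, digits = 3) {
  expect_equal(signif(x, digits), printed,
               tolerance = 1e-9,
               label = sprintf("signif(%g, %d)", x, digits))
}
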