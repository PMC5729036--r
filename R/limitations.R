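
#' Documented desk-scale limitations
#'
#' Benchmark quantities from the hydrogen-transfer literature that this
#' package deliberately does not reproduce, because they require fitted
#' multi-dimensional potential-energy surfaces, unpublished force-field
#' parameters, external electronic-structure engines, or
#' hardware-dependent timings.  Kept as a machine-readable contract so
#' the test suite can assert the scope boundary.
#'
#' @format Named character vector; names identify the quantity class,
#'   values state why it is out of reach at desk scale.
#' @export
kinst_limitations <- c(
  fitted_surface_rates = paste(
    "Absolute H+H2 / H+CH4 rates and KIEs on fitted surfaces (BKMP2,",
    "CBE, WWM) need those external potential-energy surfaces"),
  malonaldehyde_splittings = paste(
    "Malonaldehyde tunneling splittings (121 / 13.9 / 25 cm-1) and its",
    "QI KIE table need the unpublished MMPT parametrization or an",
    "external CCSD(T) surface; only the functional form is provided"),
  speedup_table = paste(
    "Estimator/factorization speedup figures are implementation- and",
    "hardware-dependent; only the convergence orders (P^-2 vs P^-4) and",
    "variance orderings are asserted"),
  azzouz_borgis = paste(
    "Condensed-phase proton transfer (Azzouz-Borgis model in liquid",
    "methyl chloride) needs a solvated simulation stack"))
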