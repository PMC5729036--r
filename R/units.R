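
#' Physical constants and spectroscopic unit conversions
#'
#' Internally the package works in reduced units with \eqn{\hbar = 1} and
#' \eqn{k_B = 1}: the user picks a mass, length and energy scale and all
#' quantities are expressed in the corresponding derived units.  For
#' molecular applications the constants below (CODATA 2018) convert between
#' the spectroscopic energy units that appear in the literature.
#'
#' All `..._to_cm1` entries are multiplicative factors taking the named unit
#' to wavenumbers; `kB_*` entries give Boltzmann's constant expressed in the
#' named energy unit per kelvin; `c2_cm_K` is the second radiation constant
#' \eqn{h c / k_B} in cm K, so an energy of 1 cm\eqn{^{-1}} equals
#' `c2_cm_K` kelvin.
#'
#' @format A named list of scalars.
#' @export
#' @examples
#' # 1463 cm-1 expressed as a temperature:
#' 1463 * kinst_constants$c2_cm_K
kinst_constants <- list(
  c2_cm_K        = 1.438776877,   # hc/kB  [cm K]
  kB_cm1_per_K   = 1 / 1.438776877,
  kB_kcalmol_per_K = 0.0019872043,
  kB_kJmol_per_K = 0.0083144626,
  kcalmol_to_cm1 = 349.75509,
  kJmol_to_cm1   = 83.593547,
  eV_to_cm1      = 8065.54394,
  amu_to_me      = 1822.888486,   # atomic mass unit in electron masses
  angstrom_to_bohr = 1 / 0.529177210903
)

#' Convert an energy between supported units
#'
#' @param x numeric energies.
#' @param from,to one of `"cm-1"`, `"kcal/mol"`, `"kJ/mol"`, `"K"`, `"eV"`.
#' @return numeric vector in the target unit.
#' @export
#' @examples
#' convert_energy(1.275, "kcal/mol", "cm-1")
convert_energy <- function(x, from, to) {
  to_cm1 <- function(u) switch(u,
    "cm-1"     = 1,
    "kcal/mol" = kinst_constants$kcalmol_to_cm1,
    "kJ/mol"   = kinst_constants$kJmol_to_cm1,
    "eV"       = kinst_constants$eV_to_cm1,
    "K"        = kinst_constants$kB_cm1_per_K,
    stop("unknown energy unit: ", u, call. = FALSE))
  x * to_cm1(from) / to_cm1(to)
}

.kB_in <- function(energy_unit) {
  switch(energy_unit,
    "reduced"  = 1,
    "cm-1"     = kinst_constants$kB_cm1_per_K,
    "kcal/mol" = kinst_constants$kB_kcalmol_per_K,
    "kJ/mol"   = kinst_constants$kB_kJmol_per_K,
    "K"        = 1,
    stop("unknown energy unit: ", energy_unit, call. = FALSE))
}

#' Thermal state (temperature and inverse temperature)
#'
#' Captures a temperature together with the energy unit in which
#' \eqn{\beta = 1/(k_B T)} is expressed.  In `"reduced"` units the
#' temperature *is* an energy (\eqn{k_B = 1}); in spectroscopic units the
#' temperature is in kelvin and \eqn{\beta} comes out in inverse energy
#' units of `energy_unit`.
#'
#' @param temperature temperature (> 0); kelvin unless `energy_unit =
#'   "reduced"`, in which case it is an energy in the working reduced unit.
#' @param beta alternatively, the inverse temperature; exactly one of
#'   `temperature`/`beta` must be given.
#' @param energy_unit unit in which energies (and hence \eqn{\beta^{-1}})
#'   are measured.
#' @return object of class `thermal_state` with fields `temperature`,
#'   `beta`, `energy_unit`.
#' @export
#' @examples
#' thermal_state(300, energy_unit = "kcal/mol")$beta   # mol/kcal
#' thermal_state(beta = 24)$temperature                # reduced units
thermal_state <- function(temperature = NULL, beta = NULL,
                          energy_unit = "reduced") {
  kB <- .kB_in(energy_unit)
  if (is.null(temperature) == is.null(beta))
    stop("give exactly one of `temperature` or `beta`", call. = FALSE)
  if (is.null(beta)) {
    if (temperature <= 0) stop("temperature must be > 0", call. = FALSE)
    beta <- 1 / (kB * temperature)
  } else {
    if (beta <= 0) stop("beta must be > 0", call. = FALSE)
    temperature <- 1 / (kB * beta)
  }
  structure(list(temperature = temperature, beta = beta,
                 energy_unit = energy_unit),
            class = "thermal_state")
}

#' @export
print.thermal_state <- function(x, ...) {
  cat(sprintf("<thermal_state> T = %g %s, beta = %g [1/%s]\n",
              x$temperature,
              if (x$energy_unit == "reduced") "(reduced)" else "K",
              x$beta, x$energy_unit))
  invisible(x)
}
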