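#' Physical and biochemical constants for the gas-exchange engine
#'
#' Returns the constant set used throughout the package: the diffusion
#' constants of the anatomical conductance equation, the isotope
#' fractionation factors, the operational conductance ratio, the boundary
#' layer conductance, the leaf temperature, and the Rubisco kinetics at
#' 25 degC with their Arrhenius activation energies (Bernacchi et al. 2001
#' parameter set).
#'
#' All values can be overridden by passing replacements, e.g.
#' `eb_constants(gs_gsmax_ratio = 1)`.
#'
#' @param ... named replacements for individual constants.
#'
#' @return A named list with components:
#' \describe{
#'   \item{dw}{diffusivity of water vapour in air at 25 degC, m^2 s^-1.}
#'   \item{v}{molar volume of air, m^3 mol^-1.}
#'   \item{frac_a}{isotope fractionation by diffusion in air, permil.}
#'   \item{frac_b}{net fractionation by carboxylation (leaf bulk material), permil.}
#'   \item{gs_gsmax_ratio}{ratio of operational to anatomical maximum
#'     stomatal conductance (field-calibrated mean, 0.51).}
#'   \item{gcb}{boundary-layer conductance to CO2, mol m^-2 s^-1.}
#'   \item{t_leaf}{operational leaf temperature, degC.}
#'   \item{rd_frac}{day respiration as a fraction of Vcmax (0.015).}
#'   \item{oxygen}{ambient O2 mole fraction, mmol mol^-1.}
#'   \item{kc25, ko25, gamma_star25}{Rubisco Michaelis constants (umol mol^-1,
#'     mmol mol^-1) and CO2 compensation point without day respiration
#'     (umol mol^-1) at 25 degC.}
#'   \item{ha_vcmax, ha_kc, ha_ko, ha_gamma_star}{activation energies, J mol^-1.}
#'   \item{gas_const}{universal gas constant, J mol^-1 K^-1.}
#' }
#' @export
#' @examples
#' cst <- eb_constants()
#' cst$gs_gsmax_ratio
eb_constants <- function(...) {
  cst <- list(
    dw             = 2.49e-5,
    v              = 2.24e-2,
    frac_a         = 4.4,
    frac_b         = 27,
    gs_gsmax_ratio = 0.51,
    gcb            = 2,
    t_leaf         = 29,
    rd_frac        = 0.015,
    oxygen         = 210,
    kc25           = 404.9,
    ko25           = 278.4,
    gamma_star25   = 42.75,
    ha_vcmax       = 65330,
    ha_kc          = 79430,
    ha_ko          = 36380,
    ha_gamma_star  = 37830,
    gas_const      = 8.314
  )
  override <- list(...)
  if (length(override)) {
    unknown <- setdiff(names(override), names(cst))
    if (length(unknown)) {
      stop("unknown constant(s): ", paste(unknown, collapse = ", "))
    }
    cst[names(override)] <- override
  }
  cst
}
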