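#' Carbon isotope discrimination from leaf and air composition
#'
#' Photosynthetic carbon isotope discrimination of the leaf relative to the
#' atmosphere:
#' \deqn{\Delta_{plant} = \frac{\delta^{13}C_{air} - \delta^{13}C_{plant}}{1 + \delta^{13}C_{plant}/1000}}
#'
#' @param d13c_plant leaf delta-13C, permil vs VPDB (vectorised).
#' @param d13c_air atmospheric delta-13C, permil vs VPDB.
#' @return discrimination, permil.
#' @export
#' @examples
#' delta_plant(-28, -8.4) # ~20.16 permil
delta_plant <- function(d13c_plant, d13c_air) {
  if (any(abs(c(d13c_plant, d13c_air)) >= 60, na.rm = TRUE)) {
    stop("delta-13C values outside the plausible range (|value| < 60 permil)")
  }
  (d13c_air - d13c_plant) / (1 + d13c_plant / 1000)
}

#' ci/ca ratio from discrimination
#'
#' Inverts the simple C3 discrimination model
#' \eqn{\Delta = a + (b - a) c_i/c_a}, where `a` is the fractionation by
#' diffusion in air (4.4 permil) and `b` the net carboxylation fractionation
#' (27 permil for leaf bulk material). The model deliberately ignores
#' boundary-layer, mesophyll, photorespiration and ternary terms; no hidden
#' corrections are applied. Values outside [0, 1] — which real isotopic noise
#' produces — are returned unmodified so that downstream regressions see them;
#' use the `flag` attribute of [augment_iwue()] to identify them.
#'
#' @param delta discrimination, permil (vectorised).
#' @param a,b fractionation factors, permil.
#' @return dimensionless ci/ca.
#' @export
#' @examples
#' ci_over_ca(20.165) # ~0.698
ci_over_ca <- function(delta, a = 4.4, b = 27) {
  (delta - a) / (b - a)
}

#' Intrinsic water-use efficiency
#'
#' \deqn{iWUE = A/g_s = c_a (1 - c_i/c_a) / 1.6}
#' with 1.6 the ratio of the diffusivities of water vapour and CO2 in air.
#'
#' @param ca ambient CO2, ppm (vectorised).
#' @param ci_ca dimensionless ci/ca ratio.
#' @return iWUE in umol mol^-1.
#' @export
#' @examples
#' iwue(400, 0.6976) # ~75.6
iwue <- function(ca, ci_ca) {
  if (any(ca <= 0, na.rm = TRUE)) stop("ca must be positive")
  ca * (1 - ci_ca) / 1.6
}

#' Full isotope chain for one specimen
#'
#' Composes [delta_plant()], [ci_over_ca()] and [iwue()] using the
#' year-matched atmospheric CO2 and delta-13C from an atmosphere series.
#'
#' @param d13c_plant leaf delta-13C, permil.
#' @param year collection year (must be covered by `atmosphere`).
#' @param atmosphere an [atmosphere_series()] object.
#' @param a,b fractionation factors, permil.
#' @return list of class `"isotope_result"` with `delta_plant`, `ci_over_ca`,
#'   `ci` (ppm), `iwue` (umol mol^-1), `ca`, and logical `out_of_range`
#'   marking ci/ca outside [0, 1].
#' @export
specimen_iwue <- function(d13c_plant, year, atmosphere, a = 4.4, b = 27) {
  if (is.na(d13c_plant)) {
    out <- list(delta_plant = NA_real_, ci_over_ca = NA_real_, ci = NA_real_,
                iwue = NA_real_, ca = NA_real_, out_of_range = NA)
    class(out) <- "isotope_result"
    return(out)
  }
  atm <- atmosphere_lookup(atmosphere, year)
  dp <- delta_plant(d13c_plant, atm$d13c_air)
  r  <- ci_over_ca(dp, a = a, b = b)
  out <- list(
    delta_plant  = dp,
    ci_over_ca   = r,
    ci           = r * atm$ca,
    iwue         = iwue(atm$ca, r),
    ca           = atm$ca,
    out_of_range = r < 0 || r > 1
  )
  class(out) <- "isotope_result"
  out
}

#' @export
print.isotope_result <- function(x, ...) {
  cat(sprintf(
    "Isotope-derived gas exchange: Delta = %.3f permil, ci/ca = %.4f%s, iWUE = %.2f umol/mol\n",
    x$delta_plant, x$ci_over_ca,
    if (isTRUE(x$out_of_range)) " (outside [0,1])" else "", x$iwue))
  invisible(x)
}

#' Append isotope-derived columns to a specimen table
#'
#' Computes discrimination, ci/ca, ci and iWUE for every specimen with a
#' delta-13C value, using year-matched atmospheric composition. Specimens
#' without delta-13C get `NA` columns.
#'
#' @param records specimen table.
#' @param atmosphere an [atmosphere_series()] covering all collection years.
#' @param a,b fractionation factors, permil.
#' @return `records` with columns `ca`, `delta_plant`, `ci_ca`, `ci`, `iwue`
#'   and logical `ci_ca_flag` (TRUE when ci/ca falls outside [0, 1]).
#' @export
augment_iwue <- function(records, atmosphere, a = 4.4, b = 27) {
  atm <- atmosphere_lookup(atmosphere, records$year)
  records$ca <- atm$ca
  dp <- ifelse(is.na(records$delta13c), NA_real_,
               delta_plant(records$delta13c, atm$d13c_air))
  r <- ci_over_ca(dp, a = a, b = b)
  records$delta_plant <- dp
  records$ci_ca       <- r
  records$ci          <- r * atm$ca
  records$iwue        <- iwue(atm$ca, r)
  records$ci_ca_flag  <- !is.na(r) & (r < 0 | r > 1)
  records
}
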