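#' Maximum stomatal pore area from pore length
#'
#' The fully open stomatal pore is modelled as an ellipse whose major axis is
#' the pore length `L` and whose minor axis is `L/2`, giving an area of
#' `pi * L^2 / 8`.
#'
#' @param pore_length_um stomatal pore length in micrometres (vectorised).
#'   `NA` is propagated.
#' @return maximum pore area in square micrometres.
#' @export
#' @examples
#' amax_from_pore_length(20) # 157.08 um^2
amax_from_pore_length <- function(pore_length_um) {
  if (any(pore_length_um < 0, na.rm = TRUE)) {
    stop("pore length must be non-negative")
  }
  pi * pore_length_um^2 / 8
}

#' Anatomical maximum stomatal conductance
#'
#' Theoretical maximum stomatal conductance to water vapour from stomatal
#' anatomy, using the diffusion equation
#' \deqn{g_{smax} = \frac{d_w}{v} \cdot \frac{D \, a_{max}}{p + \frac{\pi}{2}\sqrt{a_{max}/\pi}}}
#' where \eqn{d_w} is the diffusivity of water vapour, \eqn{v} the molar
#' volume of air, \eqn{D} stomatal density, \eqn{a_{max}} the maximum pore
#' area and \eqn{p} the pore depth (taken equal to the guard-cell width,
#' assuming guard cells inflate to a circular cross-section). All quantities
#' are converted to SI internally.
#'
#' @param density_mm2 stomatal density, stomata per mm^2 (vectorised).
#' @param amax_um2 maximum pore area, um^2.
#' @param pore_depth_um pore depth (guard-cell width), um.
#' @param constants constant set from [eb_constants()].
#' @return conductance in mol m^-2 s^-1. `NA` inputs give `NA`.
#' @export
#' @examples
#' gsmax(300, amax_from_pore_length(20), 5) # ~3.25 mol m^-2 s^-1
gsmax <- function(density_mm2, amax_um2, pore_depth_um,
                  constants = eb_constants()) {
  if (any(density_mm2 <= 0, na.rm = TRUE) ||
      any(amax_um2 <= 0, na.rm = TRUE) ||
      any(pore_depth_um <= 0, na.rm = TRUE)) {
    stop("stomatal density, pore area and pore depth must be positive")
  }
  d_m2    <- density_mm2 * 1e6    # mm^-2 -> m^-2
  amax_m2 <- amax_um2 * 1e-12     # um^2  -> m^2
  p_m     <- pore_depth_um * 1e-6 # um    -> m
  depth_term <- p_m + (pi / 2) * sqrt(amax_m2 / pi)
  (constants$dw / constants$v) * d_m2 * amax_m2 / depth_term
}

#' Per-leaf anatomical maximum conductance
#'
#' Computes the maximum pore area and anatomical maximum conductance for one
#' leaf. Pore length can be supplied either as the vector of per-stoma
#' measurements (the preferred route: each stoma's pore area is computed and
#' the areas averaged) or as a single pre-averaged leaf mean, in which case
#' the area is computed from the mean length and the result is flagged,
#' because the mean of squared lengths differs from the square of the mean.
#'
#' @param density_mm2 leaf-mean stomatal density, mm^-2.
#' @param pore_length_um pore length(s), um: either per-stoma measurements or
#'   one leaf mean.
#' @param guard_cell_width_um guard-cell width, um, used as the pore depth.
#' @param constants constant set from [eb_constants()].
#' @return A list of class `"gsmax_result"` with `amax_um2`, `pore_depth_um`,
#'   `gsmax` (mol m^-2 s^-1), and `provenance` (`"per_stoma"`, `"leaf_mean"`,
#'   or `"missing"` when any required trait is absent; then the numeric
#'   fields are `NA`, never zero).
#' @export
leaf_gsmax <- function(density_mm2, pore_length_um, guard_cell_width_um,
                       constants = eb_constants()) {
  missing_any <- length(pore_length_um) == 0L ||
    all(is.na(pore_length_um)) ||
    is.na(density_mm2) || is.na(guard_cell_width_um)
  if (missing_any) {
    out <- list(amax_um2 = NA_real_, pore_depth_um = NA_real_,
                gsmax = NA_real_, provenance = "missing")
    class(out) <- "gsmax_result"
    return(out)
  }
  lengths <- pore_length_um[!is.na(pore_length_um)]
  per_stoma <- length(lengths) > 1L
  amax <- mean(amax_from_pore_length(lengths))
  out <- list(
    amax_um2      = amax,
    pore_depth_um = guard_cell_width_um,
    gsmax         = gsmax(density_mm2, amax, guard_cell_width_um, constants),
    provenance    = if (per_stoma) "per_stoma" else "leaf_mean"
  )
  class(out) <- "gsmax_result"
  out
}

#' @export
print.gsmax_result <- function(x, ...) {
  cat("Anatomical maximum conductance\n")
  cat(sprintf("  a_max: %.3f um^2  pore depth: %.3f um  gsmax: %.4f mol m-2 s-1 [%s]\n",
              x$amax_um2, x$pore_depth_um, x$gsmax, x$provenance))
  invisible(x)
}

#' Append anatomical conductance columns to a specimen table
#'
#' Row-wise application of [leaf_gsmax()] to a specimen table. Specimens with
#' incomplete anatomy get `NA` (flagged absent, not zero).
#'
#' @param records specimen table (see [read_specimen_table()]).
#' @param constants constant set from [eb_constants()].
#' @return `records` with columns `amax_um2`, `gsmax_mol` (mol m^-2 s^-1)
#'   and `gsmax_mmol` (mmol m^-2 s^-1) appended.
#' @export
augment_gsmax <- function(records, constants = eb_constants()) {
  res <- lapply(seq_len(nrow(records)), function(i) {
    leaf_gsmax(records$stomatal_density[i], records$pore_length[i],
               records$guard_cell_width[i], constants)
  })
  records$amax_um2   <- vapply(res, `[[`, numeric(1), "amax_um2")
  records$gsmax_mol  <- vapply(res, `[[`, numeric(1), "gsmax")
  records$gsmax_mmol <- records$gsmax_mol * 1e3
  records
}
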