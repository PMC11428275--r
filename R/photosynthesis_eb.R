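# Empirical-biochemical gas-exchange engine: trait-based Vcmax prediction,
# Rubisco kinetics temperature scaling, and the coupled Rubisco-limited
# photosynthesis / Fickian diffusion solver.

arrhenius_scale <- function(t_c, ha, gas_const) {
  tk <- t_c + 273.15
  exp(ha * (tk - 298.15) / (298.15 * gas_const * tk))
}

#' Rubisco kinetics at leaf temperature
#'
#' Scales Vcmax, Kc, Ko and Gamma* from their 25 degC reference values to the
#' leaf temperature with Arrhenius functions (positive activation energies,
#' so every parameter increases with temperature). Day respiration is set to
#' `rd_frac * Vcmax` at leaf temperature.
#'
#' @param t_leaf leaf temperature, degC (0 < t_leaf < 50).
#' @param vcmax25 Vcmax at 25 degC, umol m^-2 s^-1 (vectorised).
#' @param constants constant set from [eb_constants()].
#' @return list of class `"kinetic_params"`: `vcmax`, `kc` (umol mol^-1),
#'   `ko` (mmol mol^-1), `gamma_star` (umol mol^-1), `km` (umol mol^-1,
#'   `kc * (1 + O/ko)`), `rd`, `oxygen`, `t_leaf`.
#' @export
#' @examples
#' kinetics_at(29, 66.8)
kinetics_at <- function(t_leaf, vcmax25, constants = eb_constants()) {
  if (t_leaf <= 0 || t_leaf >= 50) stop("t_leaf must be in (0, 50) degC")
  R <- constants$gas_const
  vcmax <- vcmax25 * arrhenius_scale(t_leaf, constants$ha_vcmax, R)
  kc <- constants$kc25 * arrhenius_scale(t_leaf, constants$ha_kc, R)
  ko <- constants$ko25 * arrhenius_scale(t_leaf, constants$ha_ko, R)
  gs25 <- constants$gamma_star25
  gamma_star <- gs25 * arrhenius_scale(t_leaf, constants$ha_gamma_star, R)
  out <- list(
    vcmax      = vcmax,
    kc         = kc,
    ko         = ko,
    gamma_star = gamma_star,
    km         = kc * (1 + constants$oxygen / ko),
    rd         = constants$rd_frac * vcmax,
    oxygen     = constants$oxygen,
    t_leaf     = t_leaf
  )
  class(out) <- "kinetic_params"
  out
}

#' Invert the temperature scaling of Vcmax
#'
#' Moves a Vcmax measured at `t_leaf` back to 25 degC; exact algebraic
#' inverse of the forward Arrhenius scaling in [kinetics_at()].
#'
#' @param vcmax_at_t Vcmax at `t_leaf`, umol m^-2 s^-1.
#' @param t_leaf measurement temperature, degC.
#' @param constants constant set from [eb_constants()].
#' @return Vcmax at 25 degC.
#' @export
vcmax_to_25 <- function(vcmax_at_t, t_leaf, constants = eb_constants()) {
  vcmax_at_t / arrhenius_scale(t_leaf, constants$ha_vcmax,
                               constants$gas_const)
}

#' One-point estimate of Vcmax from a gas-exchange measurement
#'
#' Under Rubisco limitation with `Rd = rd_frac * Vcmax`,
#' \deqn{V_{Cmax} = \frac{A}{(c_i - \Gamma^*)/(c_i + K_m) - rd_{frac}}}
#'
#' @param A net assimilation, umol m^-2 s^-1.
#' @param ci intercellular CO2, umol mol^-1; must exceed the compensation
#'   point far enough that the denominator is positive.
#' @param kinetics a [kinetics_at()] object at the measurement temperature.
#' @param constants constant set from [eb_constants()] (for `rd_frac`).
#' @return Vcmax at the measurement temperature, umol m^-2 s^-1.
#' @export
#' @examples
#' kin25 <- kinetics_at(25, 1)
#' vcmax_one_point(15, 280, kin25) # ~66.8
vcmax_one_point <- function(A, ci, kinetics, constants = eb_constants()) {
  denom <- (ci - kinetics$gamma_star) / (ci + kinetics$km) - constants$rd_frac
  if (any(denom <= 0)) {
    stop("measurement inconsistent with Rubisco limitation: ",
         "(ci - gamma*)/(ci + Km) - rd_frac must be positive")
  }
  A / denom
}

# -- trait model for Vcmax,25 -------------------------------------------------

#' Fit the trait-based Vcmax,25 model
#'
#' Fits the empirical mixed-effects model
#' \deqn{\ln V_{Cmax,25} = a \cdot \frac{1}{N_{area}} + b \cdot \ln SLA +
#'   c \cdot \frac{\ln SLA}{N_{area}} + d + (1|species)}
#' on a training set of leaves with known Vcmax,25 (umol m^-2 s^-1), SLA
#' (m^2 kg^-1) and N_area (g m^-2). The reciprocal and log transforms
#' normalise the trait distributions. With a single species (or when forced
#' with `mixed = FALSE`) a fixed-effects fit is used, with a warning in the
#' degenerate case. When `select = TRUE` the fixed- and mixed-effects
#' candidates are compared by maximum-likelihood AIC and the better one kept
#' (the mixed model itself is estimated by REML).
#'
#' @param training data.frame with columns `species`, `vcmax25`, `sla`,
#'   `n_area`.
#' @param mixed fit a species random intercept (default TRUE).
#' @param select choose between fixed and mixed candidates by AIC.
#' @return object of class `"vcmax_trait_model"`: coefficients `a, b, c, d`,
#'   `ranef` (named species intercepts, zero-length for fixed fits),
#'   `sigma_species`, `pseudo_r2` (squared correlation of fitted and observed
#'   ln Vcmax,25), `shapiro_p` (residual normality), `fit` (the underlying
#'   model object) and `mixed` flag.
#' @export
fit_vcmax_model <- function(training, mixed = TRUE, select = FALSE) {
  need <- c("species", "vcmax25", "sla", "n_area")
  if (!all(need %in% names(training))) {
    stop("training data must have columns: ", paste(need, collapse = ", "))
  }
  if (any(training$vcmax25 <= 0 | training$sla <= 0 | training$n_area <= 0)) {
    stop("vcmax25, sla and n_area must be positive")
  }
  dat <- data.frame(
    species = as.character(training$species),
    ln_vcmax = log(training$vcmax25),
    rec_narea = 1 / training$n_area,
    ln_sla = log(training$sla)
  )
  n_species <- length(unique(dat$species))
  use_mixed <- mixed && n_species >= 2
  if (mixed && n_species < 2) {
    warning("single species in training data: falling back to fixed effects")
  }
  fixed_fit <- stats::lm(ln_vcmax ~ rec_narea * ln_sla, data = dat)
  fit <- fixed_fit
  if (use_mixed) {
    mixed_fit <- lme4::lmer(
      ln_vcmax ~ rec_narea * ln_sla + (1 | species), data = dat, REML = TRUE)
    if (select) {
      # information-criterion comparison is done on full-likelihood refits
      ml_mixed <- lme4::lmer(ln_vcmax ~ rec_narea * ln_sla + (1 | species),
                             data = dat, REML = FALSE)
      use_mixed <- stats::AIC(ml_mixed) < stats::AIC(fixed_fit)
    }
    if (use_mixed) fit <- mixed_fit
  }
  if (inherits(fit, "merMod")) {
    beta <- lme4::fixef(fit)
    re <- lme4::ranef(fit)$species
    ranef_vec <- stats::setNames(re[["(Intercept)"]], rownames(re))
    sigma_species <- sqrt(as.numeric(lme4::VarCorr(fit)$species[1]))
    fitted_ln <- stats::fitted(fit)
    resid_ln <- stats::residuals(fit)
  } else {
    beta <- stats::coef(fit)
    ranef_vec <- stats::setNames(numeric(0), character(0))
    sigma_species <- 0
    fitted_ln <- stats::fitted(fit)
    resid_ln <- stats::residuals(fit)
  }
  shapiro_p <- if (length(resid_ln) >= 3 && stats::sd(resid_ln) > 0) {
    stats::shapiro.test(resid_ln)$p.value
  } else {
    NA_real_
  }
  out <- list(
    a = unname(beta["rec_narea"]),
    b = unname(beta["ln_sla"]),
    c = unname(beta["rec_narea:ln_sla"]),
    d = unname(beta["(Intercept)"]),
    ranef = ranef_vec,
    sigma_species = sigma_species,
    pseudo_r2 = stats::cor(fitted_ln, dat$ln_vcmax)^2,
    shapiro_p = shapiro_p,
    mixed = inherits(fit, "merMod"),
    fit = fit
  )
  class(out) <- "vcmax_trait_model"
  out
}

#' @export
print.vcmax_trait_model <- function(x, ...) {
  cat("Trait-based Vcmax,25 model (ln Vcmax,25 ~ 1/Narea * ln SLA",
      if (x$mixed) "+ (1|species)" else "", ")\n")
  cat(sprintf("  a = %.4f  b = %.4f  c = %.4f  d = %.4f\n", x$a, x$b, x$c, x$d))
  cat(sprintf("  species intercept SD = %.4f, pseudo-R2 = %.3f, residual normality p = %.3f\n",
              x$sigma_species, x$pseudo_r2, x$shapiro_p))
  invisible(x)
}

#' Predict Vcmax,25 from leaf traits
#'
#' Evaluates the trait model on the transformed scale and back-transforms.
#' Species present in the training set get their random intercept; unseen
#' species get the fixed part only.
#'
#' @param model a [fit_vcmax_model()] object.
#' @param n_area leaf nitrogen per area, g m^-2 (vectorised).
#' @param sla specific leaf area in the training units (m^2 kg^-1).
#' @param species species name(s), or `NA` for fixed-part predictions.
#' @return predicted Vcmax,25, umol m^-2 s^-1.
#' @export
predict_vcmax25 <- function(model, n_area, sla, species = NA_character_) {
  if (any(n_area <= 0, na.rm = TRUE) || any(sla <= 0, na.rm = TRUE)) {
    stop("n_area and sla must be positive")
  }
  rec <- 1 / n_area
  lsla <- log(sla)
  lp <- model$a * rec + model$b * lsla + model$c * rec * lsla + model$d
  re <- model$ranef[as.character(species)]
  re[is.na(re)] <- 0
  exp(lp + unname(re))
}

# -- conductance chain and coupled solver ------------------------------------

#' Operational stomatal conductance from the anatomical maximum
#'
#' @param gsmax anatomical maximum conductance, mol m^-2 s^-1 (vectorised).
#' @param ratio gs/gsmax ratio; default the field-calibrated mean 0.51.
#' @return operational conductance to water vapour, mol m^-2 s^-1.
#' @export
gs_from_gsmax <- function(gsmax, ratio = eb_constants()$gs_gsmax_ratio) {
  if (any(gsmax < 0, na.rm = TRUE)) stop("gsmax must be non-negative")
  ratio * gsmax
}

#' Total conductance to CO2 of a hypostomatous leaf
#'
#' Stomatal conductance to CO2 is `gs/1.6` (diffusivity ratio of H2O and CO2
#' in air); the boundary layer acts in series:
#' \deqn{g_t = \frac{g_c \, g_{cb}}{g_c + g_{cb}}}
#' Mesophyll conductance is treated as infinite.
#'
#' @param gs stomatal conductance to water vapour, mol m^-2 s^-1 (positive).
#' @param gcb boundary-layer conductance to CO2, mol m^-2 s^-1.
#' @return list with `gc` and `gt`, mol m^-2 s^-1.
#' @export
#' @examples
#' total_conductance(0.5) # gc = 0.3125, gt ~ 0.2703
total_conductance <- function(gs, gcb = eb_constants()$gcb) {
  if (any(gs <= 0, na.rm = TRUE)) stop("gs must be positive")
  gc <- gs / 1.6
  list(gc = gc, gt = gc * gcb / (gc + gcb))
}

#' Solve the coupled Rubisco-limited assimilation / diffusion system
#'
#' Substituting Fick's law `ci = ca - A/gt` into the Rubisco-limited rate
#' \eqn{A_c = V_{Cmax}(c_i - \Gamma^*)/(c_i + K_m) - R_d} yields
#' \deqn{A^2 - A\,[g_t(c_a + K_m) + V_{Cmax} - R_d] +
#'   g_t\,[V_{Cmax}(c_a - \Gamma^*) - R_d(c_a + K_m)] = 0}
#' The root giving an admissible intercellular CO2 (`ci < ca`, unique for
#' valid inputs) is returned; both returned equations hold to better than
#' 1e-9. Vectorised over `gt` and `ca` (kinetics are scalar per call).
#'
#' @param kinetics a [kinetics_at()] object (scalar `vcmax`).
#' @param gt total conductance to CO2, mol m^-2 s^-1.
#' @param ca ambient CO2, umol mol^-1; must exceed `gamma_star`.
#' @return list with vectors `A` (umol m^-2 s^-1) and `ci` (umol mol^-1).
#' @export
#' @examples
#' kin <- kinetics_at(29, 48.9)
#' solve_assimilation(kin, 0.27, 400)
solve_assimilation <- function(kinetics, gt, ca) {
  if (any(gt <= 0)) stop("gt must be positive")
  if (any(ca <= kinetics$gamma_star)) {
    stop("ca must exceed the CO2 compensation point")
  }
  vc <- kinetics$vcmax
  km <- kinetics$km
  gam <- kinetics$gamma_star
  rd <- kinetics$rd
  b <- gt * (ca + km) + vc - rd
  cc <- gt * (vc * (ca - gam) - rd * (ca + km))
  disc <- b^2 - 4 * cc
  if (any(disc < 0)) stop("no real root: inadmissible parameter combination")
  A <- (b - sqrt(disc)) / 2
  ci <- ca - A / gt
  bad <- ci >= ca + 1e-9 | !is.finite(A)
  if (any(bad)) stop("no admissible root with ci < ca")
  list(A = A, ci = ci)
}

#' RuBP-regeneration-limited assimilation rate
#'
#' \deqn{A_j = \frac{(c_i - \Gamma^*) J_{max}/4}{c_i + 2\Gamma^*} - R_d}
#' Provided for completeness of the `min(Ac, Aj)` formulation; the default
#' simulation path assumes Rubisco limitation, which holds under saturating
#' light at ambient CO2 of 400 umol mol^-1 or below.
#'
#' @param ci intercellular CO2, umol mol^-1.
#' @param jmax maximum electron-transport rate, umol m^-2 s^-1 (positive).
#' @param kinetics a [kinetics_at()] object (for `gamma_star` and `rd`).
#' @return assimilation rate, umol m^-2 s^-1.
#' @export
aj_rate <- function(ci, jmax, kinetics) {
  if (any(jmax <= 0)) stop("jmax must be positive")
  (ci - kinetics$gamma_star) * (jmax / 4) / (ci + 2 * kinetics$gamma_star) -
    kinetics$rd
}

#' Per-specimen empirical-biochemical simulation
#'
#' For every specimen with a complete set of `gsmax_mol`, `lma` and `n_area`:
#' predict Vcmax,25 from traits, scale kinetics to the operational leaf
#' temperature, set `gs = ratio * gsmax`, compute the total conductance, and
#' solve the coupled system at the collection year's ambient CO2. The
#' simulated iWUE is `A/gs`. Incomplete specimens are skipped and counted;
#' solver failures flag the specimen and the pipeline continues.
#'
#' @param records specimen table augmented with `gsmax_mol`
#'   (see [augment_gsmax()]).
#' @param atmosphere an [atmosphere_series()].
#' @param model a [fit_vcmax_model()] object.
#' @param constants constant set from [eb_constants()].
#' @return data.frame with one row per simulated specimen: `specimen_id`,
#'   `species`, `year`, `ca`, `vcmax25`, `vcmax_tl`, `gs`, `gc`, `gt`, `A`,
#'   `ci`, `iwue`, logical `solver_ok`. Attribute `n_skipped` counts
#'   incomplete specimens.
#' @export
eb_simulate <- function(records, atmosphere, model,
                        constants = eb_constants()) {
  complete <- !is.na(records$gsmax_mol) & !is.na(records$lma) &
    !is.na(records$n_area) & records$gsmax_mol > 0
  skipped <- sum(!complete)
  rec <- records[complete, , drop = FALSE]
  if (!nrow(rec)) {
    out <- data.frame()
    attr(out, "n_skipped") <- skipped
    return(out)
  }
  atm <- atmosphere_lookup(atmosphere, rec$year)
  vcmax25 <- predict_vcmax25(model, rec$n_area, 1000 / rec$lma, rec$species)
  gs <- gs_from_gsmax(rec$gsmax_mol, constants$gs_gsmax_ratio)
  g <- total_conductance(gs, constants$gcb)
  n <- nrow(rec)
  A <- ci <- rep(NA_real_, n)
  ok <- rep(FALSE, n)
  vcmax_tl <- vcmax25 *
    arrhenius_scale(constants$t_leaf, constants$ha_vcmax, constants$gas_const)
  for (i in seq_len(n)) {
    kin <- kinetics_at(constants$t_leaf, vcmax25[i], constants)
    sol <- tryCatch(solve_assimilation(kin, g$gt[i], atm$ca[i]),
                    error = function(e) NULL)
    if (!is.null(sol)) {
      A[i] <- sol$A
      ci[i] <- sol$ci
      ok[i] <- TRUE
    }
  }
  out <- data.frame(
    specimen_id = rec$specimen_id,
    species = rec$species,
    year = rec$year,
    ca = atm$ca,
    vcmax25 = vcmax25,
    vcmax_tl = vcmax_tl,
    gs = gs,
    gc = g$gc,
    gt = g$gt,
    A = A,
    ci = ci,
    iwue = A / gs,
    solver_ok = ok,
    stringsAsFactors = FALSE
  )
  attr(out, "n_skipped") <- skipped
  out
}
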