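# Monte-Carlo propagation of intraspecific gsmax regression uncertainty into
# simulated response slopes. The species-level regression gsmax ~ ca is
# fitted by OLS; 10,000 coefficient pairs are drawn from the multivariate
# normal sampling distribution of the estimates; each draw defines an annual
# gsmax trajectory that parameterises the gas-exchange engine; per-draw
# response slopes against ca yield equal-tailed 95% quantile intervals.

#' Species-level regression of anatomical maximum conductance on CO2
#'
#' Ordinary least squares of specimen-level gsmax on the collection-year
#' ambient CO2. Specimens are the empirical unit; no annual averaging.
#'
#' @param gsmax specimen gsmax, mol m^-2 s^-1.
#' @param ca year-matched ambient CO2, ppm.
#' @return list of class `"gsmax_fit"`: `coef` (intercept, slope), `vcov`
#'   (2x2 sampling covariance), `sigma`, `n`, `r2`, `p_slope`.
#' @export
fit_gsmax_regression <- function(gsmax, ca) {
  keep <- !is.na(gsmax) & !is.na(ca)
  gsmax <- gsmax[keep]
  ca <- ca[keep]
  if (length(gsmax) < 3) stop("need at least 3 specimens with gsmax")
  if (length(unique(ca)) < 2) {
    stop("rank-deficient design: all specimens share one ca value")
  }
  fit <- stats::lm(gsmax ~ ca)
  sm <- suppressWarnings(summary(fit)) # noise-free inputs fit perfectly
  out <- list(
    coef = stats::coef(fit),
    vcov = suppressWarnings(stats::vcov(fit)),
    sigma = sm$sigma,
    n = length(gsmax),
    r2 = sm$r.squared,
    p_slope = sm$coefficients["ca", "Pr(>|t|)"]
  )
  class(out) <- "gsmax_fit"
  out
}

#' Sample regression coefficients from their sampling distribution
#'
#' Draws `n_draws` (intercept, slope) pairs from the multivariate normal
#' distribution with mean the OLS point estimates and covariance their
#' sampling covariance. Reproducible under a fixed seed; a zero covariance
#' collapses every draw onto the point estimates.
#'
#' @param fit a [fit_gsmax_regression()] object (or any list with `coef` and
#'   `vcov`).
#' @param n_draws number of draws (default 10000).
#' @param seed integer seed.
#' @return list of class `"coefficient_draws"`: `draws` (n_draws x 2 matrix,
#'   columns `intercept`, `slope`), `coef`, `vcov`, `n_draws`, `seed`.
#' @export
sample_coefficients <- function(fit, n_draws = 10000, seed = 1) {
  sigma <- as.matrix(fit$vcov)
  if (any(eigen(sigma, symmetric = TRUE, only.values = TRUE)$values < -1e-8)) {
    stop("coefficient covariance is not positive semi-definite")
  }
  set.seed(seed)
  draws <- MASS::mvrnorm(n_draws, mu = fit$coef, Sigma = sigma)
  draws <- matrix(draws, ncol = 2,
                  dimnames = list(NULL, c("intercept", "slope")))
  out <- list(draws = draws, coef = fit$coef, vcov = sigma,
              n_draws = n_draws, seed = seed)
  class(out) <- "coefficient_draws"
  out
}

#' Annual gsmax trajectories implied by coefficient draws
#'
#' Evaluates `gsmax(year) = intercept + slope * ca(year)` for every draw.
#' Draws that imply a non-positive gsmax in some year are floored at a small
#' positive value and counted (the ensemble size stays fixed; rejection
#' would bias the sample).
#'
#' @param draws a [sample_coefficients()] object.
#' @param atmosphere an [atmosphere_series()].
#' @param years years to evaluate (within coverage).
#' @param floor floor for non-positive trajectories, mol m^-2 s^-1.
#' @return matrix (n_draws x length(years)) of gsmax, with attributes
#'   `years`, `ca` and `n_floored` (number of draws touched by the floor).
#' @export
gsmax_trajectories <- function(draws, atmosphere, years, floor = 1e-3) {
  ca <- atmosphere_lookup(atmosphere, years)$ca
  traj <- draws$draws[, "intercept"] %o% rep(1, length(years)) +
    draws$draws[, "slope"] %o% ca
  floored <- traj < floor
  traj[floored] <- floor
  attr(traj, "years") <- years
  attr(traj, "ca") <- ca
  attr(traj, "n_floored") <- sum(apply(floored, 1, any))
  traj
}

#' Run the gas-exchange engine over a trajectory ensemble
#'
#' For each draw and year: `gs = ratio * gsmax(year)`, total conductance,
#' and the coupled Rubisco-limited solution at that year's ambient CO2;
#' `iwue = A/gs`. The engine is parameterised with species-mean traits
#' through a single Vcmax,25 value. Draw-years whose solver fails flag the
#' whole draw; flagged draws are excluded from downstream quantiles and
#' counted.
#'
#' @param trajectories matrix from [gsmax_trajectories()].
#' @param vcmax25 species-mean Vcmax,25, umol m^-2 s^-1.
#' @param constants constant set from [eb_constants()].
#' @return list of class `"eb_ensemble"`: matrices `gs`, `A`, `iwue`
#'   (draws x years), `ca`, `years`, logical `ok` per draw, `n_failed`.
#' @export
run_ensemble <- function(trajectories, vcmax25, constants = eb_constants()) {
  ca <- attr(trajectories, "ca")
  years <- attr(trajectories, "years")
  kin <- kinetics_at(constants$t_leaf, vcmax25, constants)
  gs <- constants$gs_gsmax_ratio * trajectories
  gc <- gs / 1.6
  gt <- gc * constants$gcb / (gc + constants$gcb)
  ca_m <- matrix(ca, nrow = nrow(gs), ncol = length(ca), byrow = TRUE)
  # vectorised quadratic over the full draws x years matrix
  b <- gt * (ca_m + kin$km) + kin$vcmax - kin$rd
  cc <- gt * (kin$vcmax * (ca_m - kin$gamma_star) - kin$rd * (ca_m + kin$km))
  disc <- b^2 - 4 * cc
  A <- (b - sqrt(pmax(disc, 0))) / 2
  ci <- ca_m - A / gt
  bad <- disc < 0 | !is.finite(A) | ci >= ca_m + 1e-9
  ok <- !apply(bad, 1, any)
  out <- list(gs = gs, A = A, iwue = A / gs, ci = ci, ca = ca, years = years,
              ok = ok, n_failed = sum(!ok))
  class(out) <- "eb_ensemble"
  out
}

# per-row OLS slope of y (matrix, rows = draws) on x
.row_slopes <- function(y, x) {
  xc <- x - mean(x)
  (y %*% xc) / sum(xc^2)
}

#' Quantile confidence intervals on ensemble response slopes
#'
#' Regresses each draw's annual iWUE, A and gs series on ambient CO2 and
#' summarises the per-draw slopes (delta2 = d iWUE/d ca, gamma2 = d A/d ca,
#' eta2 = d gs/d ca) by their mean and equal-tailed 2.5/97.5 percentile
#' interval across draws.
#'
#' @param ensemble a [run_ensemble()] object.
#' @return list of class `"ensemble_response"` with one component per
#'   response (`delta2`, `gamma2`, `eta2`), each a list of `mean`, `lo`,
#'   `hi`, `slopes` (per-draw vector); plus `n_draws_used`.
#' @export
summarize_responses <- function(ensemble) {
  if (length(ensemble$ca) < 2) stop("need at least 2 years per draw")
  keep <- ensemble$ok
  summ <- function(y) {
    s <- as.numeric(.row_slopes(y[keep, , drop = FALSE], ensemble$ca))
    qq <- stats::quantile(s, c(0.025, 0.975), names = FALSE)
    list(mean = mean(s), lo = qq[1], hi = qq[2], slopes = s)
  }
  out <- list(
    delta2 = summ(ensemble$iwue),
    gamma2 = summ(ensemble$A),
    eta2   = summ(ensemble$gs),
    n_draws_used = sum(keep)
  )
  class(out) <- "ensemble_response"
  out
}

#' @export
print.ensemble_response <- function(x, ...) {
  cat("Monte-Carlo ensemble response slopes (mean [2.5%, 97.5%])\n")
  fmt <- function(nm, s) {
    cat(sprintf("  %-22s %.5f [%.5f, %.5f]\n", nm, s$mean, s$lo, s$hi))
  }
  fmt("d iWUE / d ca (delta2)", x$delta2)
  fmt("d A / d ca (gamma2)", x$gamma2)
  fmt("d gs / d ca (eta2)", x$eta2)
  cat(sprintf("  draws used: %d\n", x$n_draws_used))
  invisible(x)
}

#' Full Monte-Carlo uncertainty propagation for one or more species
#'
#' Convenience wrapper chaining [fit_gsmax_regression()],
#' [sample_coefficients()], [gsmax_trajectories()], [run_ensemble()] and
#' [summarize_responses()] per species.
#'
#' @param records specimen table augmented with `gsmax_mol`, `lma`, `n_area`.
#' @param atmosphere an [atmosphere_series()].
#' @param model a [fit_vcmax_model()] object (species-mean traits feed
#'   through it to a per-species Vcmax,25).
#' @param n_draws draws per species (default 10000).
#' @param seed integer seed; per-species seeds are derived deterministically.
#' @param years years to simulate; defaults to the full atmosphere coverage.
#' @param constants constant set from [eb_constants()].
#' @return data.frame, one row per species x response, with columns
#'   `species`, `response`, `mean`, `lo`, `hi`, `n_draws_used`, `seed`;
#'   attribute `details` holds the per-species `ensemble_response` objects.
#' @export
mc_species_responses <- function(records, atmosphere, model,
                                 n_draws = 10000, seed = 1, years = NULL,
                                 constants = eb_constants()) {
  if (is.null(years)) years <- atmosphere$year
  species <- sort(unique(records$species))
  details <- list()
  rows <- list()
  for (k in seq_along(species)) {
    sp <- species[k]
    rec <- records[records$species == sp, , drop = FALSE]
    ca <- atmosphere_lookup(atmosphere, rec$year)$ca
    fit <- fit_gsmax_regression(rec$gsmax_mol, ca)
    draws <- sample_coefficients(fit, n_draws = n_draws,
                                 seed = seed + k - 1L)
    traj <- gsmax_trajectories(draws, atmosphere, years)
    vcmax25 <- predict_vcmax25(model,
                               mean(rec$n_area, na.rm = TRUE),
                               1000 / mean(rec$lma, na.rm = TRUE),
                               sp)
    ens <- run_ensemble(traj, vcmax25, constants)
    resp <- summarize_responses(ens)
    details[[sp]] <- resp
    rows[[sp]] <- do.call(rbind, lapply(
      c("delta2", "gamma2", "eta2"),
      function(r) data.frame(species = sp, response = r,
                             mean = resp[[r]]$mean, lo = resp[[r]]$lo,
                             hi = resp[[r]]$hi,
                             n_draws_used = resp$n_draws_used,
                             seed = draws$seed,
                             stringsAsFactors = FALSE)))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "details") <- details
  out
}
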