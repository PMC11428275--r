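# Synthetic herbarium-community generator. The defaults emulate the study
# conditions the analysis targets: five tropical evergreen tree species
# sampled from herbarium sheets between 1927 and 2015 over a ~95 ppm rise in
# ambient CO2, with species-specific linear trait trends against CO2, strong
# intraspecific scatter, and sparser collection effort in early decades.
#
# Archetypes (calibrated once, see the methods vignette):
#  * two responders whose stomatal density declines at the published rates
#    (-3.52 and -0.76 mm^-2 ppm^-1), which propagate through the conductance
#    equation to gsmax trends of about -6.2 and -1.7 mmol m^-2 s^-1 ppm^-1,
#    with constant ci/ca targets giving iWUE slopes ~0.17 and ~0.14;
#  * two species with flat stomatal anatomy but constant ci/ca, so iWUE still
#    rises (~0.13-0.14 umol mol^-1 ppm^-1);
#  * one non-responder with a slight pore-area increase and a drifting ci/ca
#    target that keeps its iWUE flat.

#' Default coefficients of the synthetic Vcmax,25 trait model
#'
#' Coefficients of `ln Vcmax25 = a/N_area + b ln SLA + c (ln SLA)/N_area + d`
#' (SLA in m^2 kg^-1, N_area in g m^-2) used by the training-set generator.
#' Calibrated so the five default species' mean traits map onto Vcmax,25
#' values whose simulated assimilation sits near the species' field-measured
#' rates (15/13/14/9/9 umol m^-2 s^-1).
#'
#' @return named numeric vector with elements `a`, `b`, `c`, `d`.
#' @export
default_vcmax_coefs <- function() {
  c(a = -0.901, b = 0.427, c = -0.494, d = 3.901)
}

#' Default species configurations for the synthetic community
#'
#' Returns the five species archetypes. Trait baselines are anchored at
#' 300 ppm; trends are per ppm of CO2. Noise entries are log-normal relative
#' SDs per trait (delta-13C noise is additive, permil).
#'
#' @return named list of species configurations, each a list with elements
#'   `species`, `n`, `d0`, `d_trend` (stomatal density mm^-2 and mm^-2
#'   ppm^-1), `l0`, `l_trend` (pore length um, um ppm^-1), `p0` (guard-cell
#'   width um), `lma0` (g m^-2), `narea0` (g m^-2), `cica0`, `cica_trend`
#'   (ci/ca target and its per-ppm drift), and `noise`.
#' @export
default_species_configs <- function() {
  noise <- list(d = 0.12, l = 0.06, p = 0.04, lma = 0.10, narea = 0.10,
                d13c = 0.8)
  cfg <- function(species, n, d0, d_trend, l0, l_trend, p0, lma0, narea0,
                  cica0, cica_trend) {
    list(species = species, n = n, d0 = d0, d_trend = d_trend, l0 = l0,
         l_trend = l_trend, p0 = p0, lma0 = lma0, narea0 = narea0,
         cica0 = cica0, cica_trend = cica_trend, noise = noise)
  }
  list(
    # strong responder: D and gsmax decline, strongest iWUE gain
    `Amaroria soulameoides` = cfg("Amaroria soulameoides", 50,
                                  740, -3.52, 5.0, 0, 3.4, 110, 2.4,
                                  0.728, 0),
    # moderate responder
    `Dillenia biflora` = cfg("Dillenia biflora", 50,
                             250, -0.76, 6.5, 0, 4.6, 130, 2.2,
                             0.776, 0),
    # iWUE-only responders: flat anatomy, constant ci/ca
    `Astronidium confertiflorum` = cfg("Astronidium confertiflorum", 49,
                                       450, 0, 5.5, 0, 3.5, 100, 2.0,
                                       0.776, 0),
    `Gnetum gnemon` = cfg("Gnetum gnemon", 49,
                          90, 0, 18.0, 0, 6.0, 140, 1.6,
                          0.792, 0),
    # non-responder: slight pore enlargement, ci/ca drifts so iWUE stays flat
    `Elattostachys falcata` = cfg("Elattostachys falcata", 48,
                                  653, 0, 6.0, 0.002, 4.0, 150, 1.5,
                                  0.700, (1 - 0.700) / 404)
  )
}

#' Generate an annual atmosphere series
#'
#' Ambient CO2 follows a monotone piecewise-exponential rise (an exponential
#' excess over a fixed pre-industrial-like floor, anchored at the start and
#' end values); atmospheric delta-13C declines linearly. The defaults emulate
#' the 1927-2015 rise from ~305 to ~400 ppm.
#'
#' @param years consecutive years.
#' @param ca_start,ca_end ambient CO2 at the first and last year, ppm.
#' @param d13c_start,d13c_end atmospheric delta-13C endpoints, permil.
#' @return an [atmosphere_series()].
#' @export
#' @examples
#' atm <- generate_atmosphere()
#' range(atm$ca) # ~305 to ~400
generate_atmosphere <- function(years = 1927:2015,
                                ca_start = 305.6, ca_end = 399.6,
                                d13c_start = -6.70, d13c_end = -8.44) {
  if (length(years) < 2) stop("need at least two years")
  t <- seq_along(years) - 1
  span <- max(t)
  if (abs(ca_end - ca_start) < 1e-12) {
    ca <- rep(ca_start, length(years))
  } else if (ca_end > ca_start) {
    floor_ca <- ca_start - 25.6
    k <- log((ca_end - floor_ca) / (ca_start - floor_ca)) / span
    ca <- floor_ca + (ca_start - floor_ca) * exp(k * t)
  } else {
    ca <- ca_start + (ca_end - ca_start) * t / span
  }
  d13c <- d13c_start + (d13c_end - d13c_start) * t / span
  atmosphere_series(years, ca, d13c)
}

# multiplicative log-normal noise with unit mean
.lnoise <- function(n, sdlog) {
  if (sdlog == 0) return(rep(1, n))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

#' Generate a synthetic herbarium community
#'
#' Draws collection years with a linearly increasing effort profile (early
#' decades under-sampled, as in herbarium archives), evaluates each species'
#' linear trait trends at the year-matched CO2, applies multiplicative
#' log-normal intraspecific noise, and back-computes leaf delta-13C from the
#' species' ci/ca target trajectory by inverting the discrimination chain,
#' plus additive Gaussian isotopic noise. A white-noise mean-annual
#' precipitation column is included for variance-partition analyses.
#'
#' @param configs species configurations ([default_species_configs()]).
#' @param atmosphere an [atmosphere_series()].
#' @param seed integer seed.
#' @param effort_range relative collection effort at the first and last year
#'   (linear ramp in between).
#' @return a specimen table ([read_specimen_table()] schema) with an extra
#'   `map_mm` column; passes [validate_records()] with zero rejections.
#' @export
#' @examples
#' atm <- generate_atmosphere()
#' community <- generate_community(atmosphere = atm, seed = 1)
#' nrow(community) # 246
generate_community <- function(configs = default_species_configs(),
                               atmosphere = generate_atmosphere(),
                               seed = 1, effort_range = c(0.3, 1)) {
  set.seed(seed)
  weights <- seq(effort_range[1], effort_range[2],
                 length.out = nrow(atmosphere))
  ca_all <- atmosphere$ca
  tables <- lapply(configs, function(cf) {
    # a trend that drives a trait non-positive anywhere in the covered CO2
    # range is a configuration error, not a data point
    det <- function(base, trend) base + trend * (ca_all - 300)
    for (tr in list(det(cf$d0, cf$d_trend), det(cf$l0, cf$l_trend))) {
      if (any(tr <= 0)) {
        stop("trend drives a trait non-positive within the year range for ",
             cf$species)
      }
    }
    n <- cf$n
    year <- sample(atmosphere$year, n, replace = TRUE, prob = weights)
    atm <- atmosphere_lookup(atmosphere, year)
    ca <- atm$ca
    d <- (cf$d0 + cf$d_trend * (ca - 300)) * .lnoise(n, cf$noise$d)
    l <- (cf$l0 + cf$l_trend * (ca - 300)) * .lnoise(n, cf$noise$l)
    p <- cf$p0 * .lnoise(n, cf$noise$p)
    lma <- cf$lma0 * .lnoise(n, cf$noise$lma)
    narea <- cf$narea0 * .lnoise(n, cf$noise$narea)
    # invert the discrimination chain from the ci/ca target
    r <- cf$cica0 + cf$cica_trend * (ca - 300)
    delta <- 4.4 + (27 - 4.4) * r
    d13c <- (atm$d13c_air - delta) / (1 + delta / 1000) +
      stats::rnorm(n, 0, cf$noise$d13c)
    data.frame(
      specimen_id = sprintf("%s_%03d", gsub("[^A-Za-z]", "", cf$species), 1:n),
      species = cf$species,
      year = year,
      stomatal_density = d,
      pore_length = l,
      guard_cell_width = p,
      delta13c = d13c,
      lma = lma,
      n_area = narea,
      map_mm = stats::rnorm(n, 2500, 350),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, tables)
  rownames(out) <- NULL
  out
}

#' Generate a synthetic training set for the Vcmax trait model
#'
#' Leaves from `n_species` species (including, by default, the five focal
#' community species with their mean traits) with Vcmax,25 generated exactly
#' from the synthetic trait model plus a species random intercept and
#' residual noise on the log scale.
#'
#' @param n_species total number of species.
#' @param n_per leaves per species.
#' @param coefs trait-model coefficients ([default_vcmax_coefs()]).
#' @param sd_species SD of the species random intercept (log scale).
#' @param sd_resid residual SD (log scale).
#' @param seed integer seed.
#' @param configs focal species configurations to include.
#' @return data.frame with columns `species`, `vcmax25`, `sla` (m^2 kg^-1),
#'   `n_area` (g m^-2).
#' @export
generate_vcmax_training <- function(n_species = 20, n_per = 4,
                                    coefs = default_vcmax_coefs(),
                                    sd_species = 0.10, sd_resid = 0.08,
                                    seed = 1,
                                    configs = default_species_configs()) {
  set.seed(seed)
  focal <- data.frame(
    species = vapply(configs, `[[`, character(1), "species"),
    lma = vapply(configs, `[[`, numeric(1), "lma0"),
    narea = vapply(configs, `[[`, numeric(1), "narea0"),
    stringsAsFactors = FALSE
  )
  n_extra <- max(0, n_species - nrow(focal))
  extra <- data.frame(
    species = sprintf("aux_species_%02d", seq_len(n_extra)),
    lma = stats::runif(n_extra, 60, 180),
    narea = stats::runif(n_extra, 1.2, 2.8),
    stringsAsFactors = FALSE
  )
  sp <- rbind(focal, extra)[seq_len(min(n_species, nrow(focal) + n_extra)), ]
  sp$intercept <- stats::rnorm(nrow(sp), 0, sd_species)
  rows <- lapply(seq_len(nrow(sp)), function(i) {
    lma <- sp$lma[i] * .lnoise(n_per, 0.08)
    narea <- sp$narea[i] * .lnoise(n_per, 0.08)
    sla <- 1000 / lma
    ln_vc <- coefs["a"] / narea + coefs["b"] * log(sla) +
      coefs["c"] * log(sla) / narea + coefs["d"] +
      sp$intercept[i] + stats::rnorm(n_per, 0, sd_resid)
    data.frame(species = sp$species[i], vcmax25 = exp(ln_vc),
               sla = sla, n_area = narea, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Generate two stomatal-trait communities with controlled overlap
#'
#' Builds two synthetic plant communities in the (log amax, log D) plane:
#' each community is a mixture of species clusters around a community
#' centroid, and the centroids are displaced in inverse proportion to the
#' `overlap` control (1 = identically distributed, 0 = far-separated).
#'
#' @param overlap value in [0, 1].
#' @param seed integer seed.
#' @param n_a,n_b specimens per community.
#' @param k_a,k_b species clusters per community.
#' @return list with data.frames `a` and `b`, each with columns `species`,
#'   `amax_um2`, `density_mm2`.
#' @export
generate_two_communities <- function(overlap, seed = 1, n_a = 200, n_b = 200,
                                     k_a = 5, k_b = 8) {
  if (overlap < 0 || overlap > 1) stop("overlap must be in [0, 1]")
  set.seed(seed)
  shift <- (1 - overlap) * 3
  centre_a <- c(log(40), log(300))
  centre_b <- centre_a + shift * c(1, -1) / sqrt(2)
  one <- function(centre, k, n, tag) {
    centres <- cbind(stats::rnorm(k, centre[1], 0.35),
                     stats::rnorm(k, centre[2], 0.35))
    sp <- sample.int(k, n, replace = TRUE)
    data.frame(
      species = sprintf("%s_sp%02d", tag, sp),
      amax_um2 = exp(stats::rnorm(n, centres[sp, 1], 0.25)),
      density_mm2 = exp(stats::rnorm(n, centres[sp, 2], 0.25)),
      stringsAsFactors = FALSE
    )
  }
  list(a = one(centre_a, k_a, n_a, "a"), b = one(centre_b, k_b, n_b, "b"))
}
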