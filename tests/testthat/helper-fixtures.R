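# Shared fixtures, built in code: a linear toy atmosphere and a tiny
# specimen table. All oracles that need them re-derive values step by step.

helper_atmosphere <- function() {
  atmosphere_series(1927:2015,
                    ca = seq(305, 400, length.out = 89),
                    d13c_air = seq(-6.8, -8.4, length.out = 89))
}

helper_specimens <- function() {
  data.frame(
    specimen_id = c("s1", "s2", "s3"),
    species = c("alpha", "alpha", "beta"),
    year = c(1950, 1990, 2015),
    stomatal_density = c(310, 280, 120),
    pore_length = c(21.5, 20.0, 18.0),
    guard_cell_width = c(5.0, 4.8, 6.0),
    delta13c = c(-27.0, NA, -28.0),
    lma = c(110, 120, NA),
    n_area = c(2.1, 2.3, 1.8),
    stringsAsFactors = FALSE
  )
}

# independent SI-step evaluation of the anatomical conductance equation,
# kept deliberately separate from the package implementation
helper_gsmax_oracle <- function(d_mm2, amax_um2, p_um) {
  dw <- 2.49e-5
  v <- 2.24e-2
  numerator <- (d_mm2 * 1e6) * (amax_um2 * 1e-12)
  denominator <- (p_um * 1e-6) + (pi / 2) * sqrt((amax_um2 * 1e-12) / pi)
  (dw / v) * numerator / denominator
}

# bisection on the scalar balance f(ci) = gt (ca - ci) - Ac(ci); independent
# oracle for the quadratic solver
helper_bisect_assimilation <- function(vcmax, km, gamma_star, rd, gt, ca,
                                       tol = 1e-12) {
  f <- function(ci) gt * (ca - ci) - (vcmax * (ci - gamma_star) /
                                        (ci + km) - rd)
  lo <- 0
  hi <- ca
  if (f(lo) * f(hi) > 0) lo <- -km + 1e-9 # dark leaf: ci can exceed ca
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (f(lo) * f(mid) <= 0) hi <- mid else lo <- mid
    if (hi - lo < tol) break
  }
  ci <- (lo + hi) / 2
  list(A = gt * (ca - ci), ci = ci)
}
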