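test_that("temperature scaling is the identity at 25 C, increasing, invertible", {
  kin25 <- kinetics_at(25, 60)
  expect_equal(kin25$vcmax, 60)
  expect_equal(kin25$kc, 404.9)
  expect_equal(kin25$ko, 278.4)
  expect_equal(kin25$gamma_star, 42.75)
  expect_equal(kin25$rd, 0.015 * 60)
  expect_gt(kin25$km, kin25$gamma_star)

  kin29 <- kinetics_at(29, 60)
  expect_true(kin29$vcmax > kin25$vcmax)
  expect_true(kin29$kc > kin25$kc)
  expect_true(kin29$ko > kin25$ko)
  expect_true(kin29$gamma_star > kin25$gamma_star)

  # 25 -> 29 -> 25 algebraic round trip
  expect_equal(vcmax_to_25(kin29$vcmax, 29), 60, tolerance = 1e-12)
  expect_error(kinetics_at(60, 60), "0, 50")
})

test_that("one-point Vcmax inverts the Rubisco-limited rate", {
  kin25 <- kinetics_at(25, 1) # only kc/ko/gamma_star are used
  km <- 404.9 * (1 + 210 / 278.4)
  oracle <- 15 / ((280 - 42.75) / (280 + km) - 0.015)
  expect_equal(vcmax_one_point(15, 280, kin25), oracle, tolerance = 1e-12)
  expect_equal(vcmax_one_point(15, 280, kin25), 66.8, tolerance = 1e-3)
  expect_equal(vcmax_one_point(0, 280, kin25), 0)
  expect_error(vcmax_one_point(15, 42.75, kin25), "Rubisco")
})

test_that("trait model recovers known coefficients and random-intercept variance", {
  set.seed(101)
  coefs <- c(a = -0.9, b = 0.45, c = -0.5, d = 3.9)
  make_data <- function(n_sp, n_per, sd_sp, sd_resid) {
    sp <- sprintf("sp%02d", seq_len(n_sp))
    intercepts <- rnorm(n_sp, 0, sd_sp)
    do.call(rbind, lapply(seq_len(n_sp), function(i) {
      n_area <- runif(n_per, 1.2, 2.8)
      sla <- runif(n_per, 5, 16)
      ln_vc <- coefs["a"] / n_area + coefs["b"] * log(sla) +
        coefs["c"] * log(sla) / n_area + coefs["d"] +
        intercepts[i] + rnorm(n_per, 0, sd_resid)
      data.frame(species = sp[i], vcmax25 = exp(ln_vc), sla = sla,
                 n_area = n_area)
    }))
  }
  # noise-free, fixed-effects-only data: coefficients to numerical precision
  exact <- make_data(6, 10, 0, 0)
  fit <- fit_vcmax_model(exact, mixed = FALSE)
  expect_equal(c(a = fit$a, b = fit$b, c = fit$c, d = fit$d), coefs,
               tolerance = 1e-6)
  # interpolation consistency on a training point
  expect_equal(predict_vcmax25(fit, exact$n_area[1], exact$sla[1]),
               exact$vcmax25[1], tolerance = 1e-6)

  # species intercepts N(0, 0.1^2), 20 leaves/species: variance within 50%
  noisy <- make_data(12, 20, 0.1, 0.05)
  mfit <- fit_vcmax_model(noisy)
  expect_true(mfit$mixed)
  expect_gt(mfit$sigma_species, 0.05)
  expect_lt(mfit$sigma_species, 0.15)
  expect_gt(mfit$pseudo_r2, 0.8)

  # training-set species get their intercept; unseen species the fixed part
  pred_seen <- predict_vcmax25(mfit, 2, 10, "sp01")
  pred_unseen <- predict_vcmax25(mfit, 2, 10, "never_seen")
  fixed_part <- exp(mfit$a / 2 + mfit$b * log(10) +
                      mfit$c * log(10) / 2 + mfit$d)
  expect_equal(pred_unseen, fixed_part, tolerance = 1e-12)
  expect_equal(pred_seen, fixed_part * exp(mfit$ranef[["sp01"]]),
               tolerance = 1e-12)

  # degenerate single-species design falls back with a warning
  expect_warning(single <- fit_vcmax_model(make_data(1, 8, 0, 0.05)),
                 "single species")
  expect_false(single$mixed)
  expect_error(predict_vcmax25(mfit, -1, 10), "positive")
})

test_that("intercept-only models predict a constant", {
  flat <- structure(list(a = 0, b = 0, c = 0, d = log(50),
                         ranef = stats::setNames(numeric(0), character(0))),
                    class = "vcmax_trait_model")
  expect_equal(predict_vcmax25(flat, 1.7, 12.3), 50)
  expect_equal(predict_vcmax25(flat, 2.9, 6.1, "anything"), 50)
})

test_that("conductance chain follows the series-resistance formulation", {
  expect_equal(gs_from_gsmax(1.0), 0.51)
  expect_equal(gs_from_gsmax(0), 0)
  expect_equal(gs_from_gsmax(0.8, ratio = 1), 0.8)

  tc <- total_conductance(0.5)
  expect_equal(tc$gc, 0.3125)
  expect_equal(tc$gt, 0.3125 * 2 / 2.3125, tolerance = 1e-12)
  tc16 <- total_conductance(1.6)
  expect_equal(tc16$gc, 1)
  expect_equal(tc16$gt, 2 / 3, tolerance = 1e-12)
  # infinite boundary layer: gt -> gc
  expect_equal(total_conductance(0.5, gcb = 1e9)$gt, 0.3125,
               tolerance = 1e-6)
  expect_error(total_conductance(0), "positive")
})

test_that("the quadratic solver agrees with bisection and satisfies both laws", {
  kin <- structure(list(vcmax = 66.8, km = 710.3, gamma_star = 42.75,
                        rd = 1.002), class = "kinetic_params")
  sol <- solve_assimilation(kin, 0.27027, 400)
  oracle <- helper_bisect_assimilation(66.8, 710.3, 42.75, 1.002,
                                       0.27027, 400)
  expect_equal(sol$A, oracle$A, tolerance = 1e-9)
  expect_equal(sol$A, 17.66, tolerance = 1e-3)
  expect_equal(sol$ci, 334.66, tolerance = 1e-3)
  # flux consistency: Fick and Rubisco-limited rate simultaneously
  expect_equal(sol$A, 0.27027 * (400 - sol$ci), tolerance = 1e-9)
  expect_equal(sol$A,
               66.8 * (sol$ci - 42.75) / (sol$ci + 710.3) - 1.002,
               tolerance = 1e-9)

  # no diffusive limitation: ci -> ca, A -> Ac(ca)
  open <- solve_assimilation(kin, 1e7, 400)
  expect_equal(open$ci, 400, tolerance = 1e-4)
  expect_equal(open$A, 66.8 * (400 - 42.75) / (400 + 710.3) - 1.002,
               tolerance = 1e-4)

  # dead leaf: Vcmax = 0 implies Rd = 0, A = 0, ci = ca
  dead <- kinetics_at(29, 0)
  sol0 <- solve_assimilation(dead, 0.3, 400)
  expect_equal(sol0$A, 0, tolerance = 1e-12)
  expect_equal(sol0$ci, 400, tolerance = 1e-9)
  expect_error(solve_assimilation(kin, -0.1, 400), "positive")
  expect_error(solve_assimilation(kin, 0.3, 10), "compensation")
})

test_that("solver matches bisection over random parameterisations", {
  set.seed(202)
  n <- 200
  vcmax <- runif(n, 5, 150)
  gt <- runif(n, 0.02, 1.5)
  ca <- runif(n, 250, 450)
  worst <- 0
  for (i in seq_len(n)) {
    kin <- kinetics_at(29, vcmax[i])
    sol <- solve_assimilation(kin, gt[i], ca[i])
    oracle <- helper_bisect_assimilation(kin$vcmax, kin$km, kin$gamma_star,
                                         kin$rd, gt[i], ca[i])
    worst <- max(worst, abs(sol$A - oracle$A))
  }
  expect_lt(worst, 1e-6)
  # monotone responses on grids at fixed kinetics
  kin <- kinetics_at(29, 60)
  a_gt <- solve_assimilation(kin, seq(0.05, 1, by = 0.05), 400)$A
  expect_true(all(diff(a_gt) > 0))
  a_ca <- solve_assimilation(kin, 0.3, seq(300, 420, by = 10))$A
  expect_true(all(diff(a_ca) > 0))
})

test_that("the RuBP-regeneration rate has the right endpoints", {
  kin <- structure(list(gamma_star = 42.75, rd = 1), class = "kinetic_params")
  expect_equal(aj_rate(42.75, 100, kin), -1)
  # hand evaluation at ci = 2 gamma_star
  expect_equal(aj_rate(85.5, 100, kin),
               42.75 * 25 / (85.5 + 85.5) - 1, tolerance = 1e-12)
  expect_equal(aj_rate(85.5, 100, kin), 5.25)
  # asymptote Jmax/4 - Rd
  expect_equal(aj_rate(1e9, 100, kin), 24, tolerance = 1e-5)
  expect_error(aj_rate(100, -1, kin), "positive")
})

test_that("the per-specimen simulation chains the engine deterministically", {
  atm <- helper_atmosphere()
  model <- structure(list(a = 0, b = 0, c = 0, d = log(48.9),
                          ranef = stats::setNames(numeric(0), character(0))),
                     class = "vcmax_trait_model")
  rec <- data.frame(
    specimen_id = c("x1", "x2", "x3"),
    species = "alpha", year = 2015,
    lma = c(110, 110, 110), n_area = c(2.1, 2.1, NA),
    gsmax_mol = c(1.0, 1.0, 1.0)
  )
  out <- eb_simulate(rec, atm, model)
  expect_equal(nrow(out), 2)
  expect_equal(attr(out, "n_skipped"), 1)
  # identical specimens, identical results
  num <- vapply(out, is.numeric, logical(1))
  expect_equal(unlist(out[1, num]), unlist(out[2, num]))

  # chained hand oracle
  expect_equal(out$vcmax25[1], 48.9)
  expect_equal(out$gs[1], 0.51)
  expect_equal(out$gc[1], 0.51 / 1.6)
  expect_equal(out$gt[1], (0.51 / 1.6) * 2 / (0.51 / 1.6 + 2),
               tolerance = 1e-12)
  kin <- kinetics_at(29, 48.9)
  oracle <- helper_bisect_assimilation(kin$vcmax, kin$km, kin$gamma_star,
                                       kin$rd, out$gt[1], 400)
  expect_equal(out$A[1], oracle$A, tolerance = 1e-8)
  expect_equal(out$iwue[1], out$A[1] / 0.51, tolerance = 1e-12)
  expect_equal(out$A[1], out$gt[1] * (400 - out$ci[1]), tolerance = 1e-9)
  expect_true(all(out$solver_ok))
})
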