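test_that("the species regression recovers exact lines and flags bad designs", {
  ca <- seq(310, 400, length.out = 10)
  g <- 5 - 0.005 * ca
  fit <- fit_gsmax_regression(g, ca)
  expect_equal(unname(fit$coef), c(5, -0.005), tolerance = 1e-10)
  expect_lt(max(abs(fit$vcov)), 1e-12)

  expect_error(fit_gsmax_regression(c(1, 2), c(300, 400)), "at least 3")
  expect_error(fit_gsmax_regression(c(1, 2, 3), c(350, 350, 350)),
               "rank-deficient")
})

test_that("the regression slope CI covers a known generative slope", {
  set.seed(33)
  slope_true <- -0.00618
  hits <- 0
  for (r in 1:100) {
    ca <- runif(60, 305, 400)
    g <- 5 + slope_true * ca + rnorm(60, 0, 0.3)
    fit <- fit_gsmax_regression(g, ca)
    half <- qt(0.975, 58) * sqrt(fit$vcov[2, 2])
    if (abs(fit$coef[2] - slope_true) <= half) hits <- hits + 1
  }
  expect_gte(hits, 93)
})

test_that("coefficient sampling is reproducible and converges", {
  fit <- list(coef = c(`(Intercept)` = 5, ca = -0.005),
              vcov = matrix(c(0.04, -1e-4, -1e-4, 4e-7), 2))
  d1 <- sample_coefficients(fit, n_draws = 10000, seed = 7)
  d2 <- sample_coefficients(fit, n_draws = 10000, seed = 7)
  expect_identical(d1$draws, d2$draws)
  # draw covariance within 5% (Frobenius relative) of the input
  emp <- stats::cov(d1$draws)
  expect_lt(norm(emp - fit$vcov, "F") / norm(fit$vcov, "F"), 0.05)
  # draw means within Monte-Carlo error of the point estimates
  se_mean <- sqrt(diag(fit$vcov) / 10000)
  expect_true(all(abs(colMeans(d1$draws) - fit$coef) < 5 * se_mean))

  # degenerate distribution: all draws equal the point estimates
  fit0 <- list(coef = c(5, -0.005), vcov = matrix(0, 2, 2))
  d0 <- sample_coefficients(fit0, n_draws = 50, seed = 1)
  expect_true(all(d0$draws[, 1] == 5) && all(d0$draws[, 2] == -0.005))

  bad <- list(coef = c(0, 0), vcov = matrix(c(1, 2, 2, 1), 2))
  expect_error(sample_coefficients(bad), "positive semi-definite")
})

test_that("trajectories evaluate the drawn lines with floored negatives", {
  atm <- helper_atmosphere()
  draws <- list(draws = cbind(intercept = c(5, 0.1), slope = c(-0.005, -0.005)))
  traj <- gsmax_trajectories(draws, atm, c(1927, 2015))
  expect_equal(traj[1, 2], 5 - 0.005 * 400) # 3.0 at 400 ppm
  expect_equal(traj[1, 1], 5 - 0.005 * 305)
  # second draw goes negative late in the series: floored and counted
  expect_equal(min(traj[2, ]), 1e-3)
  expect_equal(attr(traj, "n_floored"), 1)

  flat_atm <- atmosphere_series(2000:2010, rep(380, 11))
  traj_flat <- gsmax_trajectories(draws, flat_atm, 2000:2010)
  expect_true(all(traj_flat[1, ] == traj_flat[1, 1]))
})

test_that("degenerate ensembles collapse and rising CO2 raises iWUE at fixed gs", {
  atm <- helper_atmosphere()
  fit0 <- list(coef = c(1.0, 0), vcov = matrix(0, 2, 2))
  draws <- sample_coefficients(fit0, n_draws = 100, seed = 1)
  traj <- gsmax_trajectories(draws, atm, atm$year)
  ens <- run_ensemble(traj, vcmax25 = 50)
  resp <- summarize_responses(ens)
  # all draws identical: zero-width intervals
  expect_equal(resp$delta2$lo, resp$delta2$mean)
  expect_equal(resp$delta2$hi, resp$delta2$mean)
  expect_equal(resp$eta2$mean, 0)
  # flat gsmax over rising ca: iWUE still rises through A
  expect_gt(resp$delta2$mean, 0)
  expect_gt(resp$gamma2$mean, 0)
})

test_that("per-draw slope summaries honour the quantile definition", {
  # hand-built ensemble: slopes symmetric around 0.07
  ca <- seq(300, 400, length.out = 11)
  n_draws <- 10000
  set.seed(9)
  slopes_true <- 0.07 + rnorm(n_draws, 0, 0.01)
  iwue <- outer(slopes_true, ca) + 40
  ens <- list(gs = iwue * 0 + 1, A = iwue, iwue = iwue, ca = ca,
              years = ca, ok = rep(TRUE, n_draws))
  resp <- summarize_responses(ens)
  expect_equal(resp$delta2$mean, mean(slopes_true), tolerance = 1e-9)
  expect_equal(resp$delta2$mean, 0.07, tolerance = 0.001)
  # ~250 of 10,000 draws below the lower bound (binomial tolerance)
  n_below <- sum(resp$delta2$slopes < resp$delta2$lo)
  expect_true(n_below >= 200 && n_below <= 300)
  expect_true(resp$delta2$lo <= resp$delta2$mean &&
                resp$delta2$mean <= resp$delta2$hi)
})

test_that("ensemble mean iWUE responses preserve the generative gsmax ordering", {
  # five species identical except for the density trend: a more negative
  # gsmax trajectory slope must give a larger simulated iWUE response
  base <- default_species_configs()[["Astronidium confertiflorum"]]
  trends <- c(-3, -1.5, 0, 0.5, 1)
  configs <- lapply(seq_along(trends), function(i) {
    cf <- base
    cf$species <- sprintf("ord%02d", i)
    cf$n <- 40
    cf$d_trend <- trends[i]
    cf
  })
  names(configs) <- vapply(configs, `[[`, character(1), "species")
  atm <- generate_atmosphere()
  model <- structure(list(a = 0, b = 0, c = 0, d = log(48),
                          ranef = stats::setNames(numeric(0), character(0))),
                     class = "vcmax_trait_model")
  for (seed in 1:3) {
    rec <- augment_gsmax(generate_community(configs, atm, seed = seed))
    mc <- mc_species_responses(rec, atm, model, n_draws = 500, seed = seed)
    d2 <- mc[mc$response == "delta2", ]
    d2 <- d2[order(d2$species), ]
    expect_equal(cor(d2$mean, trends, method = "spearman"), -1,
                 label = sprintf("seed %d rank correlation", seed))
  }
})

test_that("the full species-level propagation is seed-deterministic", {
  atm <- generate_atmosphere()
  cfg <- default_species_configs()[c("Amaroria soulameoides",
                                     "Dillenia biflora")]
  rec <- augment_gsmax(generate_community(cfg, atm, seed = 4))
  model <- fit_vcmax_model(generate_vcmax_training(seed = 4))
  m1 <- mc_species_responses(rec, atm, model, n_draws = 300, seed = 11)
  m2 <- mc_species_responses(rec, atm, model, n_draws = 300, seed = 11)
  expect_identical(m1, m2)
  expect_setequal(unique(m1$response), c("delta2", "gamma2", "eta2"))
  expect_true(all(m1$lo <= m1$mean & m1$mean <= m1$hi))
})
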