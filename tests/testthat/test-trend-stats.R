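test_that("trend fits match the closed-form normal equations", {
  x <- c(310, 330, 355, 370, 390, 400)
  y <- c(44, 49, 51, 56, 55, 60)
  fit <- fit_trend(x, y)
  # independent hand implementation of OLS
  slope_hat <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  intercept_hat <- mean(y) - slope_hat * mean(x)
  expect_equal(fit$slope, slope_hat, tolerance = 1e-10)
  expect_equal(fit$intercept, intercept_hat, tolerance = 1e-10)
  expect_true(fit$ci[1] <= fit$slope && fit$slope <= fit$ci[2])

  # perfect line: exact slope, r2 = 1, vanishing CI width
  exact <- fit_trend(300:400, 2 + 0.14 * (300:400))
  expect_equal(exact$slope, 0.14, tolerance = 1e-12)
  expect_equal(exact$r2, 1)
  expect_lt(diff(exact$ci), 1e-9)

  # constant response
  flat <- fit_trend(300:310, rep(7, 11))
  expect_equal(flat$slope, 0)
  expect_equal(flat$r2, 0)

  expect_error(fit_trend(rep(350, 5), 1:5), "degenerate")
  expect_error(fit_trend(1:2, 1:2), "at least 3")
})

test_that("trend CIs cover a known slope under generator-level noise", {
  set.seed(41)
  hits <- 0
  for (r in 1:100) {
    ca <- runif(200, 305, 400)
    y <- 0.14 * ca + rnorm(200, 0, 7.5) # isotope-level iWUE noise
    fit <- fit_trend(ca, y)
    if (fit$ci[1] <= 0.14 && 0.14 <= fit$ci[2]) hits <- hits + 1
  }
  expect_gte(hits, 93)
})

test_that("relative sensitivity rescales the slope by the reference value", {
  fit <- structure(list(slope = 0.05, intercept = 10), class = "response_fit")
  expect_equal(relative_sensitivity(fit), 20) # 25 at 300 ppm, +20% per 100
  flat <- structure(list(slope = 0, intercept = 10), class = "response_fit")
  expect_equal(relative_sensitivity(flat), 0)
  neg <- structure(list(slope = -0.05, intercept = 40), class = "response_fit")
  expect_lt(relative_sensitivity(neg), 0)
  # invariant to rescaling the trait by a positive constant
  fit10 <- structure(list(slope = 0.5, intercept = 100),
                     class = "response_fit")
  expect_equal(relative_sensitivity(fit10), relative_sensitivity(fit))
  zero <- structure(list(slope = 0.05, intercept = -15),
                    class = "response_fit")
  expect_error(relative_sensitivity(zero), "zero")
})

test_that("binned ANOVA separates means and reports degenerate groups", {
  set.seed(42)
  ca <- runif(120, 301, 400)
  # strongly separated bin means
  strong <- as.numeric(cut(ca, c(300, 325, 350, 375, 400))) * 10 +
    rnorm(120, 0, 1)
  res <- anova_binned(strong, ca)
  expect_lt(res$p, 0.001)
  expect_equal(res$df[1], 3)

  # identical values everywhere: no between-group variance
  res0 <- anova_binned(rep(3, 120), ca)
  expect_equal(res0$F, 0)
  expect_equal(res0$note, "no between-group variance")

  expect_error(anova_binned(rnorm(10), rep(310, 10)), "empty")

  # under the null, F is near 1 in expectation
  fs <- replicate(100, {
    ca_i <- runif(80, 301, 400)
    anova_binned(rnorm(80, 5, 1), ca_i)$F
  })
  expect_gt(mean(fs), 0.7)
  expect_lt(mean(fs), 1.4)
})

test_that("variance partition shares are symmetric and sum to the model r2", {
  set.seed(43)
  n <- 2000
  x1 <- rnorm(n); x2 <- rnorm(n)
  y <- 2 * x1 + rnorm(n, 0, 0.5)
  vp <- variance_partition(y, x1, x2)
  expect_gt(vp$share_x1, 95) # x2 is pure noise
  expect_equal(vp$share_x1 + vp$share_x2, 100, tolerance = 1e-9)

  # exchangeable predictors split evenly
  y_sym <- x1 + x2 + rnorm(n)
  vp_sym <- variance_partition(y_sym, x1, x2)
  expect_equal(vp_sym$share_x1, 50, tolerance = 5)

  # label permutation swaps the shares exactly
  vp_swap <- variance_partition(y, x2, x1)
  expect_equal(vp_swap$share_x2, vp$share_x1, tolerance = 1e-12)

  expect_error(variance_partition(y, x1, x1 * 1.0000001), "collinear")
})

test_that("slope RMSE and range summaries follow their definitions", {
  expect_equal(slope_rmse(c(a = 0.1, b = 0.2), c(a = 0.1, b = 0.2)), 0)
  five <- stats::setNames(1:5 / 10, letters[1:5])
  expect_equal(slope_rmse(five, five + 0.02), 0.02, tolerance = 1e-12)
  expect_equal(slope_rmse(c(0.1, 0.2), c(0.1, 0.24)), sqrt(0.0016 / 2),
               tolerance = 1e-12)
  # species matching is by name, order-insensitive
  expect_equal(slope_rmse(c(a = 0.1, b = 0.2), c(b = 0.24, a = 0.1)),
               sqrt(0.0016 / 2))
  expect_error(slope_rmse(c(a = 1), c(b = 1)), "mismatched")

  rs <- range_summary(c(-32.09, -28.05))
  expect_equal(rs$range, 4.04, tolerance = 1e-9)
  expect_equal(range_summary(c(-31.13, -27.60))$range, 3.53, tolerance = 1e-9)
  expect_equal(range_summary(5)$range, 0)
  expect_error(range_summary(numeric(0)), "empty")
})

test_that("the tidy trend table reports species and pooled rows", {
  atm <- helper_atmosphere()
  rec <- augment_iwue(generate_community(atmosphere = generate_atmosphere(),
                                         seed = 2),
                      generate_atmosphere())
  tt <- trend_table(rec, "iwue")
  expect_setequal(tt$species, c(sort(unique(rec$species)), "combined"))
  expect_true(all(c("slope", "ci_lo", "ci_hi", "p", "r2", "n",
                    "rel_sensitivity") %in% names(tt)))
  comb <- tt[tt$species == "combined", ]
  expect_equal(comb$n, sum(!is.na(rec$iwue)))
})
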