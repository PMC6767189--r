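test_that("a perfect line gives exact slope and zero error SSE", {
  x <- 1:5
  fit <- linear_fit_anova(x, 2 * x + 1)
  expect_equal(fit$slope, 2)
  expect_equal(fit$intercept, 1)
  expect_equal(fit$sse_error, 0)
  expect_equal(fit$f_value, Inf)
  expect_equal(fit$p_value, .Machine$double.xmin)   # clamped into (0, 1]
  expect_error(linear_fit_anova(rep(1, 5), 1:5), "degenerate")
  expect_error(linear_fit_anova(1:2, 1:2), "at least 3")
})

test_that("ANOVA matches the explicit sum-formula oracle (seeded, n = 42)", {
  x <- withr::with_seed(42, runif(42, 273, 318))
  y <- withr::with_seed(43, sample(x))     # y is a permutation of x
  fit <- linear_fit_anova(x, y)
  want <- oracle_anova(x, y)
  expect_equal(fit$slope, want$slope, tolerance = 1e-12)
  expect_equal(fit$sse_model, want$sse_model, tolerance = 1e-10)
  expect_equal(fit$sse_error, want$sse_error, tolerance = 1e-10)
  expect_equal(fit$f_value, want$f_value, tolerance = 1e-10)
  expect_equal(fit$p_value, want$p_value, tolerance = 1e-10)
})

test_that("regression internal identities hold on random inputs", {
  for (seed in 1:20) {
    n <- 5 + seed
    x <- withr::with_seed(seed, rnorm(n))
    y <- withr::with_seed(seed + 1000, 0.3 * x + rnorm(n))
    fit <- linear_fit_anova(x, y)
    expect_equal(fit$sse_total, fit$sse_model + fit$sse_error,
                 tolerance = 1e-12)
    expect_equal(fit$df_total, fit$df_model + fit$df_error)
    expect_equal(fit$f_value, fit$mse_model / fit$mse_error,
                 tolerance = 1e-12)
    expect_gt(fit$p_value, 0)
    expect_lte(fit$p_value, 1)
    # agreement with stats::lm as an independent route
    lmf <- lm(y ~ x)
    expect_equal(fit$slope, unname(coef(lmf)[2]), tolerance = 1e-12)
    expect_equal(fit$slope_se, summary(lmf)$coefficients[2, 2],
                 tolerance = 1e-10)
  }
})

test_that("confidence and prediction bands use the 95% t quantile", {
  x <- seq(273, 318, length.out = 20)
  y <- withr::with_seed(5, -6e-4 * x + 0.5 + rnorm(20, 0, 0.005))
  fit <- linear_fit_anova(x, y)
  cb <- fit$confidence_band(mean(x))
  pb <- fit$prediction_band(mean(x))
  half_conf <- qt(0.975, 18) * sqrt(fit$mse_error / 20)
  expect_equal(cb$upr - cb$fit, half_conf, tolerance = 1e-12)
  expect_gt(pb$upr - pb$fit, cb$upr - cb$fit)       # prediction band is wider
  # matches predict.lm on a grid
  lmf <- lm(y ~ x)
  grid <- c(280, 300, 315)
  expect_equal(as.matrix(fit$confidence_band(grid)[, c("fit", "lwr", "upr")]),
               unname(predict(lmf, data.frame(x = grid),
                              interval = "confidence")),
               ignore_attr = TRUE, tolerance = 1e-10)
})

test_that("f_sf equals the incomplete-beta and t-test identities", {
  # survival function vs regularized incomplete beta
  for (f in c(0.5, 2, 10, 47.56219)) {
    for (df2 in c(5, 40)) {
      expect_equal(f_sf(f, 1, df2), pbeta(df2 / (df2 + f), df2 / 2, 0.5),
                   tolerance = 1e-6)
    }
  }
  # f_sf(t^2, 1, nu) = two-sided t tail
  for (t in c(0.5, 1.5, 3)) {
    for (nu in c(8, 40)) {
      expect_equal(f_sf(t^2, 1, nu), 2 * pt(-t, nu), tolerance = 1e-12)
    }
  }
  expect_equal(f_sf(0, 3, 7), 1)
  expect_error(f_sf(1, 0, 5), "degrees of freedom")
})

test_that("expansion coefficient recovers exact exponentials and rescales", {
  temps <- seq(273, 318, by = 1)
  rho <- 1.35 * exp(-8e-4 * temps)
  ser <- thermo_series(temps, density = rho)
  ec <- expansion_coefficient(ser)
  expect_equal(ec$alpha_p, 8e-4, tolerance = 1e-12)
  # constant density -> zero coefficient
  flat <- thermo_series(temps, density = rep(1.3, length(temps)))
  expect_equal(expansion_coefficient(flat)$alpha_p, 0, tolerance = 1e-15)
  # invariant under positive rescaling of the density
  noisy <- make_thermo_series(seed = 3)
  a1 <- expansion_coefficient(noisy)$alpha_p
  scaled <- thermo_series(noisy$temperature, density = 17.3 * noisy$density)
  expect_equal(expansion_coefficient(scaled)$alpha_p, a1, tolerance = 1e-12)
  bad <- data.frame(temperature = temps[1:3], density = c(1, -1, 1))
  expect_error(expansion_coefficient(bad), "non-positive density")
})

test_that("glass transition finds an exact bilinear knee to 0.1 K", {
  bl <- make_bilinear_series(Tg = 424.7, sigma = 0)
  tg <- glass_transition(bl$temps, bl$specific_volume)
  expect_lt(abs(tg$breakpoint - 424.7), 0.1)
  expect_equal(tg$left_slope, 4.6e-4, tolerance = 1e-3)
  expect_equal(tg$right_slope, 1.38e-3, tolerance = 1e-3)
  expect_true(tg$reliable)
  expect_lt(tg$sse, 1e-12)
})

test_that("a straight line is flagged as having no reliable knee", {
  temps <- seq(100, 600, length.out = 11)
  v <- 0.6 + 5e-4 * temps
  tg <- glass_transition(temps, v)
  expect_false(tg$reliable)
  expect_error(glass_transition(temps[1:5], v[1:5]), "length")
  expect_error(glass_transition(rev(temps), v), "sorted")
})
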