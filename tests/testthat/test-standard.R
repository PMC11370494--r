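test_that("coefficients and residuals match the normal-equations oracle", {
  set.seed(42)
  for (i in 1:5) {
    X <- matrix(rnorm(20 * 3), 20, 3)
    y <- rnorm(20)
    df <- data.frame(X, y = y)
    fit <- fit_standard(df, c("X1", "X2", "X3"), outcome = "y")
    D <- cbind(1, X)
    beta <- solve(t(D) %*% D, t(D) %*% y) # closed-form OLS
    expect_equal(unname(fit$coefficients), drop(beta), tolerance = 1e-8)
    expect_equal(fit$residuals, drop(y - D %*% beta), tolerance = 1e-8)
  }
})

test_that("an exactly linear outcome yields zero residuals and R^2 = 1", {
  cfg <- small_config(expectation_fraction = 1, seed = 2) # no CR, no noise
  ds <- simulate_dataset(cfg)
  fit <- fit_standard(ds, role_columns(ds, "expectation"))
  expect_lt(max(abs(fit$residuals)), 1e-10)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  expect_equal(fit$explained_variance, 1, tolerance = 1e-12)
})

test_that("residuals are centred and orthogonal to included predictors", {
  ds <- simulate_dataset(default_config(noise_sd = 1, seed = 6))
  preds <- c(role_columns(ds, "expectation"), role_columns(ds, "cr"))
  fit <- fit_standard(ds, preds)
  expect_lt(abs(sum(fit$residuals)), 1e-8)
  for (p in preds) {
    expect_lt(abs(sum(fit$residuals * ds[[p]])), 1e-6)
  }
})

test_that("perfect collinearity falls back to a minimum-norm solution", {
  ds <- simulate_dataset(default_config(correlation = 1, seed = 3))
  preds <- c(role_columns(ds, "expectation"), role_columns(ds, "cr"))
  expect_warning(fit <- fit_standard(ds, preds), "Rank-deficient")
  expect_equal(fit$rank, 10) # intercept + 9 distinct directions
  # deterministic: same warning-path result on re-fit
  expect_warning(fit2 <- fit_standard(ds, preds), "Rank-deficient")
  expect_identical(fit$coefficients, fit2$coefficients)
  # collinear pairs share their coefficient under minimum-norm
  expect_equal(unname(fit$coefficients["x1"]), unname(fit$coefficients["x10"]),
               tolerance = 1e-8)
})

test_that("an empty predictor set fits the intercept-only model", {
  ds <- simulate_dataset(small_config(seed = 4))
  fit <- fit_standard(ds, character(0))
  expect_equal(unname(fit$coefficients[1]), mean(ds$cog_obs), tolerance = 1e-10)
  expect_equal(estimate_cr_standard(fit), ds$cog_obs - mean(ds$cog_obs),
               tolerance = 1e-10)
})

test_that("estimate_cr_standard returns the fit residuals", {
  ds <- simulate_dataset(small_config(seed = 10))
  fit <- fit_standard(ds, role_columns(ds, "expectation"))
  expect_identical(estimate_cr_standard(fit), fit$residuals)
  expect_equal(estimate_cr_standard(fit), ds$cog_obs - fit$fitted_values,
               tolerance = 1e-12)
})

test_that("estimates for expectation samples centre on zero when unbiased", {
  # no CR predictors, no correlation: classic unbiased regime
  ds <- simulate_dataset(default_config(seed = 12))
  fit <- fit_standard(ds, role_columns(ds, "expectation"))
  est_exp <- estimate_cr_standard(fit)[ds$is_expectation]
  expect_lt(abs(mean(est_exp)), 0.2)
})

test_that("missing columns produce a named error", {
  ds <- simulate_dataset(small_config(seed = 1))
  expect_error(fit_standard(ds, c("x1", "zz")), "zz")
  expect_error(fit_standard(ds, "x1", outcome = "missing_outcome"),
               "missing_outcome")
})
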