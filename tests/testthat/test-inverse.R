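test_that("a realizable linear expectation is learned essentially exactly", {
  ds <- simulate_dataset(default_config(seed = 21))
  em <- fit_expectation_model(ds[ds$is_expectation, ],
                              role_columns(ds, "expectation"), seed = 21)
  expect_true(all(em$cv_performance$r_squared >= 0.999))
  expect_lt(max(abs(em$oof_errors)), 1e-8)
})

test_that("out-of-fold errors average near zero for a well-specified learner", {
  ds <- simulate_dataset(default_config(noise_sd = 1, seed = 22))
  em <- fit_expectation_model(ds[ds$is_expectation, ],
                              role_columns(ds, "expectation"), seed = 22)
  expect_lt(abs(mean(em$oof_errors)), 0.2)
  # cross-validated performance reflects the noise floor, not overfit
  expect_true(all(em$cv_performance$mse > 0.5))
  expect_true(all(em$cv_performance$mse < 2))
})

test_that("extract_residuals matches the subtract-prediction oracle", {
  ds <- simulate_dataset(default_config(seed = 23))
  exp_rows <- ds[ds$is_expectation, ]
  targets <- ds[!ds$is_expectation, ]
  em <- fit_expectation_model(exp_rows, role_columns(ds, "expectation"),
                              seed = 23)
  raw <- extract_residuals(em, targets)
  pred <- crlearn:::predict_expectation(em, targets)
  expect_equal(raw, targets$cog_obs - pred, tolerance = 1e-12)
  # under the exact model, residuals equal the true resilience shift
  expect_equal(raw, targets$cr_true, tolerance = 1e-8)
  # and zero-CR rows get zero residuals
  raw_exp <- extract_residuals(em, exp_rows)
  expect_lt(max(abs(raw_exp)), 1e-8)
})

test_that("error correction is a no-op on uninformative errors", {
  ds <- simulate_dataset(default_config(seed = 24))
  em <- fit_expectation_model(ds[ds$is_expectation, ],
                              role_columns(ds, "expectation"), seed = 24)
  # constant out-of-fold errors: intercept-only correction, zero slopes
  em$oof_errors <- rep(2, em$n)
  ec <- fit_error_correction(em)
  coefs <- ec$fitted_model$coef
  expect_equal(coefs[1], 2, tolerance = 1e-10)
  expect_lt(max(abs(coefs[-1])), 1e-10)
  targets <- ds[!ds$is_expectation, ]
  expect_equal(predict(ec, targets), rep(2, nrow(targets)), tolerance = 1e-8)
})

test_that("corrected estimates decompose algebraically", {
  ds <- simulate_dataset(default_config(noise_sd = 1, seed = 25))
  em <- fit_expectation_model(ds[ds$is_expectation, ],
                              role_columns(ds, "expectation"), seed = 25)
  ec <- fit_error_correction(em)
  targets <- ds[!ds$is_expectation, ]
  est <- estimate_cr_inverse(em, targets, ec)
  expect_equal(est$corrected_cr + est$predicted_error, est$raw_residual,
               tolerance = 1e-12)
  # with no error model, corrected equals raw exactly
  est0 <- estimate_cr_inverse(em, targets, error_model = NULL)
  expect_identical(est0$corrected_cr, est0$raw_residual)
  expect_true(all(est0$predicted_error == 0))
})

test_that("estimates ignore how many target samples carry resilience", {
  # same design matrix and expectation subset; resilience switched off for
  # half the targets. The fitted estimator must be bit-identical, so the
  # per-sample estimation errors coincide exactly.
  ds <- simulate_dataset(default_config(seed = 26))
  preds <- role_columns(ds, "expectation")
  target_rows <- which(!ds$is_expectation)
  off <- target_rows[seq(1, length(target_rows), by = 2)]
  ds_low <- ds
  ds_low$cog_obs[off] <- ds_low$cog_obs[off] - ds_low$cr_true[off]
  ds_low$cr_true[off] <- 0

  fit_high <- fit_inverse(ds, preds, seed = 26)
  fit_low <- fit_inverse(ds_low, preds, seed = 26)
  # the fitted estimator is bit-identical: same out-of-fold errors and the
  # same predictions for every target sample
  expect_identical(fit_high$expectation_model$oof_errors,
                   fit_low$expectation_model$oof_errors)
  expect_identical(
    crlearn:::predict_expectation(fit_high$expectation_model, ds[target_rows, ]),
    crlearn:::predict_expectation(fit_low$expectation_model, ds[target_rows, ])
  )
  expect_identical(fit_high$estimates$predicted_error,
                   fit_low$estimates$predicted_error)
  # per-sample estimation errors coincide up to float re-association of the
  # outcome sum (cog_obs was rebuilt by subtracting cr_true)
  err_high <- fit_high$estimates$corrected_cr - ds$cr_true[target_rows]
  err_low <- fit_low$estimates$corrected_cr - ds_low$cr_true[target_rows]
  expect_equal(err_high, err_low, tolerance = 1e-12)
})

test_that("full pipeline recovers a noiseless linear truth exactly", {
  ds <- simulate_dataset(default_config(seed = 27))
  fit <- fit_inverse(ds, role_columns(ds, "expectation"), seed = 27)
  expect_lt(max(abs(fit$estimates$corrected_cr - target_truth(ds, fit))),
            1e-6)
})

test_that("degenerate inputs are flagged", {
  ds <- simulate_dataset(small_config(seed = 28))
  tiny <- ds[1:3, ]
  expect_error(fit_expectation_model(tiny, "x1", cv_folds = 5), "at least")
  const <- ds[1:20, ]
  const$cog_obs <- 5
  expect_warning(fit_expectation_model(const, "x1", seed = 1),
                 "Constant outcome")
  expect_error(fit_inverse(ds, "x1", membership = "nope"), "nope")
})

test_that("the boosted learner runs seeded and beats linear on a non-linear
           expectation", {
  cfg <- default_config(n_samples = 400, f_kind = "friedman", seed = 29)
  ds <- simulate_dataset(cfg)
  exp_rows <- ds[ds$is_expectation, ]
  preds <- role_columns(ds, "expectation")
  em_lin <- fit_expectation_model(exp_rows, preds, learner = "linear",
                                  cv_repeats = 2, seed = 29)
  em_gbt <- fit_expectation_model(exp_rows, preds, learner = "gbt",
                                  cv_repeats = 2, seed = 29)
  expect_lt(mean(em_gbt$cv_performance$mse), mean(em_lin$cv_performance$mse))
  # seeded reproducibility of the boosted pipeline end to end
  em_gbt2 <- fit_expectation_model(exp_rows, preds, learner = "gbt",
                                   cv_repeats = 2, seed = 29)
  expect_identical(em_gbt$oof_errors, em_gbt2$oof_errors)
  targets <- ds[!ds$is_expectation, ]
  expect_identical(extract_residuals(em_gbt, targets),
                   extract_residuals(em_gbt2, targets))
})

test_that("learner registry accepts user-supplied learners", {
  register_learner(
    "mean_only",
    fit = function(X, y, args = list()) list(mu = mean(y)),
    predict = function(model, X) rep(model$mu, nrow(X))
  )
  expect_true("mean_only" %in% list_learners())
  ds <- simulate_dataset(small_config(seed = 30))
  em <- fit_expectation_model(ds[ds$is_expectation, ], "x1",
                              learner = "mean_only", seed = 30)
  expect_equal(
    crlearn:::predict_expectation(em, ds[1:4, ]),
    rep(mean(ds$cog_obs[ds$is_expectation]), 4)
  )
  expect_error(get_learner("not_registered"), "Unknown learner")
})
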