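test_that("score_estimates matches hand-computed metrics", {
  truth <- c(1, 2, 3, 4)
  s <- score_estimates(truth, truth)
  expect_equal(s$mse, 0)
  expect_equal(s$calibration_slope, 1, tolerance = 1e-12)
  expect_equal(s$calibration_intercept, 0, tolerance = 1e-12)

  s2 <- score_estimates(truth + 2, truth)
  expect_equal(s2$mse, 4)
  expect_equal(s2$calibration_slope, 1, tolerance = 1e-12)
  expect_equal(s2$calibration_intercept, 2, tolerance = 1e-12)

  set.seed(9)
  est <- rnorm(30)
  truth <- rnorm(30)
  s3 <- score_estimates(est, truth)
  # brute-force oracle
  expect_equal(s3$mse, sum((est - truth)^2) / 30, tolerance = 1e-12)
  cal <- coef(lm(est ~ truth))
  expect_equal(s3$calibration_slope, unname(cal[2]), tolerance = 1e-10)
  expect_equal(s3$calibration_intercept, unname(cal[1]), tolerance = 1e-10)
  expect_equal(s3$r_squared, cor(est, truth)^2, tolerance = 1e-12)
})

test_that("score_estimates flags zero-variance truth and guards shapes", {
  expect_warning(s <- score_estimates(c(1, 2, 3), c(0, 0, 0)),
                 "zero variance")
  expect_true(s$truth_degenerate)
  expect_equal(s$mse, mean(c(1, 4, 9)))
  expect_true(is.na(s$calibration_slope))
  expect_error(score_estimates(1:4, 1:3), "equal length")
  expect_error(score_estimates(1:2, 1:2), "at least 3")
})

test_that("predictor sweep is tidy, reproducible, and shows the
           resilience-predictor bias in the standard approach only", {
  cfg <- sim_config(n_samples = 300, seed = 1)
  sweep <- run_predictor_sweep(cfg, n_expectation = 9, n_cr = c(0, 9),
                               replicates = 3, seed = 5)
  expect_s3_class(sweep, "cr_sweep")
  # 2 cells x 3 replicates x (standard raw + inverse raw + inverse corrected)
  expect_equal(nrow(sweep), 2 * 3 * 3)
  sweep2 <- run_predictor_sweep(cfg, n_expectation = 9, n_cr = c(0, 9),
                                replicates = 3, seed = 5)
  expect_identical(as.data.frame(sweep), as.data.frame(sweep2))

  summ <- summarise_sweep(sweep)
  std <- summ[summ$approach == "standard", ]
  expect_gt(std$mean_mse[std$n_cr == 9], std$mean_mse[std$n_cr == 0])
  inv <- summ[summ$approach == "inverse_linear" &
                summ$estimate_type == "corrected", ]
  expect_lt(max(inv$mean_mse), 1e-10)
})

test_that("correlation sweep hurts only the standard approach", {
  cfg <- sim_config(n_samples = 300, seed = 2)
  sweep <- run_correlation_sweep(cfg, rho = c(0, 0.9), replicates = 3,
                                 seed = 6)
  summ <- summarise_sweep(sweep)
  std <- summ[summ$approach == "standard", ]
  expect_gt(std$mean_mse[std$correlation == 0.9],
            2 * std$mean_mse[std$correlation == 0])
  inv <- summ[summ$approach == "inverse_linear" &
                summ$estimate_type == "corrected", ]
  expect_lt(max(inv$mean_mse), 1e-10)
})

test_that("prevalence sweep shrinks standard-approach calibration slopes", {
  cfg <- sim_config(n_samples = 300, seed = 3)
  sweep <- run_prevalence_sweep(cfg, prevalence = c(0.2, 0.8),
                                regime = "all_informative",
                                replicates = 3, seed = 7)
  summ <- summarise_sweep(sweep)
  expect_gt(summ$mean_calibration_slope[summ$prevalence == 0.2],
            summ$mean_calibration_slope[summ$prevalence == 0.8])
  # prevalence levels leaving too few expectation samples are skipped
  expect_warning(
    empty <- run_prevalence_sweep(sim_config(n_samples = 100, seed = 1),
                                  prevalence = 0.95, replicates = 1),
    "Skipping prevalence"
  )
  expect_equal(nrow(empty), 0)
})

test_that("sweep plots build without error", {
  cfg <- sim_config(n_samples = 300, seed = 4)
  sweep <- run_correlation_sweep(cfg, rho = c(0, 0.5), replicates = 2,
                                 seed = 8)
  p <- ggplot2::autoplot(sweep)
  expect_s3_class(p, "ggplot")
  fit <- fit_inverse(simulate_dataset(cfg), "x1", seed = 4)
  ds <- simulate_dataset(cfg)
  p2 <- plot_calibration(fit$estimates, ds$cr_true[fit$estimates$.row])
  expect_s3_class(p2, "ggplot")
})
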