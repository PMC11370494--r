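# Experiment drivers: simulate cohorts under controlled conditions, run the
# standard and inverse-learning estimators, and score them against the known
# resilience ground truth. Every driver returns a tidy tibble with one row
# per (condition, approach, estimate type, replicate).

# Deterministic per-cell seed derivation; stays inside 32-bit integer range.
derive_seed <- function(seed, ...) {
  offsets <- c(...)
  mix <- sum(c(as.double(seed), as.double(offsets) * 7919^seq_along(offsets)))
  as.integer(mix %% 2147483646) + 1L
}

# Rebuild a config with some fields replaced (re-validates).
modify_config <- function(config, ...) {
  stopifnot(inherits(config, "cr_sim_config"))
  args <- utils::modifyList(unclass(config), list(...))
  do.call(sim_config, args)
}

# Fit the requested approaches on one simulated dataset and score target-row
# estimates against cr_true. Approaches: "standard", "inverse_linear",
# "inverse_gbt". Inverse approaches contribute raw and corrected rows.
evaluate_approaches <- function(ds, predictors,
                                approaches = c("standard", "inverse_linear"),
                                seed = 1, cv_repeats = 5, cv_folds = 5,
                                tune = "once") {
  target <- !ds$is_expectation
  truth <- ds$cr_true[target]
  rows <- list()
  for (approach in approaches) {
    if (approach == "standard") {
      fit <- fit_standard(ds, predictors)
      est <- estimate_cr_standard(fit)[target]
      rows[[length(rows) + 1L]] <- dplyr::bind_cols(
        tibble::tibble(approach = "standard", estimate_type = "raw"),
        score_estimates(est, truth)
      )
    } else if (approach %in% c("inverse_linear", "inverse_gbt")) {
      learner <- if (approach == "inverse_gbt") "gbt" else "linear"
      fit <- fit_inverse(ds, predictors, learner = learner, correct = TRUE,
                         cv_repeats = cv_repeats, cv_folds = cv_folds,
                         seed = seed, tune = tune)
      for (type in c("raw", "corrected")) {
        est <- if (type == "raw") fit$estimates$raw_residual
               else fit$estimates$corrected_cr
        rows[[length(rows) + 1L]] <- dplyr::bind_cols(
          tibble::tibble(approach = approach, estimate_type = type),
          score_estimates(est, truth)
        )
      }
    } else {
      abort(sprintf("Unknown approach '%s'.", approach))
    }
  }
  dplyr::bind_rows(rows)
}

new_sweep <- function(results, swept) {
  out <- dplyr::bind_rows(results)
  attr(out, "swept") <- swept
  class(out) <- c("cr_sweep", class(out))
  out
}

#' Sweep the predictor subsets available to each approach
#'
#' Reproduces the predictor-selection experiment: over a grid of how many
#' expectation-informative and resilience-informative variables are offered
#' as predictors, simulate fresh cohorts and score each approach's estimates
#' on the target samples. With the standard approach, adding
#' resilience-informative predictors lets the single global regression
#' explain part of the resilience and shrinks it out of the residual; the
#' inverse-learning estimator, trained on expectation samples only, is
#' unaffected.
#'
#' @param config Base [sim_config()] (linear transforms).
#' @param n_expectation,n_cr Grids of how many expectation-block /
#'   resilience-block variables to include as predictors. Defaults
#'   `c(0, 3, 6, 9)` each.
#' @param approaches Subset of `"standard"`, `"inverse_linear"`,
#'   `"inverse_gbt"`.
#' @param replicates Independent replicate datasets per grid cell. Default 20.
#' @param seed Root seed; per-cell seeds are derived from it.
#' @param cv_repeats,cv_folds,tune Passed to [fit_inverse()].
#' @return A `cr_sweep` tibble: grid columns, `approach`, `estimate_type`,
#'   `replicate`, and the [score_estimates()] metrics.
#' @seealso [summarise_sweep()], [autoplot.cr_sweep()]
#' @export
run_predictor_sweep <- function(config = sim_config(),
                                n_expectation = c(0, 3, 6, 9),
                                n_cr = c(0, 3, 6, 9),
                                approaches = c("standard", "inverse_linear"),
                                replicates = 20, seed = 1,
                                cv_repeats = 5, cv_folds = 5, tune = "once") {
  grid <- expand.grid(n_expectation = n_expectation, n_cr = n_cr)
  results <- list()
  for (i in seq_len(nrow(grid))) {
    for (r in seq_len(replicates)) {
      cell_seed <- derive_seed(seed, i, r)
      ds <- simulate_dataset(modify_config(config, seed = cell_seed))
      predictors <- c(
        head(role_columns(ds, "expectation"), grid$n_expectation[i]),
        head(role_columns(ds, "cr"), grid$n_cr[i])
      )
      scored <- evaluate_approaches(ds, predictors, approaches,
                                    seed = cell_seed,
                                    cv_repeats = cv_repeats,
                                    cv_folds = cv_folds, tune = tune)
      results[[length(results) + 1L]] <- dplyr::bind_cols(
        tibble::tibble(n_expectation = grid$n_expectation[i],
                       n_cr = grid$n_cr[i], replicate = r),
        scored
      )
    }
  }
  new_sweep(results, swept = c("n_expectation", "n_cr"))
}

#' Sweep the correlation between expectation and resilience variables
#'
#' Simulates cohorts in which position-matched expectation-block and
#' resilience-block variables carry increasing pairwise correlation, and
#' scores both approaches given *expectation predictors only*. A fresh
#' dataset is drawn per correlation level and replicate. Correlation lets
#' the standard approach's global regression absorb resilience through the
#' correlated predictors even though no resilience-informative variable is
#' included.
#'
#' @param rho Correlation grid. Default `c(0, 0.25, 0.5, 0.75, 0.95)`.
#' @inheritParams run_predictor_sweep
#' @return A `cr_sweep` tibble with a `correlation` column.
#' @export
run_correlation_sweep <- function(config = sim_config(),
                                  rho = c(0, 0.25, 0.5, 0.75, 0.95),
                                  approaches = c("standard", "inverse_linear"),
                                  replicates = 20, seed = 1,
                                  cv_repeats = 5, cv_folds = 5, tune = "once") {
  results <- list()
  for (i in seq_along(rho)) {
    for (r in seq_len(replicates)) {
      cell_seed <- derive_seed(seed, i, r)
      ds <- simulate_dataset(
        modify_config(config, correlation = rho[i], seed = cell_seed)
      )
      predictors <- role_columns(ds, "expectation")
      scored <- evaluate_approaches(ds, predictors, approaches,
                                    seed = cell_seed,
                                    cv_repeats = cv_repeats,
                                    cv_folds = cv_folds, tune = tune)
      results[[length(results) + 1L]] <- dplyr::bind_cols(
        tibble::tibble(correlation = rho[i], replicate = r),
        scored
      )
    }
  }
  new_sweep(results, swept = "correlation")
}

#' Sweep the prevalence of resilience among the samples
#'
#' Varies the fraction of samples whose outcome carries a resilience
#' component (prevalence = 1 - expectation fraction) and scores the standard
#' approach under two predictor regimes: all informative predictors
#' (expectation + resilience blocks) or expectation predictors only. As
#' prevalence rises, the single global regression increasingly absorbs the
#' resilience signal, shrinking residuals toward zero; the calibration slope
#' of its estimates falls accordingly.
#'
#' @param prevalence Grid of resilience prevalences. Default
#'   `seq(0.1, 0.9, by = 0.1)`. Levels leaving fewer than
#'   `2 * block_size` expectation samples are skipped with a warning.
#' @param regime `"all_informative"` or `"expectation_only"` predictor set.
#' @inheritParams run_predictor_sweep
#' @return A `cr_sweep` tibble with `prevalence` and `regime` columns.
#' @export
run_prevalence_sweep <- function(config = sim_config(),
                                 prevalence = seq(0.1, 0.9, by = 0.1),
                                 regime = c("all_informative",
                                            "expectation_only"),
                                 approaches = "standard",
                                 replicates = 20, seed = 1,
                                 cv_repeats = 5, cv_folds = 5, tune = "once") {
  regime <- match.arg(regime)
  results <- list()
  for (i in seq_along(prevalence)) {
    exp_frac <- 1 - prevalence[i]
    if (exp_frac * config$n_samples < 2 * config$block_size) {
      warn(sprintf(
        "Skipping prevalence %.2f: only %.0f expectation samples would remain.",
        prevalence[i], exp_frac * config$n_samples
      ))
      next
    }
    for (r in seq_len(replicates)) {
      cell_seed <- derive_seed(seed, i, r)
      ds <- simulate_dataset(
        modify_config(config, expectation_fraction = exp_frac,
                      seed = cell_seed)
      )
      predictors <- switch(regime,
        all_informative = c(role_columns(ds, "expectation"),
                            role_columns(ds, "cr")),
        expectation_only = role_columns(ds, "expectation")
      )
      scored <- evaluate_approaches(ds, predictors, approaches,
                                    seed = cell_seed,
                                    cv_repeats = cv_repeats,
                                    cv_folds = cv_folds, tune = tune)
      results[[length(results) + 1L]] <- dplyr::bind_cols(
        tibble::tibble(prevalence = prevalence[i], regime = regime,
                       replicate = r),
        scored
      )
    }
  }
  new_sweep(results, swept = c("prevalence", "regime"))
}

#' Compare approaches under non-linear outcome transforms
#'
#' Runs the two non-linear scenarios with *all* variables offered as
#' predictors to every approach: `"linear_network"` (linear expectation
#' transform, random-network resilience transform) and `"friedman_linear"`
#' (non-linear benchmark expectation transform, linear resilience
#' transform). Scores the standard approach and the inverse-learning
#' approach with linear and gradient-boosted learners, raw and corrected.
#'
#' @param scenarios Subset of `"linear_network"`, `"friedman_linear"`.
#' @param replicates Replicate datasets per scenario. Default 10 (the
#'   boosted learner dominates runtime).
#' @inheritParams run_predictor_sweep
#' @return A `cr_sweep` tibble with a `scenario` column.
#' @export
run_nonlinear_scenarios <- function(config = sim_config(),
                                    scenarios = c("linear_network",
                                                  "friedman_linear"),
                                    approaches = c("standard",
                                                   "inverse_linear",
                                                   "inverse_gbt"),
                                    replicates = 10, seed = 1,
                                    cv_repeats = 5, cv_folds = 5,
                                    tune = "once") {
  scenarios <- match.arg(scenarios, several.ok = TRUE)
  kinds <- list(
    linear_network = list(f_kind = "linear", h_kind = "network"),
    friedman_linear = list(f_kind = "friedman", h_kind = "linear")
  )
  results <- list()
  for (i in seq_along(scenarios)) {
    sc <- scenarios[i]
    for (r in seq_len(replicates)) {
      cell_seed <- derive_seed(seed, i, r)
      ds <- simulate_dataset(
        modify_config(config, f_kind = kinds[[sc]]$f_kind,
                      h_kind = kinds[[sc]]$h_kind, seed = cell_seed)
      )
      predictors <- setdiff(names(ds),
                            c("cog_obs", "cr_true", "is_expectation", "noise"))
      scored <- evaluate_approaches(ds, predictors, approaches,
                                    seed = cell_seed,
                                    cv_repeats = cv_repeats,
                                    cv_folds = cv_folds, tune = tune)
      results[[length(results) + 1L]] <- dplyr::bind_cols(
        tibble::tibble(scenario = sc, replicate = r),
        scored
      )
    }
  }
  new_sweep(results, swept = "scenario")
}

#' Replicate-level summary of a sweep
#'
#' Averages the scoring metrics over replicates within each condition and
#' approach, with standard deviations.
#'
#' @param sweep A `cr_sweep` tibble from one of the `run_*` drivers.
#' @return A tibble with one row per condition x approach x estimate type and
#'   `mean_` / `sd_` columns for each metric.
#' @export
summarise_sweep <- function(sweep) {
  stopifnot(inherits(sweep, "cr_sweep"))
  metrics <- c("mse", "calibration_slope", "calibration_intercept",
               "r_squared")
  keys <- setdiff(names(sweep), c(metrics, "replicate", "truth_degenerate"))
  sweep |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::summarise(
      n_replicates = dplyr::n(),
      dplyr::across(
        dplyr::all_of(metrics),
        list(mean = ~ mean(.x), sd = ~ sd(.x)),
        .names = "{.fn}_{.col}"
      ),
      .groups = "drop"
    )
}
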