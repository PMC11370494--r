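#' Fit the expectation model of the inverse learning approach
#'
#' Trains a regression model to predict the observed outcome of the
#' *expectation* samples only — samples selected (by the user's phenotype
#' definition) to carry no resilience, so the model cannot learn resilience
#' associations out of the residual. Predictive performance and per-sample
#' prediction errors are measured by repeated k-fold cross-validation
#' (default 5 repeats of 5 folds); the out-of-fold errors
#' (observed minus out-of-fold prediction), averaged per sample across
#' repeats, later become the training targets of the error-correction model.
#' The returned model is refit on all expectation samples; cross-validation
#' serves diagnostics and error targets only.
#'
#' For `learner = "gbt"` (gradient-boosted trees), hyperparameters
#' (tree depth 2–4, learning rate 0.05–0.3, number of trees up to 500 with
#' early stopping) are selected by inner 3-fold cross-validation. By default
#' the search runs once on the full training set and the chosen parameters
#' are reused across the outer folds (`tune = "once"`); `tune = "nested"`
#' repeats the search inside every outer training fold.
#'
#' @param data Data frame of expectation samples only (filter with the
#'   membership indicator before calling, or use [fit_inverse()]).
#' @param predictors Character vector of predictor column names (may be
#'   empty with the linear learner: intercept-only expectation).
#' @param outcome Observed outcome column name. Default `"cog_obs"`.
#' @param learner Name of a registered learner (`"linear"`, `"gbt"`, or a
#'   user-registered one; see [register_learner()]).
#' @param cv_repeats,cv_folds Repeated cross-validation scheme. Defaults 5, 5.
#' @param seed Integer seed covering fold assignment and any learner
#'   randomness.
#' @param tune `"once"` or `"nested"` hyperparameter search placement (only
#'   meaningful for tunable learners).
#' @return A `cr_expectation_model` with the fitted final model, the
#'   averaged out-of-fold errors (`oof_errors`), the per-repeat out-of-fold
#'   prediction matrix, per-repeat cross-validated MSE / R-squared
#'   (`cv_performance`), and the training data needed by
#'   [fit_error_correction()]. Supports [tidy()] (per-repeat performance)
#'   and [glance()].
#' @examples
#' ds <- simulate_dataset(sim_config(seed = 5))
#' em <- fit_expectation_model(dplyr::filter(ds, is_expectation),
#'                             role_columns(ds, "expectation"), seed = 5)
#' glance(em)
#' @export
fit_expectation_model <- function(data, predictors, outcome = "cog_obs",
                                  learner = "linear",
                                  cv_repeats = 5, cv_folds = 5,
                                  seed = 1, tune = c("once", "nested")) {
  tune <- match.arg(tune)
  data <- as.data.frame(data)
  predictors <- as.character(predictors)
  missing_cols <- setdiff(c(predictors, outcome), names(data))
  if (length(missing_cols) > 0) {
    abort(sprintf("Missing columns: %s", paste(missing_cols, collapse = ", ")))
  }
  X <- as.matrix(data[predictors])
  y <- data[[outcome]]
  n <- length(y)
  if (n < cv_folds) {
    abort(sprintf("Need at least cv_folds = %d expectation samples; got %d.",
                  cv_folds, n))
  }
  degenerate <- var(y) == 0
  if (degenerate) {
    warn("Constant outcome among expectation samples; fit is degenerate.")
  }
  lrn <- get_learner(learner)

  state <- withr::with_seed(as.integer(seed), {
    shared_args <- if (tune == "once") lrn$tune(X, y) else NULL
    oof <- matrix(NA_real_, n, cv_repeats)
    for (r in seq_len(cv_repeats)) {
      fold_id <- sample(rep(seq_len(cv_folds), length.out = n))
      for (k in seq_len(cv_folds)) {
        test <- fold_id == k
        args <- shared_args %||%
          lrn$tune(X[!test, , drop = FALSE], y[!test])
        m <- lrn$fit(X[!test, , drop = FALSE], y[!test], args)
        oof[test, r] <- lrn$predict(m, X[test, , drop = FALSE])
      }
    }
    final_args <- shared_args %||% lrn$tune(X, y)
    final <- lrn$fit(X, y, final_args)
    list(oof = oof, final = final, args = final_args)
  })

  err <- y - state$oof
  cv_performance <- tibble::tibble(
    repeat_id = seq_len(cv_repeats),
    mse = colMeans(err^2),
    r_squared = 1 - colMeans(err^2) / mean((y - mean(y))^2)
  )

  structure(
    list(
      learner = learner,
      predictors = predictors,
      outcome = outcome,
      fitted_model = state$final,
      fit_args = state$args,
      cv_scheme = list(n_repeats = cv_repeats, n_folds = cv_folds,
                       seed = as.integer(seed)),
      oof_predictions = state$oof,
      oof_errors = rowMeans(err),
      cv_performance = cv_performance,
      training_X = X,
      training_y = y,
      n = n,
      degenerate = degenerate
    ),
    class = "cr_expectation_model"
  )
}

#' @export
print.cr_expectation_model <- function(x, ...) {
  cat(sprintf(
    "<cr_expectation_model: %s learner, %d samples, %d predictors, CV R^2 = %.4f>\n",
    x$learner, x$n, length(x$predictors), mean(x$cv_performance$r_squared)
  ))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.cr_expectation_model <- function(x, ...) x$cv_performance

#' @exportS3Method generics::glance
glance.cr_expectation_model <- function(x, ...) {
  tibble::tibble(
    learner = x$learner,
    n = x$n,
    n_predictors = length(x$predictors),
    cv_mse = mean(x$cv_performance$mse),
    cv_r_squared = mean(x$cv_performance$r_squared),
    oof_error_mean = mean(x$oof_errors)
  )
}

predict_expectation <- function(model, newdata) {
  newdata <- as.data.frame(newdata)
  missing_cols <- setdiff(model$predictors, names(newdata))
  if (length(missing_cols) > 0) {
    abort(sprintf("Missing predictor columns: %s",
                  paste(missing_cols, collapse = ", ")))
  }
  lrn <- get_learner(model$learner)
  lrn$predict(model$fitted_model, as.matrix(newdata[model$predictors]))
}

#' Raw residuals of target samples under a fitted expectation model
#'
#' Applies the expectation model to samples that may carry resilience and
#' returns `observed - predicted` per row. Target rows should be disjoint
#' from the model's training rows (the expectation subset).
#'
#' @param model A [fit_expectation_model()] object.
#' @param newdata Data frame of target samples with the model's predictor
#'   columns and the outcome column.
#' @param outcome Outcome column name; defaults to the model's.
#' @return Numeric vector of raw residuals.
#' @export
extract_residuals <- function(model, newdata, outcome = model$outcome) {
  stopifnot(inherits(model, "cr_expectation_model"))
  newdata <- as.data.frame(newdata)
  if (!outcome %in% names(newdata)) {
    abort(sprintf("Missing outcome column: %s", outcome))
  }
  newdata[[outcome]] - predict_expectation(model, newdata)
}

#' Fit the error-correction model on out-of-fold expectation errors
#'
#' Linear regression (default learner) of the expectation model's per-sample
#' averaged out-of-fold prediction error on the same predictors and samples
#' used to train the expectation model. Its predictions estimate the part of
#' a raw residual attributable to the expectation model's own error rather
#' than to resilience. When the expectation model's errors carry no
#' predictor signal — as for a well-specified linear learner — the fitted
#' slopes are near zero and correction is a no-op.
#'
#' @param model A [fit_expectation_model()] object with `oof_errors`.
#' @param learner Learner name for the correction model. Default `"linear"`.
#' @return A `cr_error_model` with the fitted regressor, its in-sample
#'   R-squared on the out-of-fold errors, and the predictor names.
#' @export
fit_error_correction <- function(model, learner = "linear") {
  stopifnot(inherits(model, "cr_expectation_model"))
  e <- model$oof_errors
  lrn <- get_learner(learner)
  fitted_model <- lrn$fit(model$training_X, e, lrn$tune(model$training_X, e))
  pred <- lrn$predict(fitted_model, model$training_X)
  ss_tot <- sum((e - mean(e))^2)
  structure(
    list(
      learner = learner,
      predictors = model$predictors,
      fitted_model = fitted_model,
      r_squared = if (ss_tot == 0) NA_real_ else 1 - sum((e - pred)^2) / ss_tot
    ),
    class = "cr_error_model"
  )
}

#' @export
print.cr_error_model <- function(x, ...) {
  cat(sprintf("<cr_error_model: %s learner on %d predictors, R^2 = %.4f>\n",
              x$learner, length(x$predictors), x$r_squared))
  invisible(x)
}

#' @export
predict.cr_error_model <- function(object, newdata, ...) {
  newdata <- as.data.frame(newdata)
  missing_cols <- setdiff(object$predictors, names(newdata))
  if (length(missing_cols) > 0) {
    abort(sprintf("Missing predictor columns: %s",
                  paste(missing_cols, collapse = ", ")))
  }
  lrn <- get_learner(object$learner)
  lrn$predict(object$fitted_model, as.matrix(newdata[object$predictors]))
}

#' Corrected resilience estimates from raw residuals
#'
#' Subtracts the error-correction model's predicted expectation-model error
#' from each raw residual: `corrected_cr = raw_residual - predicted_error`.
#' Both the raw and corrected estimates are returned so they can be compared.
#'
#' @param model A [fit_expectation_model()] object.
#' @param newdata Target samples (see [extract_residuals()]).
#' @param error_model Optional [fit_error_correction()] object; with `NULL`
#'   the predicted errors are zero and corrected equals raw.
#' @param outcome Outcome column name; defaults to the model's.
#' @return A tibble with columns `raw_residual`, `predicted_error`,
#'   `corrected_cr`.
#' @export
estimate_cr_inverse <- function(model, newdata, error_model = NULL,
                                outcome = model$outcome) {
  raw <- extract_residuals(model, newdata, outcome)
  predicted_error <- if (is.null(error_model)) {
    rep(0, length(raw))
  } else {
    predict(error_model, newdata)
  }
  tibble::tibble(
    raw_residual = raw,
    predicted_error = predicted_error,
    corrected_cr = raw - predicted_error
  )
}

#' Run the full inverse learning pipeline on one dataset
#'
#' Splits the data on a membership indicator, fits the expectation model on
#' the expectation samples, the error-correction model on their out-of-fold
#' errors, and returns raw and corrected resilience estimates for the target
#' (non-expectation) samples. Because the fitted models see only expectation
#' samples, the estimator is unaffected by how many target samples carry
#' resilience.
#'
#' @inheritParams fit_expectation_model
#' @param data Full cohort table including the membership column.
#' @param membership Name of the logical column that is `TRUE` for
#'   expectation samples. Default `"is_expectation"`.
#' @param correct Fit and apply the error-correction model? Default `TRUE`.
#' @return A `cr_inverse_fit` containing `expectation_model`, `error_model`
#'   (or `NULL`), and `estimates`: a tibble with the target rows' positions
#'   (`.row`), `raw_residual`, `predicted_error` and `corrected_cr`.
#'   Supports [tidy()] (the estimates) and [glance()].
#' @examples
#' ds <- simulate_dataset(sim_config(seed = 11))
#' fit <- fit_inverse(ds, role_columns(ds, "expectation"), seed = 11)
#' glance(fit)
#' @export
fit_inverse <- function(data, predictors, outcome = "cog_obs",
                        membership = "is_expectation",
                        learner = "linear", correct = TRUE,
                        cv_repeats = 5, cv_folds = 5, seed = 1,
                        tune = c("once", "nested")) {
  data <- tibble::as_tibble(data)
  if (!membership %in% names(data)) {
    abort(sprintf("Missing membership column: %s", membership))
  }
  is_exp <- as.logical(data[[membership]])
  if (anyNA(is_exp)) abort("Membership column must be boolean-coercible.")

  exp_data <- data[is_exp, , drop = FALSE]
  target_data <- data[!is_exp, , drop = FALSE]
  expectation_model <- fit_expectation_model(
    exp_data, predictors, outcome = outcome, learner = learner,
    cv_repeats = cv_repeats, cv_folds = cv_folds, seed = seed,
    tune = match.arg(tune)
  )
  error_model <- if (correct) fit_error_correction(expectation_model) else NULL
  estimates <- estimate_cr_inverse(expectation_model, target_data, error_model,
                                   outcome = outcome)
  estimates <- dplyr::bind_cols(tibble::tibble(.row = which(!is_exp)),
                                estimates)

  structure(
    list(
      expectation_model = expectation_model,
      error_model = error_model,
      estimates = estimates,
      membership = membership,
      n_expectation = sum(is_exp),
      n_target = sum(!is_exp)
    ),
    class = "cr_inverse_fit"
  )
}

#' @export
print.cr_inverse_fit <- function(x, ...) {
  cat(sprintf(
    "<cr_inverse_fit: %s learner, %d expectation / %d target samples, %s>\n",
    x$expectation_model$learner, x$n_expectation, x$n_target,
    if (is.null(x$error_model)) "uncorrected" else "error-corrected"
  ))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.cr_inverse_fit <- function(x, ...) x$estimates

#' @exportS3Method generics::glance
glance.cr_inverse_fit <- function(x, ...) {
  dplyr::bind_cols(
    glance(x$expectation_model),
    tibble::tibble(
      n_target = x$n_target,
      corrected = !is.null(x$error_model),
      error_model_r_squared = if (is.null(x$error_model)) NA_real_
                              else x$error_model$r_squared
    )
  )
}
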