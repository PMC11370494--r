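# Pluggable regression learners for the expectation model. A learner is a
# list of three functions:
#   tune(X, y)            -> list of fit arguments (may be empty)
#   fit(X, y, args)       -> opaque fitted model
#   predict(model, X)     -> numeric predictions
# Any regression algorithm can back the expectation model; linear least
# squares and gradient-boosted trees ship by default.

.learner_registry <- new.env(parent = emptyenv())

#' Register or look up an expectation-model learner
#'
#' The expectation model accepts any regression learner. A learner is a list
#' with functions `fit(X, y, args)` and `predict(model, X)`, plus an optional
#' `tune(X, y)` returning the `args` list for `fit` (defaults to no tuning).
#'
#' @param name Learner name, e.g. `"linear"` or `"gbt"`.
#' @param fit,predict,tune Learner functions; see Details.
#' @return `register_learner()` invisibly returns `name`; `get_learner()`
#'   the learner list; `list_learners()` the registered names.
#' @export
register_learner <- function(name, fit, predict, tune = NULL) {
  stopifnot(is.character(name), length(name) == 1,
            is.function(fit), is.function(predict))
  if (is.null(tune)) tune <- function(X, y) list()
  assign(name, list(tune = tune, fit = fit, predict = predict),
         envir = .learner_registry)
  invisible(name)
}

#' @rdname register_learner
#' @export
get_learner <- function(name) {
  if (!exists(name, envir = .learner_registry, inherits = FALSE)) {
    abort(sprintf("Unknown learner '%s'. Registered: %s",
                  name, paste(list_learners(), collapse = ", ")))
  }
  get(name, envir = .learner_registry, inherits = FALSE)
}

#' @rdname register_learner
#' @export
list_learners <- function() sort(ls(envir = .learner_registry))

# -- linear learner -----------------------------------------------------------

fit_linear_learner <- function(X, y, args = list()) {
  D <- cbind(1, X)
  sol <- min_norm_lstsq(D, y)
  list(coef = sol$coef)
}

predict_linear_learner <- function(model, X) {
  drop(cbind(1, X) %*% model$coef)
}

# -- gradient-boosted trees ---------------------------------------------------

gbt_base_params <- function() {
  list(objective = "reg:squarederror", nthread = 1,
       subsample = 1, colsample_bytree = 1)
}

# Small grid over depth and learning rate; number of trees chosen by inner
# 3-fold CV with early stopping (search ceiling 500 rounds).
tune_gbt <- function(X, y,
                     depth_grid = c(2L, 3L, 4L),
                     eta_grid = c(0.05, 0.1, 0.3),
                     max_rounds = 500L,
                     inner_folds = 3L,
                     early_stopping = 25L) {
  d <- xgboost::xgb.DMatrix(X, label = y)
  grid <- expand.grid(max_depth = depth_grid, eta = eta_grid)
  best <- NULL
  for (i in seq_len(nrow(grid))) {
    params <- c(gbt_base_params(),
                list(max_depth = grid$max_depth[i], eta = grid$eta[i]))
    cv <- xgboost::xgb.cv(
      params = params, data = d, nrounds = max_rounds,
      nfold = inner_folds, early_stopping_rounds = early_stopping,
      verbose = 0
    )
    log <- as.data.frame(cv$evaluation_log)
    it <- which.min(log$test_rmse_mean)
    rmse <- log$test_rmse_mean[it]
    if (is.null(best) || rmse < best$rmse) {
      best <- list(params = params, nrounds = log$iter[it], rmse = rmse)
    }
  }
  list(params = best$params, nrounds = best$nrounds)
}

fit_gbt_learner <- function(X, y, args = list()) {
  if (ncol(X) == 0) abort("The gradient-boosted learner needs >= 1 predictor.")
  if (is.null(args$params)) args <- tune_gbt(X, y)
  xgboost::xgb.train(
    params = args$params,
    data = xgboost::xgb.DMatrix(X, label = y),
    nrounds = args$nrounds,
    verbose = 0
  )
}

predict_gbt_learner <- function(model, X) {
  predict(model, xgboost::xgb.DMatrix(X))
}

# Registered at load time.
register_default_learners <- function() {
  register_learner("linear", fit_linear_learner, predict_linear_learner)
  register_learner("gbt", fit_gbt_learner, predict_gbt_learner,
                   tune = tune_gbt)
}

.onLoad <- function(libname, pkgname) {
  register_default_learners()
}
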