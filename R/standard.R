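# Minimum-norm least squares via SVD. Used instead of lm() so that exactly
# collinear designs (an intended experimental condition at correlation = 1)
# yield a deterministic solution rather than dropped columns.
min_norm_lstsq <- function(X, y, tol = 1e-10) {
  s <- svd(X)
  keep <- s$d > tol * s$d[1]
  rank <- sum(keep)
  dinv <- ifelse(keep, 1 / s$d, 0)
  coef <- s$v %*% (dinv * crossprod(s$u, y))
  list(coef = drop(coef), rank = rank)
}

#' Fit the standard residual approach
#'
#' Ordinary least squares of the observed outcome on the chosen predictors,
#' fit over *all* samples, with an intercept. The residuals are the standard
#' approach's per-sample resilience estimates: a positive residual means the
#' sample's observed cognition exceeds the linear model's prediction.
#'
#' Rank-deficient designs (e.g. perfectly collinear predictor pairs) are
#' solved by the minimum-norm pseudoinverse solution with a warning, so the
#' collinearity edge case runs deterministically. An empty predictor set
#' fits the intercept-only model (residuals are deviations from the mean).
#'
#' @param data Data frame with the outcome and predictor columns.
#' @param predictors Character vector of predictor column names (may be
#'   empty for an intercept-only fit).
#' @param outcome Name of the observed outcome column. Default `"cog_obs"`.
#' @return A `cr_standard_fit` with elements `coefficients` (named, with
#'   `(Intercept)` first), `fitted_values`, `residuals` (the resilience
#'   estimates), `r_squared`, `explained_variance`, `rank`, `predictors`,
#'   `outcome` and `n`. Supports [tidy()], [glance()], [augment()].
#' @examples
#' ds <- simulate_dataset(sim_config(seed = 3))
#' fit <- fit_standard(ds, role_columns(ds, "expectation"))
#' glance(fit)
#' @export
fit_standard <- function(data, predictors, outcome = "cog_obs") {
  data <- as.data.frame(data)
  predictors <- as.character(predictors)
  missing_cols <- setdiff(c(predictors, outcome), names(data))
  if (length(missing_cols) > 0) {
    abort(sprintf("Missing columns: %s", paste(missing_cols, collapse = ", ")))
  }
  y <- data[[outcome]]
  n <- length(y)
  if (n <= length(predictors) + 1) {
    abort("Need more samples than predictors plus intercept.")
  }

  X <- cbind(`(Intercept)` = rep(1, n),
             as.matrix(data[predictors]))
  sol <- min_norm_lstsq(X, y)
  if (sol$rank < ncol(X)) {
    warn(sprintf(
      "Rank-deficient design (rank %d of %d columns); minimum-norm least-squares solution used.",
      sol$rank, ncol(X)
    ))
  }
  fitted <- drop(X %*% sol$coef)
  residuals <- y - fitted
  ss_tot <- sum((y - mean(y))^2)
  r_squared <- if (ss_tot == 0) NA_real_ else 1 - sum(residuals^2) / ss_tot
  explained_variance <- if (ss_tot == 0) NA_real_ else 1 - var(residuals) / var(y)

  structure(
    list(
      coefficients = stats::setNames(sol$coef, colnames(X)),
      fitted_values = fitted,
      residuals = residuals,
      r_squared = r_squared,
      explained_variance = explained_variance,
      rank = sol$rank,
      predictors = predictors,
      outcome = outcome,
      n = n
    ),
    class = "cr_standard_fit"
  )
}

#' Per-sample resilience estimates from a standard fit
#'
#' Returns the fit's residuals (observed minus fitted outcome), the standard
#' approach's estimate of each sample's resilience.
#'
#' @param fit A [fit_standard()] object.
#' @return Numeric vector, one estimate per sample in fitting order.
#' @export
estimate_cr_standard <- function(fit) {
  stopifnot(inherits(fit, "cr_standard_fit"))
  fit$residuals
}

#' @export
print.cr_standard_fit <- function(x, ...) {
  cat(sprintf(
    "<cr_standard_fit: %d samples, %d predictors, R^2 = %.4f>\n",
    x$n, length(x$predictors), x$r_squared
  ))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.cr_standard_fit <- function(x, ...) {
  tibble::tibble(term = names(x$coefficients),
                 estimate = unname(x$coefficients))
}

#' @exportS3Method generics::glance
glance.cr_standard_fit <- function(x, ...) {
  tibble::tibble(
    r_squared = x$r_squared,
    explained_variance = x$explained_variance,
    n = x$n,
    n_predictors = length(x$predictors),
    rank = x$rank
  )
}

#' @exportS3Method generics::augment
augment.cr_standard_fit <- function(x, data = NULL, ...) {
  est <- tibble::tibble(
    .fitted = x$fitted_values,
    .resid = x$residuals,
    cr_estimate = x$residuals
  )
  if (is.null(data)) est else dplyr::bind_cols(tibble::as_tibble(data), est)
}
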