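#' Score resilience estimates against the simulated ground truth
#'
#' Computes the mean squared error of the estimates, the calibration line
#' (ordinary least squares of estimate on truth: slope 1 and intercept 0 for
#' unbiased estimation; slope below 1 indicates systematic shrinkage of the
#' estimates), and the squared correlation between estimate and truth.
#'
#' @param estimates Numeric vector of per-sample resilience estimates.
#' @param cr_true Numeric vector of true resilience values, same length.
#' @return A one-row tibble with `mse`, `calibration_slope`,
#'   `calibration_intercept`, `r_squared` and `truth_degenerate` (`TRUE`
#'   when `cr_true` has zero variance, in which case only `mse` is defined).
#' @examples
#' score_estimates(c(1, 2, 3), c(1, 2, 3))
#' @export
score_estimates <- function(estimates, cr_true) {
  estimates <- as.numeric(estimates)
  cr_true <- as.numeric(cr_true)
  if (length(estimates) != length(cr_true)) {
    abort("`estimates` and `cr_true` must have equal length.")
  }
  if (length(estimates) < 3) abort("Need at least 3 samples to score.")
  mse <- mean((estimates - cr_true)^2)
  if (var(cr_true) == 0) {
    warn("`cr_true` has zero variance; calibration is undefined.")
    return(tibble::tibble(
      mse = mse, calibration_slope = NA_real_,
      calibration_intercept = NA_real_, r_squared = NA_real_,
      truth_degenerate = TRUE
    ))
  }
  cal <- stats::lm.fit(cbind(1, cr_true), estimates)$coefficients
  tibble::tibble(
    mse = mse,
    calibration_slope = unname(cal[2]),
    calibration_intercept = unname(cal[1]),
    r_squared = cor(estimates, cr_true)^2,
    truth_degenerate = FALSE
  )
}
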