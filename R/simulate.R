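#' Draw the simulated design matrix for a configuration
#'
#' Samples `n_samples x n_variables` values from a multivariate standard
#' Gaussian. Each column is marginally standard normal. With
#' `correlation = rho > 0`, the k-th expectation-block variable and the k-th
#' resilience-block variable are given population correlation `rho`
#' (position-matched pairs; pairs are independent of each other and of all
#' other variables); `rho = 1` yields perfect collinearity. All other
#' pairwise correlations are zero.
#'
#' @param config A [sim_config()].
#' @return Numeric matrix with columns `x1..x<p>`.
#' @examples
#' X <- generate_design_matrix(sim_config(n_samples = 100, seed = 1))
#' dim(X)
#' @export
generate_design_matrix <- function(config) {
  stopifnot(inherits(config, "cr_sim_config"))
  withr::with_seed(config$seed, design_matrix_impl(config))
}

# RNG-stream implementation shared with simulate_dataset() so that the matrix
# returned standalone is identical to the one embedded in a dataset.
design_matrix_impl <- function(config) {
  n <- config$n_samples
  p <- config$n_variables
  X <- matrix(rnorm(n * p), n, p)
  rho <- config$correlation
  if (rho > 0) {
    # Gaussian pair construction: rho * a + sqrt(1 - rho^2) * independent b
    # keeps both margins standard normal with the requested correlation and
    # stays well-defined at rho = 1 (the covariance would otherwise be
    # singular there).
    for (k in seq_len(config$block_size)) {
      j_exp <- config$expectation_block[k]
      j_cr <- config$cr_block[k]
      X[, j_cr] <- rho * X[, j_exp] + sqrt(1 - rho^2) * X[, j_cr]
    }
  }
  colnames(X) <- variable_names(config)
  X
}

#' Simulate a cohort with known ground-truth resilience
#'
#' Generates the design matrix, randomly assigns an `expectation_fraction`
#' of samples to the expectation subset (seeded sampling without
#' replacement), and constructs the observed outcome
#' `cog_obs = f(X) + cr_true + noise`, where `cr_true = h(X)` for
#' non-expectation samples and exactly 0 for expectation samples.
#'
#' @param config A [sim_config()].
#' @return A tibble of class `cr_dataset` with columns `x1..x<p>`,
#'   `cog_obs`, `cr_true`, `is_expectation` and `noise` (the realized
#'   observation noise, all zero when `noise_sd = 0`). The generating
#'   config and per-variable roles are attached as attributes; see
#'   [dataset_config()], [variable_roles()] and [role_columns()].
#' @examples
#' ds <- simulate_dataset(sim_config(seed = 42))
#' sum(ds$is_expectation)
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "cr_sim_config"))
  tr <- config_transforms(config)

  parts <- withr::with_seed(config$seed, {
    X <- design_matrix_impl(config)
    n <- config$n_samples
    n_exp <- round(config$expectation_fraction * n)
    exp_rows <- sample.int(n, n_exp)
    noise <- rnorm(n, 0, config$noise_sd)
    list(X = X, exp_rows = exp_rows, noise = noise)
  })

  n <- config$n_samples
  is_expectation <- logical(n)
  is_expectation[parts$exp_rows] <- TRUE
  cr_true <- predict(tr$h, parts$X)
  cr_true[is_expectation] <- 0
  cog_obs <- predict(tr$f, parts$X) + cr_true + parts$noise

  out <- tibble::as_tibble(as.data.frame(parts$X))
  out$cog_obs <- cog_obs
  out$cr_true <- cr_true
  out$is_expectation <- is_expectation
  out$noise <- parts$noise

  attr(out, "config") <- config
  attr(out, "roles") <- config_roles(config)
  class(out) <- c("cr_dataset", class(out))
  out
}

#' Accessors for simulated-dataset provenance
#'
#' @param data A `cr_dataset` produced by [simulate_dataset()].
#' @return `dataset_config()` returns the generating [sim_config()];
#'   `variable_roles()` a tibble with one row per simulated variable and its
#'   role (`"expectation"`, `"cr"` or `"noise"`); `role_columns()` the
#'   column names holding a given role.
#' @export
dataset_config <- function(data) {
  cfg <- attr(data, "config")
  if (is.null(cfg)) abort("`data` carries no simulation config attribute.")
  cfg
}

#' @rdname dataset_config
#' @export
variable_roles <- function(data) {
  roles <- attr(data, "roles")
  if (is.null(roles)) abort("`data` carries no variable-role attribute.")
  tibble::tibble(variable = names(roles), role = unname(roles))
}

#' @rdname dataset_config
#' @param role One of `"expectation"`, `"cr"`, `"noise"`.
#' @export
role_columns <- function(data, role = c("expectation", "cr", "noise")) {
  role <- match.arg(role)
  roles <- attr(data, "roles")
  if (is.null(roles)) abort("`data` carries no variable-role attribute.")
  names(roles)[roles == role]
}
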