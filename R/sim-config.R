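#' Configuration for a ground-truth resilience simulation
#'
#' Describes one synthetic cohort: a Gaussian design matrix whose columns are
#' split into an expectation-informative block, a resilience-informative block
#' and an uninformative block; an outcome built as
#' `cog_obs = f(X) + cr + noise`, where `f` depends only on the expectation
#' block and the resilience shift `cr = h(X)` (non-zero only for samples not
#' in the expectation subset) depends only on the resilience block.
#'
#' @param n_samples Number of rows (cohort size). Default 1000.
#' @param n_variables Number of simulated variables. Default 27.
#' @param block_size Number of variables per role block. Default 9.
#' @param expectation_block,cr_block,noise_block Integer column indices of the
#'   three role blocks. Must be pairwise disjoint subsets of
#'   `1:n_variables`. Defaults: consecutive blocks `1:9`, `10:18`, `19:27`.
#' @param expectation_fraction Fraction of samples whose outcome carries no
#'   resilience component (the "expectation" subset). Default 1/3. Must
#'   satisfy `expectation_fraction * n_samples >= 2 * block_size` so that
#'   expectation models can be fit.
#' @param correlation Pairwise correlation, in `[0, 1]`, between the k-th
#'   expectation-block variable and the k-th resilience-block variable
#'   (position-matched pairs, independent across pairs). 1 gives perfect
#'   collinearity. Default 0.
#' @param f_kind Functional form of the expectation transform `f`:
#'   `"linear"` (equal-coefficient dot product over its block) or
#'   `"friedman"` (a deterministic non-linear benchmark form, see
#'   [friedman_transform()]).
#' @param h_kind Functional form of the resilience transform `h`: `"linear"`
#'   or `"network"` (fixed random-weight neural network, see
#'   [network_transform()]).
#' @param coefficient_value Shared non-zero coefficient used by linear
#'   transforms. Default 1.
#' @param noise_sd Standard deviation of additive Gaussian observation noise
#'   on the outcome. Default 0 (the outcome decomposition is exact).
#' @param seed Integer seed; all randomness in [simulate_dataset()] and
#'   [generate_design_matrix()] derives from it.
#'
#' @return A `cr_sim_config` list with the validated fields.
#' @seealso [simulate_dataset()], [generate_design_matrix()]
#' @examples
#' cfg <- sim_config(seed = 7)
#' cfg
#' @export
sim_config <- function(n_samples = 1000,
                       n_variables = 27,
                       block_size = 9,
                       expectation_block = seq_len(block_size),
                       cr_block = block_size + seq_len(block_size),
                       noise_block = 2L * block_size + seq_len(block_size),
                       expectation_fraction = 1 / 3,
                       correlation = 0,
                       f_kind = c("linear", "friedman"),
                       h_kind = c("linear", "network"),
                       coefficient_value = 1,
                       noise_sd = 0,
                       seed = 1L) {
  f_kind <- match.arg(f_kind)
  h_kind <- match.arg(h_kind)

  stopifnot(
    is.numeric(n_samples), length(n_samples) == 1, n_samples >= 1,
    is.numeric(n_variables), length(n_variables) == 1, n_variables >= 1,
    is.numeric(block_size), length(block_size) == 1, block_size >= 1,
    is.numeric(coefficient_value), length(coefficient_value) == 1,
    is.numeric(seed), length(seed) == 1
  )
  n_samples <- as.integer(n_samples)
  n_variables <- as.integer(n_variables)
  block_size <- as.integer(block_size)

  expectation_block <- as.integer(expectation_block)
  cr_block <- as.integer(cr_block)
  noise_block <- as.integer(noise_block)
  blocks <- list(
    expectation = expectation_block,
    cr = cr_block,
    noise = noise_block
  )
  all_idx <- unlist(blocks)
  if (anyDuplicated(all_idx) > 0) {
    abort("The expectation, cr and noise blocks must be pairwise disjoint.")
  }
  if (any(all_idx < 1L) || any(all_idx > n_variables)) {
    abort(sprintf(
      "Block indices must lie in 1..%d (got range %d..%d).",
      n_variables, min(all_idx), max(all_idx)
    ))
  }

  if (!is.numeric(expectation_fraction) || length(expectation_fraction) != 1 ||
      expectation_fraction <= 0 || expectation_fraction > 1) {
    abort("`expectation_fraction` must be a single number in (0, 1].")
  }
  if (expectation_fraction * n_samples < 2 * block_size) {
    abort(sprintf(
      paste0(
        "Too few expectation samples to fit models: ",
        "expectation_fraction * n_samples = %.1f < 2 * block_size = %d."
      ),
      expectation_fraction * n_samples, 2L * block_size
    ))
  }
  if (!is.numeric(correlation) || length(correlation) != 1 ||
      is.na(correlation) || correlation < 0 || correlation > 1) {
    abort("`correlation` must be a single number in [0, 1].")
  }
  if (correlation > 0 &&
      (length(expectation_block) < block_size || length(cr_block) < block_size)) {
    abort("Correlated simulation requires full expectation and cr blocks.")
  }
  if (!is.numeric(noise_sd) || length(noise_sd) != 1 || noise_sd < 0) {
    abort("`noise_sd` must be a single non-negative number.")
  }

  structure(
    list(
      n_samples = n_samples,
      n_variables = n_variables,
      block_size = block_size,
      expectation_block = expectation_block,
      cr_block = cr_block,
      noise_block = noise_block,
      expectation_fraction = expectation_fraction,
      correlation = correlation,
      f_kind = f_kind,
      h_kind = h_kind,
      coefficient_value = coefficient_value,
      noise_sd = noise_sd,
      seed = as.integer(seed)
    ),
    class = "cr_sim_config"
  )
}

#' @export
print.cr_sim_config <- function(x, ...) {
  cat("<cr_sim_config>\n")
  cat(sprintf("  samples: %d, variables: %d (blocks of %d)\n",
              x$n_samples, x$n_variables, x$block_size))
  cat(sprintf("  expectation fraction: %.3f, correlation: %.2f\n",
              x$expectation_fraction, x$correlation))
  cat(sprintf("  f: %s, h: %s, coefficient: %g, noise sd: %g, seed: %d\n",
              x$f_kind, x$h_kind, x$coefficient_value, x$noise_sd, x$seed))
  invisible(x)
}

#' Read a simulation configuration from a YAML file
#'
#' The file holds key-value pairs mirroring the arguments of [sim_config()];
#' missing keys take the defaults.
#'
#' @param path Path to a YAML file.
#' @return A `cr_sim_config`.
#' @export
read_sim_config <- function(path) {
  vals <- yaml::read_yaml(path)
  unknown <- setdiff(names(vals), names(formals(sim_config)))
  if (length(unknown) > 0) {
    abort(sprintf("Unknown configuration keys: %s",
                  paste(unknown, collapse = ", ")))
  }
  do.call(sim_config, vals)
}

variable_names <- function(config) {
  paste0("x", seq_len(config$n_variables))
}

config_roles <- function(config) {
  roles <- rep("noise", config$n_variables)
  roles[config$expectation_block] <- "expectation"
  roles[config$cr_block] <- "cr"
  names(roles) <- variable_names(config)
  roles
}
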