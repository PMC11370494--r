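#' Outcome transforms with a declared informative support
#'
#' A `cr_transform` wraps a function mapping a numeric matrix (samples x
#' variables) to one real value per row, together with the index set of
#' variables it actually uses (its support). Transforms are the building
#' blocks of the simulated outcome: `f` generates the expectation component
#' and `h` the resilience shift. By construction a transform is invariant to
#' perturbations of variables outside its support.
#'
#' @param fn Function taking a numeric matrix and returning a numeric vector
#'   of length `nrow`.
#' @param support Integer indices of the variables the transform depends on.
#' @param kind Character label for printing.
#' @return A `cr_transform` object.
#' @keywords internal
new_transform <- function(fn, support, kind) {
  structure(
    list(fn = fn, support = as.integer(support), kind = kind),
    class = "cr_transform"
  )
}

#' @export
print.cr_transform <- function(x, ...) {
  cat(sprintf("<cr_transform: %s, support {%s}>\n",
              x$kind, paste(x$support, collapse = ", ")))
  invisible(x)
}

#' Evaluate a transform on a matrix or data frame of variables
#'
#' @param object A `cr_transform`.
#' @param newdata Numeric matrix or data frame with at least
#'   `max(object$support)` columns; rows are samples.
#' @param ... Unused.
#' @return Numeric vector, one value per row.
#' @export
predict.cr_transform <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  if (ncol(X) < max(object$support)) {
    abort(sprintf(
      "Transform needs at least %d columns; got %d.",
      max(object$support), ncol(X)
    ))
  }
  object$fn(X)
}

#' Linear transform: equal-coefficient dot product over its support
#'
#' `g(x) = coefficient * sum(x[support])`: every informative variable shares
#' one non-zero coefficient, the form used for the linear expectation and
#' resilience components of the simulation.
#'
#' @param support Non-empty integer index set of informative variables.
#' @param coefficient Shared coefficient; must be non-zero.
#' @return A `cr_transform`.
#' @examples
#' g <- linear_transform(1:3)
#' predict(g, matrix(1:6, nrow = 2, byrow = TRUE))
#' @export
linear_transform <- function(support, coefficient = 1) {
  support <- as.integer(support)
  if (length(support) == 0) abort("`support` must be non-empty.")
  if (!is.numeric(coefficient) || length(coefficient) != 1 || coefficient == 0) {
    abort("`coefficient` must be a single non-zero number.")
  }
  force(coefficient)
  new_transform(
    fn = function(X) coefficient * rowSums(X[, support, drop = FALSE]),
    support = support,
    kind = sprintf("linear (coefficient %g)", coefficient)
  )
}

#' Non-linear benchmark transform (Friedman form) over nine variables
#'
#' A deterministic non-linear regression benchmark. Inputs are mapped from
#' the standard-Gaussian scale to `[0, 1]` through the standard normal CDF,
#' then the classic benchmark surface
#' `10 sin(pi u1 u2) + 20 (u3 - 0.5)^2 + 10 u4 + 5 u5`
#' is evaluated on the first five support variables, plus the same surface's
#' first three terms `10 sin(pi u6 u7) + 20 (u8 - 0.5)^2 + 10 u9` on the
#' remaining four, so that all nine support variables are informative.
#'
#' @param support Integer index set; must have exactly 9 elements.
#' @return A `cr_transform`.
#' @export
friedman_transform <- function(support) {
  support <- as.integer(support)
  if (length(support) != 9) {
    abort(sprintf("`support` must have exactly 9 variables; got %d.",
                  length(support)))
  }
  new_transform(
    fn = function(X) {
      U <- pnorm(X[, support, drop = FALSE])
      10 * sin(pi * U[, 1] * U[, 2]) + 20 * (U[, 3] - 0.5)^2 +
        10 * U[, 4] + 5 * U[, 5] +
        10 * sin(pi * U[, 6] * U[, 7]) + 20 * (U[, 8] - 0.5)^2 +
        10 * U[, 9]
    },
    support = support,
    kind = "friedman"
  )
}

#' Fixed random-weight neural-network transform
#'
#' A one-hidden-layer tanh network whose weights are drawn once from `seed`
#' and then frozen: `g(x) = w2' tanh(W1 x + b1)`. First-layer columns for
#' variables outside `support` are zeroed, so only support variables are
#' informative. The output is centred and rescaled to unit empirical variance
#' on a seeded standard-Gaussian reference sample, giving the resilience
#' shift a stable scale across seeds.
#'
#' @param support Non-empty integer index set of informative variables.
#' @param n_variables Total number of input variables (network input width).
#' @param seed Integer seed for the weights and the reference sample.
#' @param hidden_units Hidden-layer width. Default 16.
#' @return A `cr_transform`.
#' @export
network_transform <- function(support, n_variables, seed, hidden_units = 16L) {
  support <- as.integer(support)
  if (length(support) == 0) abort("`support` must be non-empty.")
  n_variables <- as.integer(n_variables)
  if (max(support) > n_variables) {
    abort("`support` indices exceed `n_variables`.")
  }

  pars <- withr::with_seed(as.integer(seed), {
    W1 <- matrix(rnorm(hidden_units * n_variables), hidden_units, n_variables)
    W1[, setdiff(seq_len(n_variables), support)] <- 0
    b1 <- rnorm(hidden_units)
    w2 <- rnorm(hidden_units)
    ref <- matrix(rnorm(4000L * n_variables), 4000L, n_variables)
    list(W1 = W1, b1 = b1, w2 = w2, ref = ref)
  })
  raw <- function(X) {
    H <- tanh(sweep(X %*% t(pars$W1), 2, pars$b1, "+"))
    as.vector(H %*% pars$w2)
  }
  ref_out <- raw(pars$ref)
  centre <- mean(ref_out)
  scale <- sd(ref_out)
  if (scale == 0) scale <- 1 # degenerate draw; keep the map well-defined

  new_transform(
    fn = function(X) (raw(X) - centre) / scale,
    support = support,
    kind = sprintf("random network (%d tanh units, seed %d)",
                   hidden_units, as.integer(seed))
  )
}

# Build the f / h pair a config asks for. The network seed is derived from the
# config seed so a config fully determines its transforms.
config_transforms <- function(config) {
  f <- switch(config$f_kind,
    linear = linear_transform(config$expectation_block,
                              config$coefficient_value),
    friedman = friedman_transform(config$expectation_block)
  )
  h <- switch(config$h_kind,
    linear = linear_transform(config$cr_block, config$coefficient_value),
    network = network_transform(config$cr_block, config$n_variables,
                                seed = config$seed)
  )
  list(f = f, h = h)
}
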