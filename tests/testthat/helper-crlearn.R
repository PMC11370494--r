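# Shared helpers: small configurations that keep unit tests fast while
# respecting the simulator's invariants (expectation samples >= 2 blocks).

small_config <- function(...) {
  sim_config(n_samples = 150, n_variables = 9, block_size = 3, ...)
}

# Default-sized config (1000 x 27) with overrides.
default_config <- function(...) sim_config(...)

sim_columns <- function(ds) setdiff(names(ds),
                                    c("cog_obs", "cr_true", "is_expectation",
                                      "noise"))

target_truth <- function(ds, fit) ds$cr_true[fit$estimates$.row]
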