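#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

# Single positive-integer seed check; all stochastic entry points funnel
# through here so that an invalid seed fails loudly, not silently.
check_seed <- function(seed) {
  if (is.null(seed)) return(invisible(NULL))
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed) ||
      seed != as.integer(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  invisible(as.integer(seed))
}

set_seed_if <- function(seed) {
  seed <- check_seed(seed)
  if (!is.null(seed)) set.seed(seed)
  invisible(seed)
}

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lower || x > upper) {
    stop(sprintf("`%s` must be a single finite number in [%s, %s]",
                 name, format(lower), format(upper)), call. = FALSE)
  }
  invisible(x)
}
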