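# Condition helpers shared across the package. Two error classes map onto the
# CLI exit codes: validation errors (bad input, exit 2) and numerical /
# degeneracy errors (exit 3).

stop_validation <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("pade_validation_error", "pade_error")))
}

stop_numerical <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("pade_numerical_error", "pade_error")))
}

assert_scalar_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0 || x >= 1)
    stop_validation("`%s` must be a single number strictly between 0 and 1, got %s",
                    name, deparse(x))
  invisible(x)
}
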