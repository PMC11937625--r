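# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

# run code under a fixed RNG seed without disturbing the caller's RNG state;
# seed = NULL means "use the ambient RNG stream"
with_seed_or_ambient <- function(seed, code) {
  if (is.null(seed)) {
    force(code)
  } else {
    withr::with_seed(as.integer(seed), code)
  }
}

stop_config <- function(field, msg) {
  stop(sprintf("invalid configuration field '%s': %s", field, msg), call. = FALSE)
}

stop_data <- function(msg, ...) {
  stop(sprintf(msg, ...), call. = FALSE)
}

is_count_scalar <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x == round(x)
}

is_proportion <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x <= 1
}
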