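# Classed conditions so callers (and tests) can distinguish failure modes.
# All abort helpers signal a condition inheriting from "somase_error".

somase_abort <- function(message, class, ...) {
  stop(errorCondition(message, ..., class = c(class, "somase_error")))
}

abort_format <- function(message, ...) somase_abort(message, "somase_format_error", ...)
abort_value <- function(message, ...) somase_abort(message, "somase_value_error", ...)
abort_duplicate <- function(message, ...) somase_abort(message, "somase_duplicate_error", ...)
abort_io <- function(message, ...) somase_abort(message, "somase_io_error", ...)
abort_usage <- function(message, ...) somase_abort(message, "somase_usage_error", ...)
abort_precondition <- function(message, ...) somase_abort(message, "somase_precondition_error", ...)
abort_insufficient_data <- function(message, ...) somase_abort(message, "somase_insufficient_data_error", ...)
abort_join <- function(message, ...) somase_abort(message, "somase_join_error", ...)
abort_config <- function(message, ...) somase_abort(message, "somase_config_error", ...)

`%||%` <- function(a, b) if (is.null(a)) b else a

# Run an expression with a private RNG stream: saves and restores the
# caller's .Random.seed so simulation never perturbs user randomness.
with_private_seed <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed), kind = "Mersenne-Twister", normal.kind = "Inversion")
  expr
}
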