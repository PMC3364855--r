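# Internal helpers shared across modules.

abort_format <- function(msg, ...) {
  rlang::abort(msg, class = "synlethal_format_error", ...)
}

abort_validation <- function(msg, ...) {
  rlang::abort(msg, class = "synlethal_validation_error", ...)
}

abort_config <- function(msg, ...) {
  rlang::abort(msg, class = "synlethal_config_error", ...)
}

abort_domain <- function(msg, ...) {
  rlang::abort(msg, class = "synlethal_domain_error", ...)
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
# Keeps every stochastic routine a pure function of (inputs, seed).
local_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    abort_config("`seed` must be a single finite number.")
  }
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(seed)
  force(code)
}

`%||%` <- rlang::`%||%`
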