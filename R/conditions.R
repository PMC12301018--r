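#' @keywords internal
"_PACKAGE"

# Structured condition helpers. Every user-facing failure mode carries a
# condition class so callers (and the CLI exit-code mapping) can dispatch on
# the kind of failure rather than on message text.

bfq_abort <- function(message, class) {
  stop(structure(
    class = c(class, "bfq_error", "error", "condition"),
    list(message = message, call = sys.call(-1))
  ))
}

abort_config     <- function(msg) bfq_abort(msg, "bfq_config_error")
abort_format     <- function(msg) bfq_abort(msg, "bfq_format_error")
abort_metadata   <- function(msg) bfq_abort(msg, "bfq_metadata_error")
abort_validation <- function(msg) bfq_abort(msg, "bfq_validation_error")
abort_empty      <- function(msg) bfq_abort(msg, "bfq_empty_input_error")
abort_degenerate <- function(msg) bfq_abort(msg, "bfq_degenerate_error")
abort_division   <- function(msg) bfq_abort(msg, "bfq_division_error")

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state
# afterwards. NULL seed means "use the current stream".
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    seed <- as.integer(seed)
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (had) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    }, add = TRUE)
    set.seed(seed)
  }
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
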