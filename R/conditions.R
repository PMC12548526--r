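# Classed conditions so callers (and the CLI) can map failures to exit codes:
# usage errors -> 1, data/format/index errors -> 2.

adx_error <- function(class, message, call = sys.call(-1), ...) {
  stop(structure(
    class = c(class, "annodex_error", "error", "condition"),
    list(message = message, call = call, ...)
  ))
}

adx_usage_error <- function(message, ...) {
  adx_error("annodex_usage_error", message, call = sys.call(-1), ...)
}

adx_data_error <- function(message, ...) {
  adx_error("annodex_data_error", message, call = sys.call(-1), ...)
}

#' @noRd
adx_malformed_error <- function(message, line_no = NA_integer_, ...) {
  adx_error(c("annodex_malformed_error", "annodex_data_error"),
            message, call = sys.call(-1), line_no = line_no, ...)
}

adx_stale_error <- function(message, ...) {
  adx_error(c("annodex_stale_error", "annodex_data_error"),
            message, call = sys.call(-1), ...)
}

adx_missing_index_error <- function(message, extension = NA_character_, ...) {
  adx_error(c("annodex_missing_index_error", "annodex_data_error"),
            message, call = sys.call(-1), extension = extension, ...)
}

adx_warn <- function(message, class = "annodex_warning") {
  warning(warningCondition(message, class = c(class, "annodex_warning")))
}

# Run an expression with a fixed RNG state, restoring the caller's state.
# Generators must be pure functions of (parameters, seed).
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
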