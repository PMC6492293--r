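#' Classed error conditions
#'
#' All user-facing failures in discoursenet signal classed conditions so
#' callers (and the CLI) can distinguish schema problems from data problems
#' without parsing message strings.
#'
#' @param class character; condition subclass, e.g. "dn_schema_error".
#' @param msg message text.
#' @param ... fields stored on the condition object.
#' @keywords internal
dn_abort <- function(class, msg, ...) {
  cond <- structure(
    class = c(class, "dn_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  )
  stop(cond)
}

# Locale-independent (byte order) sort; all deterministic orderings in the
# package go through this so outputs do not depend on the session locale.
dn_sort <- function(x) sort(x, method = "radix")
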