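# Structured error conditions shared across the package. Every error is a
# "wellcount_error"; the CLI maps subclasses to exit codes.

wc_abort <- function(class, message, ..., call = sys.call(-1)) {
  cond <- structure(
    class = c(class, "wellcount_error", "error", "condition"),
    list(message = message, call = call, ...)
  )
  stop(cond)
}

wc_check <- function(ok, class, message, ...) {
  if (!isTRUE(ok)) wc_abort(class, message, ..., call = sys.call(-2))
  invisible(TRUE)
}
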