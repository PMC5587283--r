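# Classed conditions so callers can distinguish failure modes programmatically.
# All diamorph errors inherit from "dmq_error".

stop_dmq <- function(class, msg, ...) {
  if (length(list(...))) msg <- sprintf(msg, ...)
  stop(structure(
    class = c(class, "dmq_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

#' @keywords internal
assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lower || x > upper) {
    stop_dmq("dmq_domain_error", "`%s` must be a finite number in [%s, %s]",
             name, format(lower), format(upper))
  }
  invisible(x)
}
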