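# Classed conditions so callers can branch on failure modes programmatically.
# Every error raised by the package carries class "leafallom_error" plus one
# of the specific classes below:
#   leafallom_domain_error      - invalid argument values (negative lengths, ...)
#   leafallom_data_error        - malformed/insufficient data (files, records)
#   leafallom_config_error      - invalid simulation or dialect configuration
#   leafallom_convergence_error - optimiser failure (carries diagnostics)
#   leafallom_undefined_threshold - threshold asked for at b = 1
#   leafallom_perfect_fit       - AIC requested for rss = 0

stop_leafallom <- function(subclass, message, ..., call. = FALSE) {
  cond <- structure(
    class = c(subclass, "leafallom_error", "error", "condition"),
    list(message = message, call = if (call.) sys.call(-1), ...)
  )
  stop(cond)
}

warn_leafallom <- function(subclass, message, ...) {
  cond <- structure(
    class = c(subclass, "leafallom_warning", "warning", "condition"),
    list(message = message, call = NULL, ...)
  )
  warning(cond)
}
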