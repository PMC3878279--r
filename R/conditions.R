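# Classed conditions so callers can distinguish per-well analysis failures
# (recoverable: the well is reported unevaluable) from I/O, schema and domain
# errors (hard failures).

ana_abort <- function(message, class, call = sys.call(-1)) {
  stop(structure(
    class = c(class, "anascreen_error", "error", "condition"),
    list(message = message, call = call)
  ))
}

ana_io_error         <- function(msg) ana_abort(msg, "ana_io_error")
ana_format_error     <- function(msg) ana_abort(msg, "ana_format_error")
ana_schema_error     <- function(msg) ana_abort(msg, "ana_schema_error")
ana_validation_error <- function(msg) ana_abort(msg, "ana_validation_error")
ana_analysis_error   <- function(msg) ana_abort(msg, "ana_analysis_error")
ana_domain_error     <- function(msg) ana_abort(msg, "ana_domain_error")
ana_generation_error <- function(msg) ana_abort(msg, "ana_generation_error")
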