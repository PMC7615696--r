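# Classed conditions so callers (and the CLI) can branch on failure mode.

nvc_error <- function(class, message, ..., call = sys.call(-1)) {
  stop(structure(
    class = c(class, "nvc_error", "error", "condition"),
    list(message = message, call = call, ...)
  ))
}

#' @noRd
stop_invalid_protocol <- function(message, ...) {
  nvc_error("nvc_invalid_protocol", message, ...)
}

#' @noRd
stop_invalid_parameter <- function(message, ...) {
  nvc_error("nvc_invalid_parameter", message, ...)
}

#' @noRd
stop_integration_failure <- function(message, state = NULL, time = NULL) {
  nvc_error("nvc_integration_failure", message, state = state, time = time)
}

#' @noRd
stop_configuration_error <- function(message, ...) {
  nvc_error("nvc_configuration_error", message, ...)
}

#' @noRd
stop_comparison_error <- function(message, ...) {
  nvc_error("nvc_comparison_error", message, ...)
}
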