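# Classed conditions so callers (and the pipeline's per-pair isolation) can
# distinguish configuration errors, validation errors and method
# applicability without string matching.

dtmr_error <- function(message, class, call = sys.call(-1), data = list()) {
  structure(
    class = c(class, "dtmr_error", "error", "condition"),
    list(message = message, call = call, data = data)
  )
}

stop_config <- function(message, data = list()) {
  stop(dtmr_error(message, "dtmr_config_error", data = data))
}

stop_validation <- function(message, data = list()) {
  stop(dtmr_error(message, "dtmr_validation_error", data = data))
}

stop_not_applicable <- function(message, data = list()) {
  stop(dtmr_error(message, "dtmr_not_applicable", data = data))
}

#' @noRd
`%||%` <- function(x, y) if (is.null(x)) y else x
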