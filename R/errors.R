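# Condition helpers: every user-facing failure carries a dcadose_* class so
# callers (and the CLI) can map it to an exit code.

abort_input <- function(msg, ...) {
  abort(msg, class = c("dcadose_input_error", "dcadose_error"), ...)
}

abort_config <- function(msg, ...) {
  abort(msg, class = c("dcadose_config_error", "dcadose_input_error",
                       "dcadose_error"), ...)
}

abort_format <- function(msg, ...) {
  abort(msg, class = c("dcadose_format_error", "dcadose_input_error",
                       "dcadose_error"), ...)
}

abort_insufficient <- function(msg, ...) {
  abort(msg, class = c("dcadose_insufficient_data", "dcadose_error"), ...)
}

abort_degenerate <- function(msg, ...) {
  abort(msg, class = c("dcadose_degenerate_data", "dcadose_error"), ...)
}

abort_fit <- function(msg, ...) {
  abort(msg, class = c("dcadose_fit_error", "dcadose_numeric_error",
                       "dcadose_error"), ...)
}

abort_numeric <- function(msg, ...) {
  abort(msg, class = c("dcadose_numeric_error", "dcadose_error"), ...)
}
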