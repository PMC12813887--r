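# Classed conditions so the CLI can map failures to exit codes:
#   config/usage -> cardyn_config_error, data/format -> cardyn_data_error,
#   numerical failure -> cardyn_numeric_error.

stop_config <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c("cardyn_config_error", "cardyn_error")))
}

stop_data <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c("cardyn_data_error", "cardyn_error")))
}

stop_numeric <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c("cardyn_numeric_error", "cardyn_error")))
}
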