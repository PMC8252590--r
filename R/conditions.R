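# Classed conditions so callers (and the command-line wrapper) can map
# failure categories to exit codes without parsing messages.

stop_config <- function(...) {
  stop(errorCondition(paste0(...), class = c("siecv_config_error", "siecv_error")))
}

stop_validation <- function(...) {
  stop(errorCondition(paste0(...), class = c("siecv_validation_error", "siecv_error")))
}

stop_estimation <- function(...) {
  stop(errorCondition(paste0(...), class = c("siecv_estimation_error", "siecv_error")))
}
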