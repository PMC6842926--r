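# Classed conditions so callers (and tests) can distinguish bad user input
# from internal logic errors.

stop_input <- function(msg, call. = FALSE) {
  stop(errorCondition(msg, class = c("imgsbml_input_error", "imgsbml_error")))
}

stop_logic <- function(msg) {
  stop(errorCondition(msg, class = c("imgsbml_logic_error", "imgsbml_error")))
}

stop_io <- function(msg) {
  stop(errorCondition(msg, class = c("imgsbml_io_error", "imgsbml_error")))
}
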