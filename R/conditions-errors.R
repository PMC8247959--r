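# Classed error conditions: "validation" for bad inputs/config, "data" for
# structurally unusable observations, "numerical" for failed optimizations.
# The command-line front end maps these to distinct exit codes.

stop_validation <- function(msg, call. = FALSE) {
  stop(errorCondition(msg,
                      class = c("phratefit_validation_error",
                                "phratefit_error", "error", "condition")))
}

stop_data <- function(msg) {
  stop(errorCondition(msg,
                      class = c("phratefit_data_error",
                                "phratefit_error", "error", "condition")))
}

stop_numerical <- function(msg) {
  stop(errorCondition(msg,
                      class = c("phratefit_numerical_error",
                                "phratefit_error", "error", "condition")))
}
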