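# Classed conditions so the CLI can map failures onto stable exit codes.

stop_format <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("coursefit_format_error", "coursefit_error")))
}

stop_schema <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("coursefit_schema_error", "coursefit_error")))
}

stop_generation <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("coursefit_generation_error", "coursefit_error")))
}

stop_input <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("coursefit_input_error", "coursefit_error")))
}
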