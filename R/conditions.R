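# Structured conditions so callers (and the command-line wrapper) can map
# failure modes to exit codes: configuration/validation problems vs.
# estimation problems.

stop_config <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c("panelcausal_config_error", "panelcausal_error")))
}

stop_validation <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c("panelcausal_validation_error", "panelcausal_error")))
}

stop_estimation <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c("panelcausal_estimation_error", "panelcausal_error")))
}

# Logging goes through message() so it lands on stderr and can be silenced
# with suppressMessages(); results never mix with log text.
log_msg <- function(fmt, ...) {
  message(sprintf(fmt, ...))
}
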