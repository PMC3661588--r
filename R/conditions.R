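# Classed conditions so callers (and the CLI) can map failures to exit codes:
# validation errors -> 2, convergence failures -> 3.

stop_validation <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("bmusim_validation_error", "bmusim_error")))
}

stop_domain <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("bmusim_domain_error", "bmusim_error")))
}

stop_convergence <- function(msg, ..., last_time = NA_real_, last_state = NULL) {
  cond <- errorCondition(sprintf(msg, ...),
                         class = c("bmusim_convergence_error", "bmusim_error"))
  cond$last_time <- last_time
  cond$last_state <- last_state
  stop(cond)
}
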