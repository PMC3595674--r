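# Classed conditions so callers (and the CLI) can map failures to exit codes:
# validation -> 2, solver -> 3, quality gate -> 4.

stop_validation <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("mreit_validation_error", "mreit_error", "error")))
}

stop_solver <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("mreit_solver_error", "mreit_error", "error")))
}

stop_quality <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("mreit_quality_error", "mreit_error", "error")))
}

warn_mreit <- function(msg, ...) {
  warning(warningCondition(sprintf(msg, ...),
                           class = c("mreit_warning", "warning", "condition")))
}
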