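# Typed conditions: callers (and the state controller) distinguish
# planning, topology, gating, ordering, precondition and config failures.
flapsim_error <- function(class, msg, ...) {
  stop(structure(class = c(class, "flapsim_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1), ...)))
}

plan_error <- function(msg, ...) flapsim_error("flapsim_planning_error", msg, ...)
topology_error <- function(msg, ...) flapsim_error("flapsim_topology_error", msg, ...)
gating_error <- function(msg, ...) flapsim_error("flapsim_gating_error", msg, ...)
ordering_error <- function(msg, ...) flapsim_error("flapsim_ordering_error", msg, ...)
precondition_error <- function(msg, ...) flapsim_error("flapsim_precondition_error", msg, ...)
state_error <- function(msg, ...) flapsim_error("flapsim_state_error", msg, ...)
config_error <- function(msg, ...) flapsim_error("flapsim_config_error", msg, ...)
argument_error <- function(msg, ...) flapsim_error("flapsim_argument_error", msg, ...)
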