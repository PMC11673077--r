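# Structured conditions. Every error raised by the package carries the class
# "caliper_error" plus a specific subclass so callers (and the pipeline's
# per-case error isolation) can dispatch on failure kind.

caliper_abort <- function(subclass, message, ...) {
  stop(errorCondition(message, ..., class = c(subclass, "caliper_error")))
}

caliper_warn <- function(subclass, message, ...) {
  warning(warningCondition(message, ..., class = c(subclass, "caliper_warning")))
}

abort_missing_vessel <- function(class_code, label = vessel_class_name(class_code)) {
  caliper_abort("missing_vessel",
                sprintf("no pixels of vessel class %s (%s) in mask", class_code, label),
                class_code = class_code)
}

abort_degenerate_region <- function(message) {
  caliper_abort("degenerate_region", message)
}
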