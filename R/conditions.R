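# Structured conditions. Every error raised by the package carries class
# "cbp_error" plus a subclass naming the failure mode, so callers (and the
# CLI) can branch on the condition class instead of matching message text.

cbp_abort <- function(message, class, ...) {
  stop(errorCondition(message, ..., class = c(class, "cbp_error")))
}

cbp_validation_error <- function(message, ...) {
  cbp_abort(message, "cbp_validation_error", ...)
}

cbp_conflict_error <- function(message, ...) {
  cbp_abort(message, "cbp_conflict_error", ...)
}

cbp_not_found_error <- function(message, ...) {
  cbp_abort(message, "cbp_not_found_error", ...)
}

cbp_parse_error <- function(message, file = NULL, line = NULL, ...) {
  cbp_abort(message, "cbp_parse_error", file = file, line = line, ...)
}

cbp_io_error <- function(message, ...) {
  cbp_abort(message, "cbp_io_error", ...)
}

cbp_referential_error <- function(message, ...) {
  cbp_abort(message, "cbp_referential_error", ...)
}

# Workflow-ordering violations (e.g. adding a sample before its patient).
cbp_precondition_error <- function(message, ...) {
  cbp_abort(message, "cbp_precondition_error", ...)
}

cbp_unsupported_error <- function(message, ...) {
  cbp_abort(message, "cbp_unsupported_error", ...)
}

# Missing required columns in a MAF or clinical file.
cbp_format_error <- function(message, missing_columns = NULL, ...) {
  cbp_abort(message, "cbp_format_error", missing_columns = missing_columns, ...)
}

cbp_datatype_error <- function(message, ...) {
  cbp_abort(message, "cbp_datatype_error", ...)
}

cbp_warn <- function(message, class = "cbp_warning") {
  warning(warningCondition(message, class = c(class, "cbp_warning")))
}
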