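# Classed error conditions so callers and tests can discriminate failure
# modes without string matching.

mv_abort <- function(msg, class, call. = FALSE, ...) {
  stop(errorCondition(msg, ..., class = c(class, "microvar_error")))
}

mv_format_error <- function(msg, ...) mv_abort(msg, "mv_format_error", ...)
mv_validation_error <- function(msg, ...) mv_abort(msg, "mv_validation_error", ...)
mv_reference_error <- function(msg, ...) mv_abort(msg, "mv_reference_error", ...)
mv_domain_error <- function(msg, ...) mv_abort(msg, "mv_domain_error", ...)
mv_insufficient_data <- function(msg, ...) mv_abort(msg, "mv_insufficient_data", ...)
mv_parse_error <- function(msg, ...) mv_abort(msg, "mv_parse_error", ...)
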