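# Classed conditions so callers (and the CLI) can dispatch on error kind.

hrfph_abort <- function(message, class) {
  stop(errorCondition(message, class = c(class, "hrfph_error")))
}

abort_validation <- function(message) hrfph_abort(message, "hrfph_validation_error")
abort_domain     <- function(message) hrfph_abort(message, "hrfph_domain_error")
abort_missing    <- function(message) hrfph_abort(message, "hrfph_missing_data_error")
abort_unit       <- function(message) hrfph_abort(message, "hrfph_unit_error")
abort_parse      <- function(message) hrfph_abort(message, "hrfph_parse_error")
abort_config     <- function(message) hrfph_abort(message, "hrfph_config_error")
abort_usage      <- function(message) hrfph_abort(message, "hrfph_usage_error")
abort_degenerate <- function(message) hrfph_abort(message, "hrfph_degenerate_table_error")
abort_consistency <- function(message) hrfph_abort(message, "hrfph_consistency_error")
abort_singular   <- function(message) hrfph_abort(message, "hrfph_singularity_error")
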