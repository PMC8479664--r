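# Classed conditions so callers (and the CLI) can distinguish bad input data
# from malformed files and plain I/O trouble.

stop_validation <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c("poisdecon_validation_error", "poisdecon_error")))
}

stop_format <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c("poisdecon_format_error", "poisdecon_error")))
}

stop_io <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c("poisdecon_io_error", "poisdecon_error")))
}

stop_domain <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c("poisdecon_domain_error", "poisdecon_error")))
}
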