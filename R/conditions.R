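# Classed conditions so callers (and the CLI) can map failures to exit codes:
#   sctf_parameter_error / sctf_config_error -> 2
#   sctf_format_error / sctf_validation_error / sctf_data_error -> 3
#   sctf_premise_error (no TF contrast) -> 4

sctf_abort <- function(class, message, call = sys.call(-1), data = list()) {
  cond <- structure(
    class = c(class, "sctf_error", "error", "condition"),
    c(list(message = message, call = call), data)
  )
  stop(cond)
}

sctf_parameter_error <- function(message, ...) sctf_abort("sctf_parameter_error", message, ...)
sctf_config_error    <- function(message, ...) sctf_abort("sctf_config_error", message, ...)
sctf_format_error    <- function(message, ...) sctf_abort("sctf_format_error", message, ...)
sctf_validation_error <- function(message, ...) sctf_abort("sctf_validation_error", message, ...)
sctf_data_error      <- function(message, ...) sctf_abort("sctf_data_error", message, ...)
sctf_io_error        <- function(message, ...) sctf_abort("sctf_io_error", message, ...)

# Premise failure: the design relies on transfection-induced TF heterogeneity;
# a flat (or absent) TF profile means the experiment cannot inform target calls.
sctf_premise_error   <- function(message, ...) sctf_abort("sctf_premise_error", message, ...)

#' Map a condition raised by the pipeline to a process exit code
#'
#' Used by the command-line wrapper: 2 for configuration/parameter problems,
#' 3 for malformed or inconsistent data, 4 for premise failure (no TF
#' expression contrast across cells), 1 for anything else.
#'
#' @param cond A condition object.
#' @return Integer exit code.
#' @export
sctf_exit_code <- function(cond) {
  cls <- class(cond)
  if (any(cls %in% c("sctf_parameter_error", "sctf_config_error"))) return(2L)
  if (any(cls %in% c("sctf_format_error", "sctf_validation_error",
                     "sctf_data_error", "sctf_io_error"))) return(3L)
  if ("sctf_premise_error" %in% cls) return(4L)
  1L
}
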