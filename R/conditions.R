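#' @keywords internal
#' @noRd
egg_abort <- function(message, class, call = sys.call(-1)) {
  stop(structure(
    class = c(class, "egg_error", "error", "condition"),
    list(message = message, call = call)
  ))
}

abort_config <- function(message) egg_abort(message, "egg_config_error")
abort_domain <- function(message) egg_abort(message, "egg_domain_error")
abort_length <- function(message) egg_abort(message, "egg_length_error")
abort_state <- function(message) egg_abort(message, "egg_state_error")
abort_data <- function(message) egg_abort(message, "egg_data_error")
abort_undefined <- function(message) egg_abort(message, "egg_undefined_result_error")
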