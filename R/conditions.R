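#' @useDynLib scopeskill, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Classed condition helper. Every recoverable failure in the package is
# signalled as a condition of class "scopeskill_<code>" so callers can
# tryCatch on the specific failure mode.
stop_scopeskill <- function(code, message, ..., call. = FALSE) {
  data <- list(...)
  cond <- structure(
    class = c(paste0("scopeskill_", code), "scopeskill_error", "error", "condition"),
    list(message = message, call = if (call.) sys.call(-1) else NULL, data = data)
  )
  stop(cond)
}

# Returns TRUE if expr signals a scopeskill condition of the given code.
is_error_code <- function(expr, code) {
  tryCatch({ force(expr); FALSE },
           error = function(e) inherits(e, paste0("scopeskill_", code)))
}
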