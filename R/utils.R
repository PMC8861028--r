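`%||%` <- function(x, y) if (is.null(x)) y else x

#' Signal a classed package error
#'
#' All user-facing failures carry a subclass of `tarsalct_error` so callers
#' (and the test suite) can distinguish, e.g., geometry errors from metadata
#' errors without matching message text.
#'
#' @param message Error message.
#' @param class Error subclass, e.g. `"geometry"`.
#' @noRd
stop_tarsalct <- function(message, class, call = sys.call(-1)) {
  stop(errorCondition(
    message,
    class = c(paste0("tarsalct_", class, "_error"), "tarsalct_error", "error", "condition"),
    call = call
  ))
}

#' djb2 string hash, returned as hex; used to fingerprint run configurations
#' in pipeline manifests (no cryptographic intent).
#' @noRd
config_hash <- function(x) {
  s <- utf8ToInt(paste(deparse(x), collapse = "\n"))
  h <- 5381
  for (ch in s) h <- (h * 33 + ch) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' Format a vector for error messages
#' @noRd
fmt_rows <- function(idx, max_show = 10) {
  shown <- utils::head(idx, max_show)
  extra <- if (length(idx) > max_show) sprintf(" (and %d more)", length(idx) - max_show) else ""
  paste0(paste(shown, collapse = ", "), extra)
}
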