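#' Raise a coded bedcert error
#'
#' All contract violations in the package raise classed conditions carrying a
#' symbolic `code` (e.g. `PROHIBITED_VARIANT`, `CONFIG_ERROR`) so callers can
#' branch on the code rather than match message text.
#'
#' @param code symbolic error code, upper snake case.
#' @param message human-readable message; should quote the offending token.
#' @param ... additional fields stored on the condition.
#' @return does not return; signals an error of classes
#'   `bedcert_<code>` (lower case) and `bedcert_error`.
#' @keywords internal
#' @noRd
bedcert_stop <- function(code, message, ...) {
  cond <- errorCondition(
    message,
    code = code,
    ...,
    class = c(paste0("bedcert_", tolower(code)), "bedcert_error")
  )
  stop(cond)
}

#' Extract the symbolic code from a bedcert error
#'
#' @param expr expression expected to signal a `bedcert_error`.
#' @return the condition's `code` string, or `NA_character_` if `expr`
#'   completes without error.
#' @examples
#' error_code(detect_variant(10))
#' @export
error_code <- function(expr) {
  tryCatch({
    force(expr)
    NA_character_
  }, bedcert_error = function(e) e$code)
}
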