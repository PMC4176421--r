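# Typed condition helpers. Every user-facing failure is signalled as a
# condition inheriting from "glyph_error" plus one specific subclass, so
# callers (and the CLI) can branch on the kind of failure without string
# matching.

glyph_abort <- function(message, kind, ...) {
  rlang::abort(
    message,
    class = c(paste0("glyph_error_", kind), "glyph_error"),
    ...
  )
}

#' Test whether a condition is a typed glyph error
#'
#' @param cnd A condition object.
#' @param kind Optional specific kind (e.g. `"unknown_type"`); when `NULL`,
#'   any glyph error matches.
#' @return `TRUE` or `FALSE`.
#' @export
is_glyph_error <- function(cnd, kind = NULL) {
  if (!inherits(cnd, "glyph_error")) return(FALSE)
  is.null(kind) || inherits(cnd, paste0("glyph_error_", kind))
}

glyph_warn <- function(message, kind = "warning") {
  rlang::warn(message, class = c(paste0("glyph_warning_", kind), "glyph_warning"))
}
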