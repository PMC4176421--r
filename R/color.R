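# RGBA colors. Internally a color is an integer vector of length four
# (red, green, blue, alpha), each component in [0, 255], with class "rgba".
# Downstream geometry and SVG code carries colors as "#RRGGBBAA" hex text;
# the rgba vector form is used wherever components are interpolated.

#' Construct an RGBA color
#'
#' @param r,g,b,a Integer components in `[0, 255]`. `a` defaults to 255
#'   (opaque).
#' @return An object of class `rgba`: an integer vector `c(r, g, b, a)`.
#' @examples
#' rgba(255, 0, 0)      # opaque red
#' rgba(0, 0, 0, 128)   # half-transparent black
#' @export
rgba <- function(r, g, b, a = 255L) {
  comp <- c(r, g, b, a)
  if (length(comp) != 4L || anyNA(comp) || !is.numeric(comp)) {
    glyph_abort("an RGBA color needs four numeric components", "color_parse")
  }
  if (any(comp < 0 | comp > 255)) {
    glyph_abort(
      sprintf(
        "RGBA components must lie in [0, 255], got (%s)",
        paste(comp, collapse = ", ")
      ),
      "range"
    )
  }
  if (any(comp != round(comp))) {
    glyph_abort("RGBA components must be integers", "color_parse")
  }
  structure(as.integer(round(comp)), class = "rgba")
}

#' @export
print.rgba <- function(x, ...) {
  cat("<rgba ", rgba_to_hex(x), ">\n", sep = "")
  invisible(x)
}

#' Format an RGBA color as hex text
#'
#' @param color An [rgba()] color.
#' @param keep_alpha Emit `#RRGGBBAA` (default) or drop an opaque alpha
#'   channel and emit `#RRGGBB`.
#' @return A character scalar.
#' @export
rgba_to_hex <- function(color, keep_alpha = TRUE) {
  stopifnot(inherits(color, "rgba"))
  if (keep_alpha || color[[4L]] != 255L) {
    sprintf("#%02X%02X%02X%02X", color[[1L]], color[[2L]], color[[3L]], color[[4L]])
  } else {
    sprintf("#%02X%02X%02X", color[[1L]], color[[2L]], color[[3L]])
  }
}

#' Parse a color token
#'
#' Accepts a named color (the standard X11/CSS names known to R, e.g.
#' `red`, `steelblue`), `#RRGGBB`, or `#RRGGBBAA` hex (case-insensitive).
#' Named colors and 6-digit hex resolve with an opaque alpha of 255.
#'
#' @param token A character scalar.
#' @return An [rgba()] color.
#' @examples
#' parse_color("#FF0000")    # red
#' parse_color("#00000080")  # half-transparent black
#' @export
parse_color <- function(token) {
  if (!is.character(token) || length(token) != 1L || is.na(token)) {
    glyph_abort("color token must be a single string", "color_parse")
  }
  token <- trimws(token)
  if (grepl("^#", token)) {
    if (grepl("^#[0-9a-fA-F]{8}$", token)) {
      comp <- strtoi(substring(token, c(2L, 4L, 6L, 8L), c(3L, 5L, 7L, 9L)), 16L)
      return(rgba(comp[1L], comp[2L], comp[3L], comp[4L]))
    }
    if (grepl("^#[0-9a-fA-F]{6}$", token)) {
      comp <- strtoi(substring(token, c(2L, 4L, 6L), c(3L, 5L, 7L)), 16L)
      return(rgba(comp[1L], comp[2L], comp[3L]))
    }
    glyph_abort(
      sprintf("malformed hex color '%s' (expected #RRGGBB or #RRGGBBAA)", token),
      "color_parse"
    )
  }
  name <- tolower(token)
  if (!name %in% grDevices::colors()) {
    glyph_abort(sprintf("unknown color name '%s'", token), "color_parse")
  }
  comp <- grDevices::col2rgb(name, alpha = TRUE)[, 1L]
  rgba(comp[["red"]], comp[["green"]], comp[["blue"]], comp[["alpha"]])
}

# Hex text -> rgba, for internal use on already-validated strings.
hex_to_rgba <- function(hex) parse_color(hex)

# Round half-up, the convention used whenever interpolated components are
# quantized back to [0, 255] integers.
round_half_up <- function(x) floor(x + 0.5)
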