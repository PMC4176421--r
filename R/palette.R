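# Palette generation and color interpolation.
#
# Interpolation is carried out in straight RGBA space (alpha like any other
# component) and quantized with round-half-up; this is the simplest scheme
# that keeps anchor colors exact and components monotone between anchors.

hsv_rgba <- function(h, s, v) {
  hex <- grDevices::hsv(h %% 1, s, v)
  parse_color(hex)
}

#' Generate a palette from a colorlist keyword
#'
#' * `rainbow` — `n` fully saturated, full-brightness hues evenly spaced
#'   at `i/n` around the hue circle, starting at red (0 degrees).
#' * `contrasting` — hues stepped by the golden angle (~137.5 degrees) so
#'   consecutive colors sit far apart on the wheel.
#' * `modulated` — rainbow hues with saturation and brightness alternating
#'   between 1.0 and 0.6.
#' * `random` — `n` uniform hues from a seeded generator; identical seeds
#'   give identical palettes.
#'
#' All palette colors are opaque.
#'
#' @param keyword One of `contrasting`, `modulated`, `rainbow`, `random`.
#' @param n Number of colors (at least 1).
#' @param seed Integer seed, used by `random` only.
#' @return A character vector of `n` `#RRGGBBAA` colors.
#' @examples
#' generate_palette("rainbow", 3)
#' @export
generate_palette <- function(keyword, n, seed = 0L) {
  keyword <- match.arg(keyword, c("contrasting", "modulated", "rainbow", "random"))
  if (!is.numeric(n) || length(n) != 1L || n < 1) {
    glyph_abort("a palette needs at least one color", "empty_palette")
  }
  n <- as.integer(n)
  i <- seq_len(n) - 1L
  colors <- switch(keyword,
    rainbow = lapply(i / n, hsv_rgba, s = 1, v = 1),
    contrasting = {
      golden <- 0.61803398874989485  # golden-ratio conjugate of the hue circle
      lapply((i * golden) %% 1, hsv_rgba, s = 1, v = 1)
    },
    modulated = {
      sv <- ifelse(i %% 2L == 0L, 1.0, 0.6)
      Map(function(h, x) hsv_rgba(h, x, x), i / n, sv)
    },
    random = {
      hues <- withr::with_seed(as.integer(seed), stats::runif(n))
      lapply(hues, hsv_rgba, s = 1, v = 1)
    }
  )
  vapply(colors, rgba_to_hex, character(1))
}

#' Pick the up, down, or zero color for a signed value
#'
#' @param value A single finite number.
#' @param colors An updown colorlist payload with `up`, `down`, and `zero`
#'   [rgba()] colors (see [parse_colorlist()]).
#' @return An [rgba()] color: `up` for positive, `down` for negative,
#'   `zero` for exactly zero.
#' @export
resolve_updown <- function(value, colors) {
  if (is.null(colors$up) || is.null(colors$down) || is.null(colors$zero)) {
    glyph_abort("updown colors need up, down, and zero entries", "value_type")
  }
  if (!is.numeric(value) || length(value) != 1L || !is.finite(value)) {
    glyph_abort("cannot pick an up/down color for a missing value", "missing_value")
  }
  if (value > 0) colors$up else if (value < 0) colors$down else colors$zero
}

#' Registered gradient-ramp keywords
#'
#' @return A character vector of the eight ramp keywords accepted by the
#'   heat-strip colorlist.
#' @export
gradient_keywords <- function() {
  c("yellowcyan", "yellowblue", "orangepurple", "bluegreenyellow",
    "purpleyellow", "greenpurple", "redyellow", "redgreen")
}

#' Build the color ramp for a gradient keyword
#'
#' Two-name keywords (e.g. `yellowblue`) give a two-anchor ramp: the first
#' color paints the positive extreme and the second the negative extreme.
#' The only three-name keyword, `bluegreenyellow`, gives a three-anchor
#' ramp with the middle color pinned at zero.
#'
#' @param keyword One of [gradient_keywords()].
#' @return A list with `anchors` (list of [rgba()], positive end first)
#'   and `keyword`.
#' @examples
#' ramp_for_keyword("yellowblue")
#' @export
ramp_for_keyword <- function(keyword) {
  keyword <- tolower(trimws(keyword))
  parts <- switch(keyword,
    yellowcyan      = c("yellow", "cyan"),
    yellowblue      = c("yellow", "blue"),
    orangepurple    = c("orange", "purple"),
    bluegreenyellow = c("blue", "green", "yellow"),
    purpleyellow    = c("purple", "yellow"),
    greenpurple     = c("green", "purple"),
    redyellow       = c("red", "yellow"),
    redgreen        = c("red", "green"),
    glyph_abort(
      sprintf(
        "unknown gradient keyword '%s' (valid: %s)",
        keyword, paste(gradient_keywords(), collapse = ", ")
      ),
      "unknown_keyword"
    )
  )
  list(anchors = lapply(parts, parse_color), keyword = keyword)
}

# An updown colorlist as a three-anchor ramp (up at +1, zero at 0, down at
# -1), so heat strips can treat both colorlist forms uniformly.
ramp_from_updown <- function(colors) {
  list(anchors = list(colors$up, colors$zero, colors$down), keyword = "updown")
}

lerp_rgba <- function(c0, c1, w) {
  # w = 0 -> c0, w = 1 -> c1
  comp <- round_half_up(as.numeric(c0) + (as.numeric(c1) - as.numeric(c0)) * w)
  rgba(comp[1L], comp[2L], comp[3L], comp[4L])
}

#' Interpolate a ramp at a normalized value
#'
#' For a two-anchor ramp the first anchor sits at `t = +1` and the second
#' at `t = -1`, with straight linear RGBA interpolation through their
#' midpoint at zero. A three-anchor ramp is piecewise linear with the
#' middle anchor exactly at zero.
#'
#' @param ramp A ramp from [ramp_for_keyword()].
#' @param t Normalized value in `[-1, 1]`.
#' @return An [rgba()] color.
#' @examples
#' interpolate_ramp(ramp_for_keyword("yellowblue"), 0)  # mid gray
#' @export
interpolate_ramp <- function(ramp, t) {
  if (!is.numeric(t) || length(t) != 1L || !is.finite(t) || abs(t) > 1) {
    glyph_abort("normalized value must lie in [-1, 1]", "range")
  }
  a <- ramp$anchors
  if (length(a) == 2L) {
    # a[[1]] at t = +1, a[[2]] at t = -1
    lerp_rgba(a[[1L]], a[[2L]], (1 - t) / 2)
  } else if (length(a) == 3L) {
    if (t >= 0) lerp_rgba(a[[2L]], a[[1L]], t) else lerp_rgba(a[[2L]], a[[3L]], -t)
  } else {
    glyph_abort("a ramp has two or three anchors", "value_type")
  }
}

#' Evaluate a gradient stop list at a position
#'
#' Piecewise-linear RGBA interpolation between the bracketing stops;
#' positions before the first or after the last stop clamp to that stop's
#' color.
#'
#' @param stops A sorted, non-empty stop list from [parse_stoplist()].
#' @param t Position along the gradient axis (proportion).
#' @return An [rgba()] color.
#' @export
stops_to_paint <- function(stops, t) {
  if (length(stops) == 0L) glyph_abort("stoplist is empty", "arity")
  pos <- vapply(stops, `[[`, numeric(1), "position")
  if (t <= pos[[1L]]) return(stops[[1L]]$color)
  n <- length(stops)
  if (t >= pos[[n]]) return(stops[[n]]$color)
  hi <- which(pos >= t)[[1L]]
  lo <- hi - 1L
  span <- pos[[hi]] - pos[[lo]]
  w <- if (span == 0) 0 else (t - pos[[lo]]) / span
  lerp_rgba(stops[[lo]]$color, stops[[hi]]$color, w)
}
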