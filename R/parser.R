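# Parser for the glyph instruction mini-language.
#
# An instruction is `prefix: name=value name="quoted value" ...`.
# Two prefixes define gradient paints (lingrad, radgrad) and six define
# charts (barchart, circoschart, heatstripchart, linechart, piechart,
# stripechart). Values may be bare tokens (running to the next whitespace)
# or double-quoted (may then contain spaces and '='); single quotes are
# not special.

#' Registered glyph prefixes
#'
#' @param category `"all"`, `"chart"`, or `"gradient"`.
#' @return A character vector of instruction prefixes.
#' @examples
#' glyph_prefixes("chart")
#' @export
glyph_prefixes <- function(category = c("all", "chart", "gradient")) {
  category <- match.arg(category)
  charts <- c(
    "barchart", "circoschart", "heatstripchart",
    "linechart", "piechart", "stripechart"
  )
  gradients <- c("lingrad", "radgrad")
  switch(category,
    all = c(gradients, charts),
    chart = charts,
    gradient = gradients
  )
}

#' Tokenize an instruction string
#'
#' Splits `prefix: name=value ...` into its prefix and an ordered list of
#' raw (still textual) argument values. The prefix is lowercased before
#' validation; surrounding double quotes are stripped from values.
#'
#' @param text A single instruction string.
#' @return A list with elements `prefix` (character) and `args` (named list
#'   of character values, in input order).
#' @examples
#' tokenize_instruction('piechart: values="1,1,2" colorlist="rainbow"')
#' @export
tokenize_instruction <- function(text) {
  if (!is.character(text) || length(text) != 1L || is.na(text) || !nzchar(trimws(text))) {
    glyph_abort("instruction text must be a non-empty string", "syntax")
  }
  colon <- regexpr(":", text, fixed = TRUE)
  if (colon < 0L) {
    glyph_abort("instruction must contain ':' separating prefix from arguments", "syntax")
  }
  prefix <- tolower(trimws(substr(text, 1L, colon - 1L)))
  if (!prefix %in% glyph_prefixes()) {
    glyph_abort(
      sprintf(
        "unknown glyph type '%s' (expected one of %s)",
        prefix, paste(glyph_prefixes(), collapse = ", ")
      ),
      "unknown_type", prefix = prefix
    )
  }
  args <- scan_arglist(substr(text, colon + 1L, nchar(text)), offset = colon)
  if (anyDuplicated(names(args))) {
    dup <- names(args)[duplicated(names(args))][[1L]]
    glyph_abort(
      sprintf("argument '%s' given more than once", dup),
      "duplicate_arg", arg = dup
    )
  }
  list(prefix = prefix, args = args)
}

# Character scanner for the arglist. `offset` is the number of characters
# consumed before the arglist starts, so error offsets refer to the whole
# instruction string.
scan_arglist <- function(arglist, offset = 0L) {
  chars <- strsplit(arglist, "", fixed = TRUE)[[1L]]
  n <- length(chars)
  i <- 1L
  args <- list()
  skip_ws <- function(i) {
    while (i <= n && grepl("^\\s$", chars[[i]])) i <- i + 1L
    i
  }
  while ((i <- skip_ws(i)) <= n) {
    start <- i
    while (i <= n && !grepl("^[\\s=]$", chars[[i]], perl = TRUE)) i <- i + 1L
    name <- paste(chars[start:(i - 1L)], collapse = "")
    if (i > n || chars[[i]] != "=" || !nzchar(name)) {
      glyph_abort(
        sprintf("expected name=value at character %d", offset + start),
        "syntax", offset = offset + start
      )
    }
    i <- i + 1L  # consume '='
    if (i <= n && chars[[i]] == "\"") {
      qstart <- i
      i <- i + 1L
      vstart <- i
      while (i <= n && chars[[i]] != "\"") i <- i + 1L
      if (i > n) {
        glyph_abort(
          sprintf("unterminated quote starting at character %d", offset + qstart),
          "syntax", offset = offset + qstart
        )
      }
      value <- if (i > vstart) paste(chars[vstart:(i - 1L)], collapse = "") else ""
      i <- i + 1L  # closing quote
    } else {
      vstart <- i
      while (i <= n && !grepl("^\\s$", chars[[i]])) i <- i + 1L
      value <- if (i > vstart) paste(chars[vstart:(i - 1L)], collapse = "") else ""
    }
    args <- c(args, stats::setNames(list(value), name))
  }
  args
}

# ---- scalar token parsers ---------------------------------------------------

# Numeric literals are integer or decimal; scientific notation is rejected.
num_regex <- "^[+-]?([0-9]+(\\.[0-9]*)?|\\.[0-9]+)$"

parse_number <- function(token, arg) {
  token <- trimws(token)
  if (!grepl(num_regex, token)) {
    glyph_abort(
      sprintf("argument '%s': '%s' is not a plain numeric literal", arg, token),
      "value_type", arg = arg, token = token
    )
  }
  as.numeric(token)
}

parse_number_list <- function(token, arg) {
  parts <- strsplit(token, ",", fixed = TRUE)[[1L]]
  if (length(parts) == 0L) {
    glyph_abort(sprintf("argument '%s' is empty", arg), "value_type", arg = arg)
  }
  vapply(parts, parse_number, numeric(1), arg = arg, USE.NAMES = FALSE)
}

parse_proportion <- function(token, arg) {
  v <- parse_number(token, arg)
  if (v < 0 || v > 1) {
    glyph_abort(
      sprintf("argument '%s' must be a proportion in [0, 1], got %s", arg, token),
      "range", arg = arg
    )
  }
  v
}

parse_point <- function(token, arg) {
  v <- parse_number_list(token, arg)
  if (length(v) != 2L) {
    glyph_abort(sprintf("argument '%s' must be 'x,y'", arg), "value_type", arg = arg)
  }
  if (any(v < 0 | v > 1)) {
    glyph_abort(
      sprintf("argument '%s': coordinates must be proportions in [0, 1]", arg),
      "range", arg = arg
    )
  }
  v
}

parse_bool <- function(token, arg) {
  t <- tolower(trimws(token))
  if (!t %in% c("true", "false")) {
    glyph_abort(
      sprintf("argument '%s' must be true or false, got '%s'", arg, token),
      "value_type", arg = arg
    )
  }
  t == "true"
}

parse_text_list <- function(token) {
  trimws(strsplit(token, ",", fixed = TRUE)[[1L]])
}

parse_range_arg <- function(token, arg = "range") {
  v <- parse_number_list(token, arg)
  if (length(v) != 2L) {
    glyph_abort("range must be 'min,max'", "value_type", arg = arg)
  }
  if (v[[1L]] >= v[[2L]]) {
    glyph_abort(
      sprintf("range min (%s) must be less than max (%s)", v[[1L]], v[[2L]]),
      "range", arg = arg
    )
  }
  v
}

parse_ybase <- function(token, arg = "ybase") {
  t <- tolower(trimws(token))
  if (t %in% c("top", "middle", "bottom")) return(t)
  parse_proportion(t, arg)
}

#' Parse a gradient stop list
#'
#' A stoplist is one or more `r,g,b,a,position` groups separated by `|`.
#' Color components must lie in `[0, 255]` and positions (proportions along
#' the gradient axis) in `[0, 1]`. Stops are returned sorted ascending by
#' position.
#'
#' @param text The stoplist text.
#' @return A list of stops, each `list(color = rgba, position = numeric)`.
#' @examples
#' parse_stoplist("255,0,0,255,0|0,0,255,255,1")
#' @export
parse_stoplist <- function(text) {
  groups <- strsplit(text, "|", fixed = TRUE)[[1L]]
  if (length(groups) == 0L || !nzchar(trimws(text))) {
    glyph_abort("stoplist must contain at least one stop", "arity")
  }
  stops <- lapply(groups, function(g) {
    parts <- trimws(strsplit(g, ",", fixed = TRUE)[[1L]])
    if (length(parts) != 5L) {
      glyph_abort(
        sprintf("stop '%s' must have 5 fields (r,g,b,a,position)", g),
        "arity"
      )
    }
    comp <- vapply(parts, parse_number, numeric(1), arg = "stoplist", USE.NAMES = FALSE)
    if (any(comp[1:4] < 0 | comp[1:4] > 255)) {
      glyph_abort(
        sprintf("stop '%s': color components must lie in [0, 255]", g),
        "range"
      )
    }
    if (comp[[5L]] < 0 || comp[[5L]] > 1) {
      glyph_abort(
        sprintf("stop '%s': position must lie in [0, 1]", g),
        "range"
      )
    }
    list(
      color = rgba(comp[[1L]], comp[[2L]], comp[[3L]], comp[[4L]]),
      position = comp[[5L]]
    )
  })
  positions <- vapply(stops, `[[`, numeric(1), "position")
  stops[order(positions)]
}

#' Parse a colorlist argument
#'
#' The colorlist takes one of four forms, tried in this order:
#' a palette keyword (`contrasting`, `modulated`, `rainbow`, `random`);
#' a gradient-ramp keyword (see [ramp_for_keyword()]); an up/down
#' specification `up:color,down:color[,zero:color]` assigning colors to
#' positive, negative, and zero values (the zero color defaults to opaque
#' black); or an explicit comma-separated list of colors.
#'
#' @param text The colorlist text.
#' @return A list with `mode` (`"keyword"`, `"gradient_keyword"`,
#'   `"updown"`, or `"explicit"`) and the matching payload.
#' @examples
#' parse_colorlist("rainbow")
#' parse_colorlist("up:red,down:blue")
#' parse_colorlist("#FF0000,#00FF00")
#' @export
parse_colorlist <- function(text) {
  t <- trimws(text)
  if (!nzchar(t)) glyph_abort("colorlist is empty", "value_type", arg = "colorlist")
  lower <- tolower(t)
  if (lower %in% c("contrasting", "modulated", "rainbow", "random")) {
    return(list(mode = "keyword", keyword = lower))
  }
  if (lower %in% gradient_keywords()) {
    return(list(mode = "gradient_keyword", keyword = lower))
  }
  if (grepl("(^|,)\\s*(up|down|zero)\\s*:", lower)) {
    parts <- trimws(strsplit(t, ",", fixed = TRUE)[[1L]])
    ud <- list()
    for (p in parts) {
      m <- regmatches(p, regexec("^(up|down|zero)\\s*:\\s*(.+)$", tolower(p)))[[1L]]
      if (length(m) == 0L) {
        glyph_abort(
          sprintf("updown colorlist mixes forms near '%s'", p),
          "syntax", arg = "colorlist"
        )
      }
      key <- m[[2L]]
      if (!is.null(ud[[key]])) {
        glyph_abort(sprintf("updown colorlist repeats '%s'", key), "duplicate_arg")
      }
      # take the value from the original (case-preserved) text
      value <- sub("^[^:]*:\\s*", "", p)
      ud[[key]] <- parse_color(value)
    }
    if (is.null(ud$up) || is.null(ud$down)) {
      glyph_abort("updown colorlist needs both up: and down: colors", "value_type",
        arg = "colorlist")
    }
    if (is.null(ud$zero)) ud$zero <- rgba(0, 0, 0, 255)
    return(list(mode = "updown", up = ud$up, down = ud$down, zero = ud$zero))
  }
  colors <- lapply(parse_text_list(t), parse_color)
  list(mode = "explicit", colors = colors)
}

# ---- per-prefix schema ------------------------------------------------------

common_arg_names <- c(
  "attributelist", "colorlist", "labels", "labelcolor", "labelfont",
  "labelsize", "labelstyle", "range", "scale", "showlabels", "values", "ybase"
)

chart_arg_names <- list(
  barchart       = "separation",
  circoschart    = c("arcstart", "arcwidth", "firstarc", "firstarcwidth",
                     "labelcircles", "sortslices"),
  heatstripchart = "separation",
  linechart      = "linewidth",
  piechart       = c("arcstart", "sortslices"),
  stripechart    = character(),
  lingrad        = c("start", "end", "stoplist"),
  radgrad        = c("center", "radius", "stoplist")
)

# Common arguments a prefix does NOT accept. Pie and circos reject
# range/scale/ybase; stripe accepts nothing but colorlist; gradients take
# no common arguments at all.
allowed_args <- function(prefix) {
  common <- switch(prefix,
    piechart    = setdiff(common_arg_names, c("range", "scale", "ybase")),
    circoschart = setdiff(common_arg_names, c("range", "scale", "ybase")),
    stripechart = "colorlist",
    lingrad     = character(),
    radgrad     = character(),
    common_arg_names
  )
  c(common, chart_arg_names[[prefix]])
}

all_arg_names <- function() {
  unique(c(common_arg_names, unlist(chart_arg_names, use.names = FALSE)))
}

chart_defaults <- list(
  barchart       = list(separation = 0),
  circoschart    = list(arcstart = 0, arcwidth = 0.3, firstarc = 0.2,
                        firstarcwidth = 0.3, labelcircles = FALSE,
                        sortslices = FALSE),
  heatstripchart = list(separation = 0),
  linechart      = list(linewidth = 1),
  piechart       = list(arcstart = 0, sortslices = FALSE),
  stripechart    = list(),
  lingrad        = list(start = c(0, 0), end = c(1, 0)),
  radgrad        = list(center = c(0.5, 0.5), radius = 0.5)
)

common_defaults <- function() {
  list(
    attributelist = NULL, values = NULL, labels = NULL,
    labelcolor = NULL, labelfont = NULL, labelsize = NULL,
    labelstyle = "plain", range = NULL, scale = 1,
    showlabels = TRUE, ybase = "bottom", colorlist = NULL
  )
}

parse_arg_value <- function(arg, token) {
  switch(arg,
    attributelist = parse_text_list(token),
    values        = parse_number_list(token, arg),
    labels        = parse_text_list(token),
    labelcolor    = parse_color(token),
    labelfont     = trimws(token),
    labelsize     = {
      v <- parse_number(token, arg)
      if (v <= 0) glyph_abort("labelsize must be positive", "range", arg = arg)
      v
    },
    labelstyle    = {
      t <- tolower(trimws(token))
      if (!t %in% c("italics", "bold", "bolditalic", "plain")) {
        glyph_abort(
          sprintf("labelstyle must be italics, bold, bolditalic, or plain, got '%s'", token),
          "value_type", arg = arg
        )
      }
      t
    },
    range         = parse_range_arg(token),
    scale         = {
      v <- parse_number(token, arg)
      if (v <= 0) glyph_abort("scale must be positive", "range", arg = arg)
      v
    },
    showlabels    = parse_bool(token, arg),
    ybase         = parse_ybase(token),
    colorlist     = parse_colorlist(token),
    separation    = {
      v <- parse_number(token, arg)
      if (v < 0) glyph_abort("separation must be nonnegative", "range", arg = arg)
      v
    },
    arcstart      = parse_number(token, arg),
    arcwidth      = parse_proportion(token, arg),
    firstarc      = parse_proportion(token, arg),
    firstarcwidth = parse_proportion(token, arg),
    labelcircles  = parse_bool(token, arg),
    sortslices    = parse_bool(token, arg),
    linewidth     = {
      v <- parse_number(token, arg)
      if (v <= 0) glyph_abort("linewidth must be positive", "range", arg = arg)
      v
    },
    start         = parse_point(token, arg),
    end           = parse_point(token, arg),
    center        = parse_point(token, arg),
    radius        = parse_proportion(token, arg),
    stoplist      = parse_stoplist(token),
    glyph_abort(sprintf("unknown argument '%s'", arg), "unknown_arg", arg = arg)
  )
}

#' Parse an instruction string into a validated glyph spec
#'
#' Tokenizes the instruction, parses every argument by its declared type,
#' rejects arguments the prefix does not accept, fills defaults, and
#' returns a `glyph_spec` object. Chart prefixes that draw values
#' (bar, circos, heat strip, line, pie) require exactly one of `values`
#' or `attributelist`; when `labels` is absent it defaults to the
#' `attributelist` column names.
#'
#' @param text A single instruction string.
#' @return A `glyph_spec`: a list with `prefix`, `common` (shared
#'   arguments), and `chart` (per-prefix arguments).
#' @examples
#' parse_instruction('piechart: values="1,1,2" colorlist="rainbow"')
#' parse_instruction(paste0(
#'   'heatstripchart: attributelist="gal1RGexp,gal4RGexp,gal80Rexp" ',
#'   'colorlist="yellowblue" range="-3.0,3.0"'
#' ))
#' @export
parse_instruction <- function(text) {
  raw <- tokenize_instruction(text)
  prefix <- raw$prefix
  ok <- allowed_args(prefix)
  for (nm in names(raw$args)) {
    if (!nm %in% ok) {
      if (nm %in% all_arg_names()) {
        glyph_abort(
          sprintf("argument '%s' is not accepted by %s", nm, prefix),
          "forbidden_arg", prefix = prefix, arg = nm
        )
      }
      glyph_abort(
        sprintf("unknown argument '%s' for %s", nm, prefix),
        "unknown_arg", prefix = prefix, arg = nm
      )
    }
  }
  arg_names <- names(raw$args) %||% character()
  parsed <- lapply(rlang::set_names(arg_names), function(nm) {
    parse_arg_value(nm, raw$args[[nm]])
  })

  common <- common_defaults()
  for (nm in intersect(names(parsed), common_arg_names)) {
    common[[nm]] <- parsed[[nm]]
  }
  chart <- chart_defaults[[prefix]]
  for (nm in intersect(names(parsed), chart_arg_names[[prefix]])) {
    chart[[nm]] <- parsed[[nm]]
  }

  value_driven <- c("barchart", "circoschart", "heatstripchart", "linechart", "piechart")
  if (prefix %in% value_driven) {
    if (!is.null(common$values) && !is.null(common$attributelist)) {
      glyph_abort(
        sprintf("%s takes either values or attributelist, not both", prefix),
        "forbidden_arg", prefix = prefix, arg = "values"
      )
    }
    if (is.null(common$values) && is.null(common$attributelist)) {
      glyph_abort(
        sprintf("%s requires one of values or attributelist", prefix),
        "missing_required", prefix = prefix
      )
    }
  }
  if (prefix %in% c("lingrad", "radgrad") && is.null(parsed$stoplist)) {
    glyph_abort(
      sprintf("%s requires a stoplist", prefix),
      "missing_required", prefix = prefix, arg = "stoplist"
    )
  }
  if (prefix == "stripechart") {
    if (is.null(common$colorlist)) {
      glyph_abort("stripechart requires a colorlist", "missing_required",
        prefix = prefix, arg = "colorlist")
    }
    if (common$colorlist$mode != "explicit") {
      glyph_abort(
        "stripechart colorlist must be an explicit list of colors (it has no values to count)",
        "value_type", prefix = prefix, arg = "colorlist"
      )
    }
  }
  if (prefix == "heatstripchart" && !is.null(common$colorlist) &&
      !common$colorlist$mode %in% c("gradient_keyword", "updown")) {
    glyph_abort(
      "heatstripchart colorlist must be a gradient keyword or updown colors",
      "value_type", prefix = prefix, arg = "colorlist"
    )
  }
  if (is.null(common$labels) && !is.null(common$attributelist)) {
    common$labels <- common$attributelist
  }

  structure(list(prefix = prefix, common = common, chart = chart),
            class = "glyph_spec")
}

#' @export
print.glyph_spec <- function(x, ...) {
  cat("<glyph_spec> ", serialize_instruction(x), "\n", sep = "")
  invisible(x)
}

# ---- canonical serialization ------------------------------------------------

fmt_num <- function(x) {
  vapply(x, function(v) {
    if (is.finite(v) && v == round(v) && abs(v) < 1e15) {
      sprintf("%.1f", v)
    } else {
      format(v, digits = 15, scientific = FALSE, trim = TRUE)
    }
  }, character(1))
}

serialize_colorlist <- function(cl) {
  switch(cl$mode,
    keyword = cl$keyword,
    gradient_keyword = cl$keyword,
    updown = paste0(
      "up:", rgba_to_hex(cl$up), ",down:", rgba_to_hex(cl$down),
      ",zero:", rgba_to_hex(cl$zero)
    ),
    explicit = paste(vapply(cl$colors, rgba_to_hex, character(1)), collapse = ",")
  )
}

serialize_stoplist <- function(stops) {
  paste(vapply(stops, function(s) {
    paste(c(s$color[1:4], fmt_num(s$position)), collapse = ",")
  }, character(1)), collapse = "|")
}

serialize_arg_value <- function(arg, value) {
  switch(arg,
    attributelist = ,
    labels        = paste(value, collapse = ","),
    values        = paste(fmt_num(value), collapse = ","),
    labelcolor    = rgba_to_hex(value),
    labelfont     = ,
    labelstyle    = value,
    range         = paste(fmt_num(value), collapse = ","),
    scale         = ,
    labelsize     = ,
    separation    = ,
    arcstart      = ,
    arcwidth      = ,
    firstarc      = ,
    firstarcwidth = ,
    linewidth     = ,
    radius        = fmt_num(value),
    showlabels    = ,
    labelcircles  = ,
    sortslices    = if (isTRUE(value)) "true" else "false",
    ybase         = if (is.character(value)) value else fmt_num(value),
    colorlist     = serialize_colorlist(value),
    start         = ,
    end           = ,
    center        = paste(fmt_num(value), collapse = ","),
    stoplist      = serialize_stoplist(value)
  )
}

# Canonical argument order: common arguments alphabetically-stable in the
# documented order, then chart arguments in schema order.
canonical_arg_order <- function(prefix) {
  common <- switch(prefix,
    lingrad = character(), radgrad = character(),
    common_arg_names
  )
  c(common, chart_arg_names[[prefix]])
}

#' Serialize a glyph spec to its canonical instruction string
#'
#' Emits the prefix, a colon, and every argument whose value differs from
#' its default, in a fixed documented order with all values double-quoted.
#' `parse_instruction()` of the result reproduces the spec exactly
#' (canonical round trip), and serializing again is a fixed point.
#'
#' @param spec A `glyph_spec` from [parse_instruction()].
#' @return A character scalar instruction string.
#' @examples
#' serialize_instruction(parse_instruction("piechart: values=1,1,2"))
#' @export
serialize_instruction <- function(spec) {
  stopifnot(inherits(spec, "glyph_spec"))
  defaults <- c(common_defaults(), chart_defaults[[spec$prefix]])
  current <- c(spec$common, spec$chart)
  # labels defaulted from attributelist are implicit, don't emit them
  if (!is.null(current$labels) && !is.null(current$attributelist) &&
      identical(current$labels, current$attributelist)) {
    current$labels <- NULL
  }
  parts <- character()
  for (nm in canonical_arg_order(spec$prefix)) {
    val <- current[[nm]]
    if (is.null(val)) next
    if (!is.null(defaults[[nm]]) && identical(val, defaults[[nm]])) next
    parts <- c(parts, sprintf('%s="%s"', nm, serialize_arg_value(nm, val)))
  }
  paste0(spec$prefix, ": ", paste(parts, collapse = " "))
}
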