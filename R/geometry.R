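# Chart geometry in the node-local unit frame ("UnitBox"): x and y run
# over [0, 1] with the origin at the top-left and y increasing downward.
# All layouts are computed here before any placement or scaling; angles
# are degrees with 0 at 12 o'clock and positive angles advancing
# clockwise.

#' Construct a node record
#'
#' A node record carries one node's id plus its scalar and list-valued
#' attribute columns, the form expected by [resolve_series()].
#'
#' @param node_id Node identifier.
#' @param scalars Named list of scalar values (numeric or text).
#' @param lists Named list of numeric vectors (list-valued columns).
#' @return A `node_record` object.
#' @export
node_record <- function(node_id, scalars = list(), lists = list()) {
  if (any(names(lists) %in% names(scalars))) {
    glyph_abort("column names must be unique across scalar and list columns", "duplicate_id")
  }
  structure(list(node_id = as.character(node_id), scalars = scalars, lists = lists),
            class = "node_record")
}

# ---- value resolution -------------------------------------------------------

lookup_scalar <- function(node, column) {
  v <- node$scalars[[column]]
  if (is.null(v)) {
    glyph_abort(
      sprintf("node '%s' has no column '%s'", node$node_id, column),
      "missing_attribute", node = node$node_id, column = column
    )
  }
  if (!is.numeric(v)) {
    num <- suppressWarnings(as.numeric(v))
    if (is.na(num) && !is.na(v)) {
      glyph_abort(
        sprintf("node '%s': column '%s' is not numeric ('%s')", node$node_id, column, v),
        "type", node = node$node_id, column = column
      )
    }
    v <- num
  }
  as.numeric(v)
}

series_colors <- function(colorlist, values, n, seed = 0L) {
  if (is.null(colorlist)) {
    return(generate_palette("rainbow", n, seed))
  }
  switch(colorlist$mode,
    keyword = generate_palette(colorlist$keyword, n, seed),
    gradient_keyword = {
      ramp <- ramp_for_keyword(colorlist$keyword)
      ts <- if (n == 1L) 1 else seq(1, -1, length.out = n)
      vapply(ts, function(t) rgba_to_hex(interpolate_ramp(ramp, t)), character(1))
    },
    updown = vapply(unname(values), function(v) {
      if (!is.finite(v)) v <- 0
      rgba_to_hex(resolve_updown(v, colorlist))
    }, character(1)),
    explicit = {
      cols <- vapply(colorlist$colors, rgba_to_hex, character(1))
      if (length(cols) == n) cols
      else if (length(cols) == 1L) rep(cols, n)
      else glyph_abort(
        sprintf("colorlist has %d colors for %d values", length(cols), n),
        "value_type", arg = "colorlist"
      )
    }
  )
}

#' Resolve a glyph spec's data series against one node
#'
#' Values come from the literal `values` argument when present, otherwise
#' from scalar lookups over `attributelist` (a single list-valued column
#' supplies the whole series). Labels default to the attribute names and
#' colors are resolved through the colorlist with one color per value.
#'
#' @param spec A `glyph_spec` for a chart prefix.
#' @param node A [node_record()].
#' @param seed Integer seed for seeded palettes.
#' @return A tibble with columns `value`, `label`, `color` (hex).
#' @export
resolve_series <- function(spec, node, seed = 0L) {
  stopifnot(inherits(spec, "glyph_spec"))
  common <- spec$common
  if (!is.null(common$values)) {
    values <- common$values
    labels <- common$labels %||% rep("", length(values))
  } else if (!is.null(common$attributelist)) {
    attrs <- common$attributelist
    if (length(attrs) == 1L && !is.null(node$lists[[attrs]])) {
      values <- as.numeric(node$lists[[attrs]])
      labels <- rep("", length(values))
    } else {
      values <- vapply(attrs, lookup_scalar, numeric(1), node = node)
      labels <- common$labels %||% attrs
    }
  } else {
    glyph_abort(sprintf("%s has no values or attributelist", spec$prefix),
      "missing_required")
  }
  n <- length(values)
  if (!is.null(common$labels) && length(common$labels) == n) {
    labels <- common$labels
  }
  if (length(labels) != n) labels <- rep("", n)
  tibble::tibble(
    value = unname(values),
    label = unname(labels),
    color = series_colors(common$colorlist, values, n, seed)
  )
}

# Rings for a circos chart: each attributelist entry names a list-valued
# column (a scalar column gives a one-slice ring).
resolve_rings <- function(spec, node, seed = 0L) {
  common <- spec$common
  if (!is.null(common$values)) {
    return(list(resolve_series(spec, node, seed)))
  }
  lapply(common$attributelist, function(column) {
    if (!is.null(node$lists[[column]])) {
      values <- as.numeric(node$lists[[column]])
    } else {
      values <- lookup_scalar(node, column)
    }
    n <- length(values)
    tibble::tibble(
      value = values,
      label = if (n == 1L) column else rep("", n),
      color = series_colors(common$colorlist, values, n, seed)
    )
  })
}

# ---- normalization ----------------------------------------------------------

#' Normalize a value against a range
#'
#' When the range straddles zero the normalization is symmetric about
#' zero: `t = v / max(|min|, |max|)`, so zero always maps to the chart
#' baseline. Otherwise `[min, max]` maps affinely onto `[0, 1]`. Values
#' outside the range clamp to the nearest bound.
#'
#' @param v Numeric vector of values.
#' @param range Numeric `c(min, max)` with `min < max`.
#' @return Normalized values in `[-1, 1]`.
#' @examples
#' normalize_value(c(-3, 0, 3), c(-3, 3))
#' @export
normalize_value <- function(v, range) {
  if (!is.numeric(range) || length(range) != 2L || range[[1L]] >= range[[2L]]) {
    glyph_abort("range must be c(min, max) with min < max", "range")
  }
  lo <- range[[1L]]; hi <- range[[2L]]
  if (lo < 0 && hi > 0) {
    t <- v / max(abs(lo), abs(hi))
    pmin(pmax(t, -1), 1)
  } else {
    t <- (v - lo) / (hi - lo)
    pmin(pmax(t, 0), 1)
  }
}

# Normalize a series using the spec range when given, else the per-node
# extremes; a flat (degenerate) autoscale range falls back to the sign of
# each value. Missing values map to 0 with a warning.
normalize_series <- function(values, range = NULL) {
  bad <- !is.finite(values)
  if (any(bad)) {
    glyph_warn(sprintf("%d missing value(s) rendered at zero extent", sum(bad)), "missing_value")
    values[bad] <- 0
  }
  if (!is.null(range)) {
    if (any(values < range[[1L]] | values > range[[2L]])) {
      glyph_warn("values outside range clamped", "clamp")
    }
    return(normalize_value(values, range))
  }
  lo <- min(values); hi <- max(values)
  if (lo == hi) return(sign(values))
  normalize_value(values, c(lo, hi))
}

ybase_value <- function(ybase) {
  if (is.character(ybase)) {
    switch(ybase, top = 0, middle = 0.5, bottom = 1,
      glyph_abort(sprintf("invalid ybase '%s'", ybase), "value_type"))
  } else {
    as.numeric(ybase)
  }
}

# ---- angular charts ---------------------------------------------------------

sort_slices <- function(series) {
  series[order(-series$value), , drop = FALSE]
}

angular_layout <- function(series, arcstart, sortslices, inner_radius, outer_radius) {
  values <- series$value
  bad <- !is.finite(values)
  if (any(bad)) {
    glyph_warn(sprintf("%d missing value(s) rendered at zero extent", sum(bad)), "missing_value")
    series$value[bad] <- 0
    values <- series$value
  }
  if (any(values < 0)) {
    glyph_abort("pie and circos slices require nonnegative values", "negative_slice")
  }
  total <- sum(values)
  if (total <= 0) {
    glyph_abort("cannot lay out a chart whose values sum to zero", "degenerate_pie")
  }
  if (sortslices) series <- sort_slices(series)
  extent <- 360 * series$value / total
  start <- arcstart + c(0, cumsum(extent)[-length(extent)])
  dplyr::mutate(series,
    start_angle = start %% 360,
    extent = extent,
    inner_radius = inner_radius,
    outer_radius = outer_radius
  )
}

#' Lay out a pie chart
#'
#' Slices are laid consecutively clockwise from `arcstart` (degrees, 0 at
#' 12 o'clock) with extents proportional to the values; `sortslices`
#' orders them largest first (stable under ties).
#'
#' @param series A resolved series tibble (see [resolve_series()]).
#' @param arcstart Start angle in degrees.
#' @param sortslices Sort slices from largest to smallest?
#' @return A tibble of slices with `start_angle`, `extent`,
#'   `inner_radius` (0), `outer_radius` (0.5), `color`, `label`.
#' @examples
#' s <- tibble::tibble(value = c(1, 1, 2), label = "", color = "#FF0000FF")
#' pie_layout(s)$extent
#' @export
pie_layout <- function(series, arcstart = 0, sortslices = FALSE) {
  angular_layout(series, arcstart, sortslices, inner_radius = 0, outer_radius = 0.5)
}

#' Lay out a circos (ring) chart
#'
#' Ring `k` occupies the radial band starting at `firstarc / 2` with width
#' `firstarcwidth / 2` for the innermost ring and `arcwidth / 2` for each
#' ring after it (radial proportions are stated as fractions of the node
#' diameter, hence halved into radius units with a maximum of 0.5).
#' Within each ring the angular layout is that of [pie_layout()].
#'
#' @param rings List of resolved series tibbles, innermost first.
#' @param firstarc Start of the first ring as a proportion of the node.
#' @param firstarcwidth Width of the first ring (node proportion).
#' @param arcwidth Width of each subsequent ring (node proportion).
#' @param arcstart Start angle in degrees.
#' @param sortslices Sort slices within each ring?
#' @return A tibble of slices with a `ring` column.
#' @export
circos_layout <- function(rings, firstarc = 0.2, firstarcwidth = 0.3,
                          arcwidth = 0.3, arcstart = 0, sortslices = FALSE) {
  if (length(rings) == 0L) glyph_abort("circos chart needs at least one ring", "arity")
  k <- length(rings)
  widths <- c(firstarcwidth, rep(arcwidth, k - 1L)) / 2
  inner <- firstarc / 2 + c(0, cumsum(widths)[-k])
  outer <- inner + widths
  if (outer[[k]] > 0.5 + 1e-9) {
    glyph_abort(
      sprintf("rings extend to radius %.3f, past the node edge (0.5)", outer[[k]]),
      "overflow"
    )
  }
  out <- purrr::imap(rings, function(series, i) {
    dplyr::mutate(
      angular_layout(series, arcstart, sortslices, inner[[i]], outer[[i]]),
      ring = i
    )
  })
  dplyr::bind_rows(out)
}

# ---- rectangular charts -----------------------------------------------------

bar_rects <- function(series, separation, ybase, range) {
  n <- nrow(series)
  if (n == 0L) glyph_abort("empty series", "arity")
  sep <- separation / 100  # reference units of a 100x100 node box
  if (sep * (n - 1L) >= 1) {
    glyph_abort(
      sprintf("separation %s leaves no room for %d bars", separation, n),
      "overflow"
    )
  }
  width <- (1 - sep * (n - 1L)) / n
  t <- normalize_series(series$value, range)
  yb <- ybase_value(ybase)
  x0 <- (seq_len(n) - 1L) * (width + sep)
  up <- t >= 0
  y0 <- ifelse(up, yb - t * yb, yb)
  y1 <- ifelse(up, yb, yb + (-t) * (1 - yb))
  dplyr::mutate(series,
    x0 = x0, x1 = x0 + width, y0 = y0, y1 = y1, t = t, up = up
  )
}

#' Lay out a bar chart
#'
#' `n` equal-width bars span the unit box with `separation` (in reference
#' units of a 100-wide node) between them. The baseline sits at `ybase`
#' (`top`, `middle`, `bottom`, or a proportion); positive normalized
#' values extend upward from it and negative values downward.
#'
#' @inheritParams pie_layout
#' @param separation Gap between bars in 100-unit reference units.
#' @param ybase Baseline position.
#' @param range Optional `c(min, max)` for cross-node scaling; defaults
#'   to the per-node series extremes.
#' @return A tibble of bars with `x0`, `x1`, `y0`, `y1`, the normalized
#'   value `t`, and direction flag `up`.
#' @export
bar_layout <- function(series, separation = 0, ybase = "bottom", range = NULL) {
  bar_rects(series, separation, ybase, range)
}

#' Lay out a heat-strip chart
#'
#' Identical bar geometry to [bar_layout()]; each bar is filled with a
#' vertical gradient running from the ramp color at its normalized value
#' (at the bar tip) to the ramp's zero color at the baseline.
#'
#' @inheritParams bar_layout
#' @param ramp A ramp from [ramp_for_keyword()] or an updown colorlist via
#'   its three-anchor form.
#' @return As [bar_layout()], plus `tip_color` and a `fill` list-column of
#'   linear-gradient paints.
#' @export
heatstrip_layout <- function(series, separation = 0, ramp, range = NULL,
                             ybase = "bottom") {
  bars <- bar_rects(series, separation, ybase, range)
  zero_color <- rgba_to_hex(interpolate_ramp(ramp, 0))
  tip <- vapply(bars$t, function(t) rgba_to_hex(interpolate_ramp(ramp, t)), character(1))
  # Paint coordinates are relative to each bar's own bounding box
  # (objectBoundingBox): the gradient runs from the bar tip to the
  # baseline regardless of where the bar lands on the canvas.
  fills <- purrr::map(bars$up, function(up) {
    list(
      type = "linear",
      x1 = 0.5, y1 = if (up) 0 else 1,  # tip
      x2 = 0.5, y2 = if (up) 1 else 0,  # baseline
      stops = list(
        list(color = NA_character_, position = 0),
        list(color = zero_color, position = 1)
      )
    )
  })
  fills <- purrr::map2(fills, tip, function(f, tc) {
    f$stops[[1L]]$color <- tc
    f
  })
  dplyr::mutate(bars, tip_color = tip, fill = fills, color = tip)
}

#' Lay out a line chart
#'
#' Points sit at `x = i/(n-1)` with y from the normalized value about the
#' `ybase` baseline, joined by a polyline.
#'
#' @inheritParams bar_layout
#' @param linewidth Stroke width in 100-unit reference units.
#' @return A list with `points` (tibble `x`, `y`, `label`, `t`),
#'   `linewidth` (unit-box units), and `color`.
#' @export
line_layout <- function(series, linewidth = 1, range = NULL, ybase = "bottom") {
  n <- nrow(series)
  if (n < 2L) {
    glyph_abort("a line chart needs at least two points", "too_few_points")
  }
  t <- normalize_series(series$value, range)
  yb <- ybase_value(ybase)
  y <- ifelse(t >= 0, yb - t * yb, yb + (-t) * (1 - yb))
  list(
    points = tibble::tibble(
      x = (seq_len(n) - 1L) / (n - 1L),
      y = y,
      label = series$label,
      t = t
    ),
    linewidth = linewidth / 100,
    color = series$color[[1L]]
  )
}

#' Lay out a stripe chart
#'
#' Splits the unit box into `n` full-height vertical stripes of equal
#' width, one per palette color, with no gaps.
#'
#' @param colors Character vector of hex colors, left to right.
#' @return A tibble of stripes with `x0`, `x1`, `y0`, `y1`, `color`.
#' @export
stripe_layout <- function(colors) {
  n <- length(colors)
  if (n == 0L) glyph_abort("stripe chart needs at least one color", "empty_palette")
  i <- seq_len(n) - 1L
  tibble::tibble(
    x0 = i / n, x1 = (i + 1L) / n, y0 = 0, y1 = 1,
    color = colors
  )
}

#' Build the paint definition for a gradient glyph
#'
#' Linear gradients run along the axis from `start` to `end`; radial
#' gradients emanate from `center` out to the proportional `radius`. The
#' paint fills the node shape.
#'
#' @param spec A `glyph_spec` with prefix `lingrad` or `radgrad`.
#' @return A paint list (`type`, geometry fields, `stops` with hex
#'   colors).
#' @export
gradient_frame <- function(spec) {
  stopifnot(inherits(spec, "glyph_spec"))
  stops <- lapply(spec$chart$stoplist, function(s) {
    list(color = rgba_to_hex(s$color), position = s$position)
  })
  if (spec$prefix == "lingrad") {
    if (identical(spec$chart$start, spec$chart$end)) {
      glyph_abort("linear gradient start and end coincide", "degenerate_axis")
    }
    list(type = "linear",
         x1 = spec$chart$start[[1L]], y1 = spec$chart$start[[2L]],
         x2 = spec$chart$end[[1L]], y2 = spec$chart$end[[2L]],
         stops = stops)
  } else if (spec$prefix == "radgrad") {
    list(type = "radial",
         cx = spec$chart$center[[1L]], cy = spec$chart$center[[2L]],
         r = spec$chart$radius,
         stops = stops)
  } else {
    glyph_abort(sprintf("'%s' is not a gradient prefix", spec$prefix), "value_type")
  }
}
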