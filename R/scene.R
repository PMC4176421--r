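# Vector scenes: ordered lists of styled primitives, first in node-local
# unit coordinates, then composed (scaled, offset by slot, translated)
# into canvas coordinates. Primitives render strictly in list order.
# Gradient paints use coordinates relative to the bounding box of the
# element they fill, so composition never has to rewrite them.

new_scene <- function(primitives, scale = 1) {
  structure(list(primitives = primitives, scale = scale), class = "glyph_scene")
}

#' @export
print.glyph_scene <- function(x, ...) {
  kinds <- vapply(x$primitives, `[[`, character(1), "kind")
  cat("<glyph_scene> ", length(kinds), " primitives (",
      paste(sprintf("%s=%d", names(table(kinds)), table(kinds)), collapse = ", "),
      ")\n", sep = "")
  invisible(x)
}

prim_rect <- function(x0, y0, x1, y1, fill) {
  list(kind = "rect", x0 = x0, y0 = y0, x1 = x1, y1 = y1, fill = fill)
}
prim_sector <- function(cx, cy, r0, r1, start, extent, fill) {
  list(kind = "sector", cx = cx, cy = cy, r0 = r0, r1 = r1,
       start = start, extent = extent, fill = fill)
}
prim_polyline <- function(x, y, stroke, width) {
  list(kind = "polyline", x = x, y = y, stroke = stroke, width = width)
}
prim_text <- function(x, y, text, style, anchor = "middle") {
  list(kind = "text", x = x, y = y, text = text, style = style, anchor = anchor)
}
prim_nodefill <- function(fill) {
  list(kind = "nodefill", fill = fill)
}

known_fonts <- c("sans-serif", "serif", "monospace", "arial", "helvetica",
                 "times", "times new roman", "courier", "courier new")

label_style_from <- function(common) {
  font <- common$labelfont %||% "sans-serif"
  if (!tolower(font) %in% known_fonts) {
    glyph_warn(sprintf("font '%s' may be unavailable; a sans fallback is appended", font),
               "font_fallback")
    font <- paste0(font, ", sans-serif")
  }
  list(
    font = font,
    size = (common$labelsize %||% 8) / 100,  # points in the 100-unit reference box
    style = common$labelstyle %||% "plain",
    color = if (is.null(common$labelcolor)) "#000000FF" else rgba_to_hex(common$labelcolor)
  )
}

#' Build a vector scene from chart geometry
#'
#' Chart primitives come first, then (unless `showlabels` is `FALSE`) one
#' text primitive per labelled element: above or below the tip for bars
#' and heat strips, at mid-angle and mid-radius for pie and circos
#' slices, at each point for lines.
#'
#' @param layout The output of one of the `*_layout()` functions.
#' @param type One of `pie`, `circos`, `bar`, `heatstrip`, `line`,
#'   `stripe`, `gradient`.
#' @param label_style A list with `font`, `size`, `style`, `color`.
#' @param showlabels Draw label text?
#' @return A `glyph_scene`.
#' @export
build_scene <- function(layout, type, label_style = NULL, showlabels = TRUE) {
  style <- label_style %||% label_style_from(common_defaults())
  prims <- list()
  labels <- list()
  add_label <- function(x, y, text, anchor = "middle") {
    if (is.na(text) || !nzchar(text)) return(invisible(NULL))
    labels[[length(labels) + 1L]] <<- prim_text(x, y, text, style, anchor)
    invisible(NULL)
  }
  if (type %in% c("pie", "circos")) {
    for (i in seq_len(nrow(layout))) {
      s <- layout[i, ]
      prims[[length(prims) + 1L]] <- prim_sector(
        0.5, 0.5, s$inner_radius, s$outer_radius, s$start_angle, s$extent, s$color
      )
      mid_a <- (s$start_angle + s$extent / 2) * pi / 180
      mid_r <- (s$inner_radius + s$outer_radius) / 2
      add_label(0.5 + mid_r * sin(mid_a), 0.5 - mid_r * cos(mid_a), s$label)
    }
  } else if (type %in% c("bar", "heatstrip")) {
    for (i in seq_len(nrow(layout))) {
      b <- layout[i, ]
      fill <- if (type == "heatstrip") b$fill[[1L]] else b$color
      prims[[length(prims) + 1L]] <- prim_rect(b$x0, b$y0, b$x1, b$y1, fill)
      xm <- (b$x0 + b$x1) / 2
      if (b$up) add_label(xm, b$y0 - 0.02, b$label)
      else add_label(xm, b$y1 + 0.02 + style$size, b$label)
    }
  } else if (type == "line") {
    prims[[1L]] <- prim_polyline(layout$points$x, layout$points$y,
                                 layout$color, layout$linewidth)
    for (i in seq_len(nrow(layout$points))) {
      p <- layout$points[i, ]
      add_label(p$x, p$y - 0.02, p$label)
    }
  } else if (type == "stripe") {
    for (i in seq_len(nrow(layout))) {
      s <- layout[i, ]
      prims[[length(prims) + 1L]] <- prim_rect(s$x0, s$y0, s$x1, s$y1, s$color)
    }
  } else if (type == "gradient") {
    prims[[1L]] <- prim_nodefill(layout)
  } else {
    glyph_abort(sprintf("unknown scene type '%s'", type), "value_type")
  }
  if (!showlabels) labels <- list()
  new_scene(c(prims, labels))
}

#' Build the scene for one glyph spec on one node
#'
#' Dispatches on the spec's prefix: resolves the data series from the
#' node record, computes the layout, and assembles the vector scene
#' (carrying the spec's `scale` for composition).
#'
#' @param spec A `glyph_spec`.
#' @param node A [node_record()] (ignored by gradients, which do not
#'   depend on node data).
#' @param seed Integer seed for seeded palettes.
#' @return A `glyph_scene`.
#' @export
glyph_scene_for <- function(spec, node = node_record("n"), seed = 0L) {
  stopifnot(inherits(spec, "glyph_spec"))
  common <- spec$common
  style <- label_style_from(common)
  show <- isTRUE(common$showlabels)
  scene <- switch(spec$prefix,
    piechart = {
      series <- resolve_series(spec, node, seed)
      build_scene(pie_layout(series, spec$chart$arcstart, spec$chart$sortslices),
                  "pie", style, show)
    },
    circoschart = {
      rings <- resolve_rings(spec, node, seed)
      layout <- circos_layout(rings, spec$chart$firstarc, spec$chart$firstarcwidth,
                              spec$chart$arcwidth, spec$chart$arcstart,
                              spec$chart$sortslices)
      sc <- build_scene(layout, "circos", style, show)
      if (isTRUE(spec$chart$labelcircles) && show) {
        # ring names at each ring's mid-radius, 12 o'clock
        mids <- tapply((layout$inner_radius + layout$outer_radius) / 2, layout$ring, mean)
        nms <- common$attributelist %||% rep("", length(mids))
        for (i in seq_along(mids)) {
          if (i <= length(nms) && nzchar(nms[[i]])) {
            sc$primitives[[length(sc$primitives) + 1L]] <-
              prim_text(0.5, 0.5 - mids[[i]], nms[[i]], style)
          }
        }
      }
      sc
    },
    barchart = {
      series <- resolve_series(spec, node, seed)
      build_scene(bar_layout(series, spec$chart$separation, common$ybase, common$range),
                  "bar", style, show)
    },
    heatstripchart = {
      series <- resolve_series(spec, node, seed)
      cl <- common$colorlist %||% list(mode = "gradient_keyword", keyword = "yellowblue")
      ramp <- if (cl$mode == "updown") ramp_from_updown(cl) else ramp_for_keyword(cl$keyword)
      build_scene(
        heatstrip_layout(series, spec$chart$separation, ramp, common$range, common$ybase),
        "heatstrip", style, show
      )
    },
    linechart = {
      series <- resolve_series(spec, node, seed)
      build_scene(line_layout(series, spec$chart$linewidth, common$range, common$ybase),
                  "line", style, show)
    },
    stripechart = {
      colors <- series_colors(common$colorlist, numeric(),
                              length(common$colorlist$colors), seed)
      build_scene(stripe_layout(colors), "stripe", style, show)
    },
    lingrad = ,
    radgrad = build_scene(gradient_frame(spec), "gradient", style, FALSE)
  )
  scene$scale <- common$scale %||% 1
  scene
}

# ---- slot composition -------------------------------------------------------

#' Default offsets of the nine glyph slots
#'
#' Slot 1 is the node center; slots 2-9 walk the eight compass points
#' clockwise from north. Offsets are expressed in node-size fractions.
#'
#' @return A tibble with `slot`, `dx`, `dy`.
#' @export
slot_offsets <- function() {
  tibble::tibble(
    slot = 1:9,
    dx = c(0, 0, 1, 1, 1, 0, -1, -1, -1),
    dy = c(0, -1, -1, 0, 1, 1, 1, 0, -1)
  )
}

#' Compose glyph scenes onto a node
#'
#' Each scene is scaled by its spec's `scale` about its own center,
#' translated to the node center plus its slot offset, and drawn in slot
#' order (later slots above earlier ones). Gradient node fills become the
#' node shape itself, filled with the gradient paint.
#'
#' @param scenes A list of `glyph_scene` objects (at most nine).
#' @param slots Integer slots in `[1, 9]`, one per scene, no duplicates.
#' @param node_bbox Numeric `c(x, y, width, height)`: node center and
#'   size in canvas units.
#' @param node_shape `"rect"` or `"ellipse"`.
#' @return A composed `glyph_scene` in canvas coordinates.
#' @export
compose_node <- function(scenes, slots = seq_along(scenes), node_bbox,
                         node_shape = c("rect", "ellipse")) {
  node_shape <- match.arg(node_shape)
  if (length(scenes) < 1L) glyph_abort("nothing to compose", "arity")
  if (length(scenes) > 9L) {
    glyph_abort(
      sprintf("%d glyphs requested but a node has only 9 slots", length(scenes)),
      "slot_overflow"
    )
  }
  if (length(slots) != length(scenes) || any(slots < 1L | slots > 9L)) {
    glyph_abort("each scene needs a slot in [1, 9]", "range")
  }
  if (anyDuplicated(slots)) {
    glyph_abort(
      sprintf("slot %d assigned twice", slots[duplicated(slots)][[1L]]),
      "duplicate_slot"
    )
  }
  cx <- node_bbox[[1L]]; cy <- node_bbox[[2L]]
  w <- node_bbox[[3L]]; h <- node_bbox[[4L]]
  offsets <- slot_offsets()
  ord <- order(slots)
  prims <- list()
  for (k in ord) {
    scene <- scenes[[k]]
    s <- scene$scale %||% 1
    off <- offsets[offsets$slot == slots[[k]], ]
    tx <- function(u) cx + ((u - 0.5) * s + off$dx) * w
    ty <- function(v) cy + ((v - 0.5) * s + off$dy) * h
    for (p in scene$primitives) {
      q <- switch(p$kind,
        rect = prim_rect(tx(p$x0), ty(p$y0), tx(p$x1), ty(p$y1), p$fill),
        sector = {
          p$cx <- tx(p$cx); p$cy <- ty(p$cy)
          p$rx0 <- p$r0 * s * w; p$ry0 <- p$r0 * s * h
          p$rx1 <- p$r1 * s * w; p$ry1 <- p$r1 * s * h
          p
        },
        polyline = prim_polyline(tx(p$x), ty(p$y), p$stroke,
                                 p$width * s * min(w, h)),
        text = {
          p$x <- tx(p$x); p$y <- ty(p$y)
          p$style$size <- p$style$size * s * h
          p
        },
        nodefill = {
          # the gradient paints the node shape itself
          half_w <- w * s / 2; half_h <- h * s / 2
          ncx <- cx + off$dx * w; ncy <- cy + off$dy * h
          list(kind = if (node_shape == "ellipse") "ellipse" else "rect2",
               cx = ncx, cy = ncy, rx = half_w, ry = half_h,
               x0 = ncx - half_w, y0 = ncy - half_h,
               x1 = ncx + half_w, y1 = ncy + half_h,
               fill = p$fill)
        },
        p
      )
      if (identical(q$kind, "rect2")) q$kind <- "rect"
      prims[[length(prims) + 1L]] <- q
    }
  }
  new_scene(prims)
}
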