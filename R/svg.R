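# Deterministic SVG 1.1 emission. The same inputs always produce
# byte-identical output: element ids derive from node id and slot, floats
# are formatted with a fixed rule, and primitives are written in scene
# order.

fmt_svg <- function(x) {
  s <- sprintf("%.4f", x)
  s <- sub("0+$", "", s)
  s <- sub("\\.$", "", s)
  sub("^-0$", "0", s)
}

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  gsub("\"", "&quot;", x, fixed = TRUE)
}

# hex "#RRGGBBAA" -> list(color = "#RRGGBB", opacity = numeric)
split_alpha <- function(hex) {
  if (nchar(hex) == 9L) {
    list(color = substr(hex, 1L, 7L),
         opacity = strtoi(substr(hex, 8L, 9L), 16L) / 255)
  } else {
    list(color = hex, opacity = 1)
  }
}

fill_attrs <- function(hex) {
  fa <- split_alpha(hex)
  if (fa$opacity < 1) {
    sprintf('fill="%s" fill-opacity="%s"', fa$color, fmt_svg(fa$opacity))
  } else {
    sprintf('fill="%s"', fa$color)
  }
}

gradient_def <- function(paint, id) {
  stops <- vapply(paint$stops, function(s) {
    fa <- split_alpha(s$color)
    sprintf('    <stop offset="%s" stop-color="%s" stop-opacity="%s"/>',
            fmt_svg(s$position), fa$color, fmt_svg(fa$opacity))
  }, character(1))
  if (paint$type == "linear") {
    open <- sprintf(
      '  <linearGradient id="%s" x1="%s" y1="%s" x2="%s" y2="%s">',
      id, fmt_svg(paint$x1), fmt_svg(paint$y1), fmt_svg(paint$x2), fmt_svg(paint$y2)
    )
    close <- "  </linearGradient>"
  } else {
    open <- sprintf(
      '  <radialGradient id="%s" cx="%s" cy="%s" r="%s">',
      id, fmt_svg(paint$cx), fmt_svg(paint$cy), fmt_svg(paint$r)
    )
    close <- "  </radialGradient>"
  }
  paste(c(open, stops, close), collapse = "\n")
}

sector_path <- function(p) {
  rx1 <- p$rx1 %||% p$r1; ry1 <- p$ry1 %||% p$r1
  rx0 <- p$rx0 %||% p$r0; ry0 <- p$ry0 %||% p$r0
  pt <- function(rx, ry, ang) {
    a <- ang * pi / 180
    c(p$cx + rx * sin(a), p$cy - ry * cos(a))
  }
  a0 <- p$start; a1 <- p$start + min(p$extent, 360)
  if (p$extent >= 360 - 1e-9) {
    # full ring: two half arcs (outer), and two reversed (inner) if r0 > 0
    o1 <- pt(rx1, ry1, a0); o2 <- pt(rx1, ry1, a0 + 180)
    d <- sprintf("M %s %s A %s %s 0 1 1 %s %s A %s %s 0 1 1 %s %s Z",
      fmt_svg(o1[1]), fmt_svg(o1[2]), fmt_svg(rx1), fmt_svg(ry1),
      fmt_svg(o2[1]), fmt_svg(o2[2]), fmt_svg(rx1), fmt_svg(ry1),
      fmt_svg(o1[1]), fmt_svg(o1[2]))
    if (rx0 > 0) {
      i1 <- pt(rx0, ry0, a0); i2 <- pt(rx0, ry0, a0 + 180)
      d <- paste(d, sprintf("M %s %s A %s %s 0 1 0 %s %s A %s %s 0 1 0 %s %s Z",
        fmt_svg(i1[1]), fmt_svg(i1[2]), fmt_svg(rx0), fmt_svg(ry0),
        fmt_svg(i2[1]), fmt_svg(i2[2]), fmt_svg(rx0), fmt_svg(ry0),
        fmt_svg(i1[1]), fmt_svg(i1[2])))
    }
    return(d)
  }
  large <- if (p$extent > 180) 1 else 0
  o0 <- pt(rx1, ry1, a0); o1 <- pt(rx1, ry1, a1)
  if (rx0 > 0) {
    i1 <- pt(rx0, ry0, a1); i0 <- pt(rx0, ry0, a0)
    sprintf("M %s %s A %s %s 0 %d 1 %s %s L %s %s A %s %s 0 %d 0 %s %s Z",
      fmt_svg(o0[1]), fmt_svg(o0[2]), fmt_svg(rx1), fmt_svg(ry1), large,
      fmt_svg(o1[1]), fmt_svg(o1[2]),
      fmt_svg(i1[1]), fmt_svg(i1[2]), fmt_svg(rx0), fmt_svg(ry0), large,
      fmt_svg(i0[1]), fmt_svg(i0[2]))
  } else {
    sprintf("M %s %s L %s %s A %s %s 0 %d 1 %s %s Z",
      fmt_svg(p$cx), fmt_svg(p$cy),
      fmt_svg(o0[1]), fmt_svg(o0[2]), fmt_svg(rx1), fmt_svg(ry1), large,
      fmt_svg(o1[1]), fmt_svg(o1[2]))
  }
}

font_style_attrs <- function(style) {
  extra <- switch(style$style,
    italics = ' font-style="italic"',
    bold = ' font-weight="bold"',
    bolditalic = ' font-style="italic" font-weight="bold"',
    ""
  )
  fa <- split_alpha(style$color)
  sprintf('font-family="%s" font-size="%s" fill="%s"%s',
          xml_escape(style$font), fmt_svg(style$size), fa$color, extra)
}

emit_primitive <- function(p, fill_id = NULL) {
  fill <- if (is.list(p$fill)) {
    sprintf('fill="url(#%s)"', fill_id)
  } else if (!is.null(p$fill)) {
    fill_attrs(p$fill)
  } else {
    ""
  }
  switch(p$kind,
    rect = sprintf('    <rect x="%s" y="%s" width="%s" height="%s" %s/>',
      fmt_svg(min(p$x0, p$x1)), fmt_svg(min(p$y0, p$y1)),
      fmt_svg(abs(p$x1 - p$x0)), fmt_svg(abs(p$y1 - p$y0)), fill),
    ellipse = sprintf('    <ellipse cx="%s" cy="%s" rx="%s" ry="%s" %s/>',
      fmt_svg(p$cx), fmt_svg(p$cy), fmt_svg(p$rx), fmt_svg(p$ry), fill),
    sector = sprintf('    <path d="%s" %s/>', sector_path(p), fill),
    polyline = sprintf(
      '    <polyline points="%s" fill="none" stroke="%s" stroke-width="%s"/>',
      paste(sprintf("%s,%s", vapply(p$x, fmt_svg, character(1)),
                    vapply(p$y, fmt_svg, character(1))), collapse = " "),
      split_alpha(p$stroke)$color, fmt_svg(p$width)),
    text = sprintf('    <text x="%s" y="%s" text-anchor="%s" %s>%s</text>',
      fmt_svg(p$x), fmt_svg(p$y), p$anchor %||% "middle",
      font_style_attrs(p$style), xml_escape(p$text)),
    glyph_abort(sprintf("cannot emit primitive kind '%s'", p$kind), "value_type")
  )
}

#' Render a composed network scene to SVG text
#'
#' Emits well-formed SVG 1.1: gradient paints as `<linearGradient>` /
#' `<radialGradient>` defs, edges as lines, node base shapes, then the
#' composed glyph scenes in stable order. Identical inputs give
#' byte-identical output; element ids derive from node id and slot.
#'
#' @param nodes Tibble with `id`, `x`, `y`, `width`, `height`, `shape`.
#' @param edges Tibble with `source`, `target` (ids present in `nodes`),
#'   or `NULL`.
#' @param node_scenes Named list (by node id) of composed `glyph_scene`
#'   objects in canvas coordinates.
#' @param canvas Numeric `c(width, height)` in pixels.
#' @return A character scalar: the SVG document.
#' @export
render_svg <- function(nodes, edges = NULL, node_scenes = list(),
                       canvas = c(800, 600)) {
  out <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    sprintf(
      '<svg xmlns="http://www.w3.org/2000/svg" version="1.1" width="%s" height="%s" viewBox="0 0 %s %s">',
      fmt_svg(canvas[[1L]]), fmt_svg(canvas[[2L]]),
      fmt_svg(canvas[[1L]]), fmt_svg(canvas[[2L]])
    )
  )
  # collect gradient defs in document order
  defs <- character()
  fill_ids <- list()
  for (node_id in names(node_scenes)) {
    prims <- node_scenes[[node_id]]$primitives
    k <- 0L
    ids <- character(length(prims))
    for (i in seq_along(prims)) {
      if (is.list(prims[[i]]$fill)) {
        k <- k + 1L
        ids[[i]] <- sprintf("grad-%s-%d", gsub("[^A-Za-z0-9_.-]", "_", node_id), k)
        defs <- c(defs, gradient_def(prims[[i]]$fill, ids[[i]]))
      }
    }
    fill_ids[[node_id]] <- ids
  }
  if (length(defs)) out <- c(out, "<defs>", defs, "</defs>")

  if (!is.null(edges) && nrow(edges)) {
    out <- c(out, '  <g id="edges" stroke="#999999" stroke-width="1">')
    for (i in seq_len(nrow(edges))) {
      s <- nodes[nodes$id == edges$source[[i]], ]
      t <- nodes[nodes$id == edges$target[[i]], ]
      if (nrow(s) == 0L || nrow(t) == 0L) next
      out <- c(out, sprintf('    <line x1="%s" y1="%s" x2="%s" y2="%s"/>',
        fmt_svg(s$x), fmt_svg(s$y), fmt_svg(t$x), fmt_svg(t$y)))
    }
    out <- c(out, "  </g>")
  }

  if (nrow(nodes)) {
    out <- c(out, '  <g id="nodes" fill="#F2F2F2" stroke="#666666" stroke-width="1">')
    for (i in seq_len(nrow(nodes))) {
      n <- nodes[i, ]
      if (identical(n$shape, "ellipse")) {
        out <- c(out, sprintf('    <ellipse cx="%s" cy="%s" rx="%s" ry="%s"/>',
          fmt_svg(n$x), fmt_svg(n$y), fmt_svg(n$width / 2), fmt_svg(n$height / 2)))
      } else {
        out <- c(out, sprintf('    <rect x="%s" y="%s" width="%s" height="%s"/>',
          fmt_svg(n$x - n$width / 2), fmt_svg(n$y - n$height / 2),
          fmt_svg(n$width), fmt_svg(n$height)))
      }
    }
    out <- c(out, "  </g>")
  }

  for (node_id in names(node_scenes)) {
    scene <- node_scenes[[node_id]]
    out <- c(out, sprintf('  <g id="glyph-%s">', gsub("[^A-Za-z0-9_.-]", "_", node_id)))
    ids <- fill_ids[[node_id]]
    for (i in seq_along(scene$primitives)) {
      out <- c(out, emit_primitive(scene$primitives[[i]], ids[[i]]))
    }
    out <- c(out, "  </g>")
  }
  paste(c(out, "</svg>", ""), collapse = "\n")
}

#' Rasterize an SVG document to PNG
#'
#' Delegates to an external rasterizer (`rsvg-convert`, `cairosvg`, or
#' `inkscape`, whichever is found on the PATH). This is a preview
#' convenience only; the canonical output of the package is the SVG
#' itself.
#'
#' @param svg SVG document text.
#' @param path Output PNG path.
#' @param dpi Raster resolution (dots per inch; SVG pixels are 96/inch).
#' @param rasterizer Optional explicit rasterizer command name.
#' @return The output path, invisibly.
#' @export
render_raster <- function(svg, path, dpi = 96, rasterizer = NULL) {
  candidates <- rasterizer %||% c("rsvg-convert", "cairosvg", "inkscape")
  found <- candidates[nzchar(Sys.which(candidates))]
  if (length(found) == 0L) {
    glyph_abort(
      paste0(
        "no SVG rasterizer found on the PATH; install one of ",
        paste(candidates, collapse = ", "),
        " (e.g. rsvg-convert from librsvg) for PNG previews"
      ),
      "capability"
    )
  }
  tool <- found[[1L]]
  tmp <- tempfile(fileext = ".svg")
  on.exit(unlink(tmp), add = TRUE)
  writeLines(svg, tmp)
  args <- switch(tool,
    "rsvg-convert" = c("-d", dpi, "-p", dpi, "-o", path, tmp),
    "cairosvg" = c(tmp, "-d", dpi, "-o", path),
    "inkscape" = c(tmp, sprintf("--export-dpi=%s", dpi),
                   sprintf("--export-filename=%s", path))
  )
  status <- system2(tool, args, stdout = FALSE, stderr = FALSE)
  if (status != 0L || !file.exists(path)) {
    glyph_abort(sprintf("rasterizer %s failed (exit %d)", tool, status), "capability")
  }
  invisible(path)
}
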