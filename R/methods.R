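# Tidier and plotting methods for the package's objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a glyph spec into an argument table
#'
#' @param x A `glyph_spec`.
#' @param ... Unused.
#' @return A tibble with one row per non-default argument: `argument`,
#'   `value` (canonical text form).
#' @method tidy glyph_spec
#' @export
tidy.glyph_spec <- function(x, ...) {
  defaults <- c(common_defaults(), chart_defaults[[x$prefix]])
  current <- c(x$common, x$chart)
  rows <- purrr::compact(purrr::map(canonical_arg_order(x$prefix), function(nm) {
    val <- current[[nm]]
    if (is.null(val)) return(NULL)
    if (!is.null(defaults[[nm]]) && identical(val, defaults[[nm]])) return(NULL)
    tibble::tibble(argument = nm, value = serialize_arg_value(nm, val))
  }))
  dplyr::bind_rows(rows)
}

#' One-row summary of a glyph spec
#'
#' @param x A `glyph_spec`.
#' @param ... Unused.
#' @return A one-row tibble: `prefix`, `category` (chart or gradient),
#'   `n_args`, `n_values`, `uses_attributes`.
#' @method glance glyph_spec
#' @export
glance.glyph_spec <- function(x, ...) {
  tibble::tibble(
    prefix = x$prefix,
    category = if (x$prefix %in% glyph_prefixes("gradient")) "gradient" else "chart",
    n_args = nrow(tidy(x)),
    n_values = length(x$common$values %||% numeric()),
    uses_attributes = !is.null(x$common$attributelist)
  )
}

# Flatten a scene's primitives for plotting or inspection.
scene_tibble <- function(scene) {
  rows <- purrr::map(scene$primitives, function(p) {
    fill <- if (is.list(p$fill)) p$fill$stops[[1L]]$color else p$fill %||% NA_character_
    switch(p$kind,
      rect = tibble::tibble(kind = "rect", x0 = p$x0, y0 = p$y0, x1 = p$x1,
                            y1 = p$y1, fill = fill),
      sector = tibble::tibble(kind = "sector", cx = p$cx, cy = p$cy,
                              r0 = p$r0, r1 = p$r1, start = p$start,
                              extent = p$extent, fill = fill),
      polyline = tibble::tibble(kind = "polyline", fill = p$stroke),
      text = tibble::tibble(kind = "text", x0 = p$x, y0 = p$y, fill = p$style$color),
      tibble::tibble(kind = p$kind, fill = fill)
    )
  })
  dplyr::bind_rows(rows)
}

#' Plot a glyph scene with ggplot2
#'
#' A quick-look rendering of a node-local scene: rectangles, sector
#' outlines (as polygon approximations), polylines, and label anchors.
#' The canonical output of the package is [render_svg()]; this plot is a
#' development aid.
#'
#' @param object A `glyph_scene`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.glyph_scene <- function(object, ...) {
  rlang::check_installed("ggplot2")
  layers <- list()
  poly <- list()
  for (p in object$primitives) {
    if (p$kind == "rect") {
      fill <- if (is.list(p$fill)) p$fill$stops[[1L]]$color else p$fill
      poly[[length(poly) + 1L]] <- tibble::tibble(
        x = c(p$x0, p$x1, p$x1, p$x0), y = c(p$y0, p$y0, p$y1, p$y1),
        group = length(poly) + 1L, fill = substr(fill, 1, 7)
      )
    } else if (p$kind == "sector") {
      a <- seq(p$start, p$start + p$extent, length.out = 64) * pi / 180
      r1 <- p$r1 %||% p$rx1
      r0 <- p$r0 %||% p$rx0
      x <- c(p$cx + r1 * sin(a), rev(p$cx + r0 * sin(a)))
      y <- c(p$cy - r1 * cos(a), rev(p$cy - r0 * cos(a)))
      poly[[length(poly) + 1L]] <- tibble::tibble(
        x = x, y = y, group = length(poly) + 1L, fill = substr(p$fill, 1, 7)
      )
    } else if (p$kind == "polyline") {
      layers[[length(layers) + 1L]] <- ggplot2::geom_path(
        data = tibble::tibble(x = p$x, y = p$y),
        ggplot2::aes(x = .data$x, y = .data$y),
        color = substr(p$stroke, 1, 7), linewidth = 1
      )
    } else if (p$kind == "text") {
      layers[[length(layers) + 1L]] <- ggplot2::geom_text(
        data = tibble::tibble(x = p$x, y = p$y, label = p$text),
        ggplot2::aes(x = .data$x, y = .data$y, label = .data$label),
        size = 3
      )
    }
  }
  gg <- ggplot2::ggplot()
  if (length(poly)) {
    gg <- gg + ggplot2::geom_polygon(
      data = dplyr::bind_rows(poly),
      ggplot2::aes(x = .data$x, y = .data$y, group = .data$group,
                   fill = I(.data$fill))
    )
  }
  for (l in layers) gg <- gg + l
  gg + ggplot2::scale_y_reverse() + ggplot2::coord_fixed() +
    ggplot2::theme_void()
}
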