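# End-to-end rendering: node table + network + slot mapping -> SVG text.

#' Render a glyph network to SVG
#'
#' For every node, each mapped instruction column with a non-empty cell
#' is parsed, its glyph scene built against that node's record, and the
#' scenes composed at their slots; the whole network is then emitted as
#' deterministic SVG. An invalid instruction on any node fails the render
#' unless `skip_bad_nodes` is set, in which case the offending node is
#' rendered without glyphs and a warning names it.
#'
#' @param table Node-table tibble (first column `id`); instruction
#'   columns hold `type: name=value ...` text.
#' @param network A `glyph_network` from [read_network()], or `NULL` to
#'   render the table's nodes without edges.
#' @param mapping Tibble with `column` and `slot` (1-9, unique).
#' @param canvas Numeric `c(width, height)` in pixels.
#' @param node_size Numeric `c(width, height)` for nodes without layout.
#' @param node_shape `"rect"` or `"ellipse"`.
#' @param seed Integer seed for seeded palettes.
#' @param skip_bad_nodes Render past per-node instruction errors?
#' @return The SVG document as a character scalar.
#' @export
render_glyph_network <- function(table, network = NULL, mapping,
                                 canvas = c(800, 600), node_size = c(60, 60),
                                 node_shape = "ellipse", seed = 0L,
                                 skip_bad_nodes = FALSE) {
  if (!"id" %in% names(table)) {
    glyph_abort("node table must have an 'id' column", "parse")
  }
  missing_cols <- setdiff(mapping$column, names(table))
  if (length(missing_cols)) {
    glyph_abort(
      sprintf("mapped column '%s' is not in the table", missing_cols[[1L]]),
      "missing_attribute", column = missing_cols[[1L]]
    )
  }
  if (anyDuplicated(mapping$slot)) {
    glyph_abort("mapping assigns a slot twice", "duplicate_slot")
  }
  ids <- if (is.null(network)) table$id else network$nodes$id
  layout <- if (!is.null(network) && !is.null(network$layout)) {
    network$layout
  } else {
    circle_layout(ids, canvas, node_size)
  }
  nodes <- dplyr::mutate(layout, shape = node_shape)

  node_scenes <- list()
  for (id in ids) {
    if (!id %in% table$id) next
    record <- table_node_record(table, id, instruction_columns = mapping$column)
    row <- table[table$id == id, , drop = FALSE]
    scenes <- list(); slots <- integer()
    bad <- FALSE
    for (k in seq_len(nrow(mapping))) {
      cell <- row[[mapping$column[[k]]]]
      if (is.list(cell)) cell <- paste(unlist(cell), collapse = "|")
      cell <- as.character(cell)
      if (is.na(cell) || !nzchar(trimws(cell))) next
      result <- tryCatch(
        {
          spec <- parse_instruction(cell)
          glyph_scene_for(spec, record, seed)
        },
        glyph_error = function(e) e
      )
      if (is_glyph_error(result)) {
        if (skip_bad_nodes) {
          glyph_warn(
            sprintf("node '%s', column '%s': %s (skipped)",
                    id, mapping$column[[k]], conditionMessage(result)),
            "skipped_node"
          )
          bad <- TRUE
          next
        }
        glyph_abort(
          sprintf("node '%s', column '%s': %s", id, mapping$column[[k]],
                  conditionMessage(result)),
          "node_instruction",
          parent = result, node = id, column = mapping$column[[k]]
        )
      }
      scenes[[length(scenes) + 1L]] <- result
      slots <- c(slots, mapping$slot[[k]])
    }
    if (length(scenes)) {
      bbox <- nodes[nodes$id == id, ]
      node_scenes[[id]] <- compose_node(
        scenes, slots,
        c(bbox$x, bbox$y, bbox$width, bbox$height),
        node_shape = node_shape
      )
    }
  }
  edges <- if (is.null(network)) NULL else network$edges
  render_svg(nodes, edges, node_scenes, canvas)
}
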