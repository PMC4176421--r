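# Network and node-table input. GraphML is read through igraph; SIF is a
# three-column whitespace format (source, interaction, targets...) that
# carries topology only, so SIF input always needs a separate node table.

new_network <- function(nodes, edges, layout = NULL) {
  structure(list(nodes = nodes, edges = edges, layout = layout),
            class = "glyph_network")
}

#' @export
print.glyph_network <- function(x, ...) {
  cat("<glyph_network> ", nrow(x$nodes), " nodes, ", nrow(x$edges), " edges\n",
      sep = "")
  invisible(x)
}

#' Read a network from GraphML or SIF
#'
#' GraphML node data keys become scalar columns of the node tibble; SIF
#' yields topology only. Node positions, if absent, are filled later by a
#' deterministic circular layout.
#'
#' @param path File path.
#' @param format `"auto"` (by extension), `"graphml"`, or `"sif"`.
#' @return A `glyph_network`: a list with `nodes` (tibble, first column
#'   `id`), `edges` (tibble `source`, `target`, `interaction`), and
#'   `layout` (`NULL` or a tibble `id`, `x`, `y`, `width`, `height`).
#' @export
read_network <- function(path, format = c("auto", "graphml", "sif")) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    glyph_abort(sprintf("network file '%s' does not exist", path), "parse")
  }
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, graphml = "graphml", xml = "graphml", sif = "sif",
      glyph_abort(sprintf("cannot infer network format from '%s'", path), "parse"))
  }
  if (format == "graphml") read_graphml(path) else read_sif(path)
}

read_graphml <- function(path) {
  g <- tryCatch(
    igraph::read_graph(path, format = "graphml"),
    error = function(e) {
      glyph_abort(sprintf("malformed GraphML in '%s': %s", path, conditionMessage(e)),
        "parse", parent = e)
    }
  )
  attrs <- igraph::vertex_attr(g)
  ids <- attrs$name %||% attrs$id %||% as.character(seq_len(igraph::vcount(g)))
  nodes <- tibble::tibble(id = as.character(ids))
  for (nm in setdiff(names(attrs), c("name", "id"))) {
    nodes[[nm]] <- attrs[[nm]]
  }
  el <- igraph::as_edgelist(g, names = FALSE)
  edges <- tibble::tibble(
    source = nodes$id[el[, 1L]],
    target = nodes$id[el[, 2L]],
    interaction = igraph::edge_attr(g)$interaction %||% NA_character_
  )
  layout <- NULL
  if (all(c("x", "y") %in% names(attrs))) {
    layout <- tibble::tibble(
      id = nodes$id,
      x = as.numeric(attrs$x), y = as.numeric(attrs$y),
      width = as.numeric(attrs$width %||% 60), height = as.numeric(attrs$height %||% 60)
    )
    nodes$x <- NULL; nodes$y <- NULL
  }
  new_network(nodes, edges, layout)
}

read_sif <- function(path) {
  lines <- readLines(path, warn = FALSE)
  nodes <- character()
  edges <- list()
  for (i in seq_along(lines)) {
    line <- trimws(lines[[i]])
    if (!nzchar(line)) next
    tokens <- strsplit(line, "\\s+")[[1L]]
    if (length(tokens) == 1L) {
      nodes <- c(nodes, tokens)
    } else if (length(tokens) >= 3L) {
      src <- tokens[[1L]]; interaction <- tokens[[2L]]
      for (tgt in tokens[-(1:2)]) {
        edges[[length(edges) + 1L]] <- tibble::tibble(
          source = src, target = tgt, interaction = interaction
        )
      }
      nodes <- c(nodes, src, tokens[-(1:2)])
    } else {
      glyph_abort(
        sprintf("SIF line %d has 2 tokens (expected 1, or source/interaction/targets)", i),
        "parse", line = i
      )
    }
  }
  edges <- if (length(edges)) dplyr::bind_rows(edges) else
    tibble::tibble(source = character(), target = character(),
                   interaction = character())
  new_network(tibble::tibble(id = unique(nodes)), edges, NULL)
}

#' Read a delimited node table
#'
#' The first column is the node id and a header row is required. Cells
#' containing the list delimiter (default `|`) parse as list-of-real
#' columns; columns whose cells are all plain numbers parse as numeric;
#' everything else (including instruction columns) stays text.
#'
#' @param path File path.
#' @param delim Field delimiter; inferred from the extension (`.csv` vs
#'   `.tsv`/`.txt`) when `NULL`.
#' @param list_delim Delimiter inside list-valued cells.
#' @return A tibble; list-valued columns are list-columns of numeric
#'   vectors.
#' @export
read_node_table <- function(path, delim = NULL, list_delim = "|") {
  if (!file.exists(path)) {
    glyph_abort(sprintf("table file '%s' does not exist", path), "parse")
  }
  delim <- delim %||% if (tolower(tools::file_ext(path)) == "csv") "," else "\t"
  tab <- suppressWarnings(readr::read_delim(
    path, delim = delim, col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE, show_col_types = FALSE
  ))
  probs <- readr::problems(tab)
  if (nrow(probs)) {
    glyph_abort(
      sprintf("row %d of '%s' has the wrong number of fields", probs$row[[1L]], path),
      "row_arity", row = probs$row[[1L]]
    )
  }
  if (ncol(tab) < 1L) glyph_abort("node table is empty", "parse")
  names(tab)[[1L]] <- "id"
  tab$id <- as.character(tab$id)
  if (anyDuplicated(tab$id)) {
    glyph_abort(
      sprintf("duplicate node id '%s'", tab$id[duplicated(tab$id)][[1L]]),
      "duplicate_id"
    )
  }
  for (nm in setdiff(names(tab), "id")) {
    tab[[nm]] <- type_column(tab[[nm]], nm, list_delim)
  }
  tab
}

type_column <- function(cells, name, list_delim) {
  non_missing <- cells[!is.na(cells) & nzchar(cells)]
  if (length(non_missing) == 0L) return(cells)
  # list columns: at least one cell holds the delimiter and every cell is
  # a numeric list (instruction strings, which may contain '|' inside a
  # stoplist, therefore stay text)
  if (any(grepl(list_delim, non_missing, fixed = TRUE))) {
    parsed <- lapply(cells, function(cell) {
      if (is.na(cell) || !nzchar(cell)) return(numeric())
      suppressWarnings(as.numeric(strsplit(cell, list_delim, fixed = TRUE)[[1L]]))
    })
    if (!anyNA(unlist(parsed))) return(parsed)
    return(cells)
  }
  if (all(grepl(num_regex, non_missing))) {
    return(suppressWarnings(as.numeric(cells)))
  }
  cells
}

#' Write a node table
#'
#' Inverse of [read_node_table()]: list-columns are joined with the list
#' delimiter and numbers formatted so they re-read exactly.
#'
#' @param table A node-table tibble.
#' @param path Output path.
#' @param delim Field delimiter.
#' @param list_delim Delimiter inside list-valued cells.
#' @return `path`, invisibly.
#' @export
write_node_table <- function(table, path, delim = "\t", list_delim = "|") {
  fmt_cell <- function(x) {
    if (is.numeric(x)) format(x, digits = 15, scientific = FALSE, trim = TRUE)
    else as.character(x)
  }
  out <- table
  for (nm in names(out)) {
    col <- out[[nm]]
    if (is.list(col)) {
      out[[nm]] <- vapply(col, function(v) paste(fmt_cell(v), collapse = list_delim),
                          character(1))
    } else if (is.numeric(col)) {
      out[[nm]] <- vapply(col, fmt_cell, character(1))
    }
  }
  readr::write_delim(out, path, delim = delim, na = "")
  invisible(path)
}

#' Extract one node's record from a node table
#'
#' @param table A node-table tibble from [read_node_table()].
#' @param id Node id.
#' @param instruction_columns Columns to exclude (they hold instruction
#'   text, not data).
#' @return A [node_record()].
#' @export
table_node_record <- function(table, id, instruction_columns = character()) {
  row <- table[table$id == id, , drop = FALSE]
  if (nrow(row) == 0L) {
    glyph_abort(sprintf("node '%s' is not in the table", id), "missing_attribute")
  }
  scalars <- list(); lists <- list()
  for (nm in setdiff(names(table), c("id", instruction_columns))) {
    v <- row[[nm]]
    if (is.list(v)) lists[[nm]] <- v[[1L]] else scalars[[nm]] <- v[[1L]]
  }
  node_record(id, scalars, lists)
}

# Deterministic circular layout for networks without node positions.
circle_layout <- function(ids, canvas, node_size = c(60, 60)) {
  n <- length(ids)
  r <- 0.5 * min(canvas) - max(node_size)
  r <- max(r, 0.25 * min(canvas))
  angle <- 2 * pi * (seq_len(n) - 1L) / max(n, 1L)
  tibble::tibble(
    id = ids,
    x = canvas[[1L]] / 2 + r * sin(angle),
    y = canvas[[2L]] / 2 - r * cos(angle),
    width = node_size[[1L]],
    height = node_size[[2L]]
  )
}
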