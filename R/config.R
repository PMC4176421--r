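# YAML render configuration: which instruction columns go to which of the
# nine glyph slots, plus canvas and node geometry.
#
# Example:
#   mapping:
#     heatstrip: 1
#     pies: 2
#   canvas: {width: 800, height: 600}
#   node: {width: 60, height: 40, shape: ellipse}
#   seed: 1

config_known_keys <- c("mapping", "canvas", "node", "seed")

#' Load a render configuration
#'
#' @param path Path to a YAML (or JSON, which YAML subsumes) config file.
#' @return A list with `mapping` (tibble `column`, `slot`), `canvas`
#'   (`c(width, height)`), `node_size`, `node_shape`, and `seed`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) {
    glyph_abort(sprintf("config file '%s' does not exist", path), "config")
  }
  cfg <- tryCatch(yaml::read_yaml(path), error = function(e) {
    glyph_abort(sprintf("cannot parse config '%s': %s", path, conditionMessage(e)),
      "config", parent = e)
  })
  unknown <- setdiff(names(cfg), config_known_keys)
  if (length(unknown)) {
    glyph_abort(
      sprintf("unknown config key '%s' (known: %s)", unknown[[1L]],
              paste(config_known_keys, collapse = ", ")),
      "config"
    )
  }
  if (is.null(cfg$mapping) || length(cfg$mapping) == 0L) {
    glyph_abort("config must map at least one instruction column to a slot", "config")
  }
  slots <- vapply(cfg$mapping, function(s) {
    s <- suppressWarnings(as.integer(s))
    if (is.na(s) || s < 1L || s > 9L) {
      glyph_abort("slots must be integers in [1, 9]", "config")
    }
    s
  }, integer(1))
  if (anyDuplicated(slots)) {
    glyph_abort(
      sprintf("slot %d assigned to more than one column", slots[duplicated(slots)][[1L]]),
      "duplicate_slot"
    )
  }
  mapping <- tibble::tibble(column = names(cfg$mapping), slot = unname(slots))
  canvas <- c(
    as.numeric(cfg$canvas$width %||% 800),
    as.numeric(cfg$canvas$height %||% 600)
  )
  list(
    mapping = mapping,
    canvas = canvas,
    node_size = c(as.numeric(cfg$node$width %||% 60),
                  as.numeric(cfg$node$height %||% 60)),
    node_shape = cfg$node$shape %||% "ellipse",
    seed = as.integer(cfg$seed %||% 0L)
  )
}
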