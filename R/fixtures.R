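# Seeded demonstration fixtures. Two kinds are generated:
#
# * "gallery" — one node per glyph type, with integer columns a-d,
#   list-of-real columns Values, Circle1, Circle2, and one instruction
#   column per prefix, so every glyph type is exercised once.
# * "expression" — a small connected protein-interaction-like network
#   with three expression columns (values in [-3, 3]) and a single
#   heat-strip instruction column shared by all nodes, scaled
#   consistently across nodes by an explicit range.

gallery_instructions <- function() {
  c(
    glyph_lingrad = paste0(
      'lingrad: start="0.0,0.0" end="1.0,0.0" ',
      'stoplist="255,255,255,255,0.0|0,0,255,255,1.0"'
    ),
    glyph_radgrad = paste0(
      'radgrad: center="0.5,0.5" radius="0.5" ',
      'stoplist="255,255,0,255,0.0|255,0,0,255,1.0"'
    ),
    glyph_barchart = 'barchart: attributelist="a,b,c,d" colorlist="modulated" separation="2.0"',
    glyph_circoschart = paste0(
      'circoschart: attributelist="Circle1,Circle2" firstarc="0.3" ',
      'firstarcwidth="0.3" arcwidth="0.2" colorlist="contrasting"'
    ),
    glyph_heatstripchart = paste0(
      'heatstripchart: attributelist="a,b,c,d" colorlist="yellowblue" ',
      'range="-10.0,10.0"'
    ),
    glyph_linechart = 'linechart: attributelist="Values" colorlist="blue" linewidth="2.0" ybase="middle"',
    glyph_piechart = 'piechart: values="1.0,1.0,2.0" colorlist="rainbow" labels="a,b,c"',
    glyph_stripechart = 'stripechart: colorlist="red,orange,yellow,green,blue,purple"'
  )
}

expression_instruction <- function() {
  paste0(
    'heatstripchart: attributelist="gal1RGexp,gal4RGexp,gal80Rexp" ',
    'colorlist="yellowblue" range="-3.0,3.0"'
  )
}

#' Generate a seeded demo fixture
#'
#' `gallery` builds one node per glyph type carrying integer columns
#' `a`-`d`, list columns `Values`, `Circle1`, `Circle2`, and eight
#' instruction columns (each populated only on its own node).
#' `expression` builds a connected network whose nodes carry three
#' expression-like columns drawn from a seeded normal and clamped to
#' `[-3, 3]`, plus one shared heat-strip instruction column. Output is
#' bit-reproducible for a fixed seed.
#'
#' @param kind `"gallery"` or `"expression"`.
#' @param n_nodes Number of nodes (`gallery` is fixed at one per glyph
#'   type).
#' @param seed Integer seed.
#' @return A list with `network` (a `glyph_network`), `table` (node
#'   tibble including instruction columns), and `mapping` (tibble
#'   `column`, `slot`).
#' @export
generate_fixture <- function(kind = c("gallery", "expression"), n_nodes = 20,
                             seed = 1L) {
  kind <- match.arg(kind)
  if (n_nodes < 1L) glyph_abort("n_nodes must be at least 1", "range")
  withr::with_seed(as.integer(seed), {
    if (kind == "gallery") gallery_fixture() else expression_fixture(n_nodes)
  })
}

gallery_fixture <- function() {
  instr <- gallery_instructions()
  n <- length(instr)
  ids <- sub("^glyph_", "", names(instr))
  tab <- tibble::tibble(
    id = ids,
    a = sample(-9:9, n, replace = TRUE),
    b = sample(-9:9, n, replace = TRUE),
    c = sample(1:9, n, replace = TRUE),
    d = sample(-9:9, n, replace = TRUE),
    Values = lapply(seq_len(n), function(i) round(stats::runif(5, -1, 1), 3)),
    Circle1 = lapply(seq_len(n), function(i) round(stats::runif(4, 0.5, 3), 3)),
    Circle2 = lapply(seq_len(n), function(i) round(stats::runif(6, 0.5, 3), 3))
  )
  for (k in seq_len(n)) {
    col <- names(instr)[[k]]
    tab[[col]] <- ifelse(seq_len(n) == k, instr[[k]], "")
  }
  edges <- tibble::tibble(
    source = ids[-n], target = ids[-1], interaction = "demo"
  )
  network <- new_network(tibble::tibble(id = ids), edges)
  mapping <- tibble::tibble(column = names(instr), slot = seq_len(n))
  list(network = network, table = tab, mapping = mapping)
}

expression_fixture <- function(n_nodes) {
  ids <- sprintf("YGL%03dC", seq_len(n_nodes))
  clamp3 <- function(x) pmin(pmax(round(x, 3), -3), 3)
  tab <- tibble::tibble(
    id = ids,
    gal1RGexp = clamp3(stats::rnorm(n_nodes, 0, 1.2)),
    gal4RGexp = clamp3(stats::rnorm(n_nodes, 0, 1.2)),
    gal80Rexp = clamp3(stats::rnorm(n_nodes, 0, 1.2)),
    heatstrip = expression_instruction()
  )
  # ring for connectivity plus a few random chords
  edges <- tibble::tibble(
    source = ids,
    target = ids[c(seq_len(n_nodes)[-1L], 1L)],
    interaction = "pp"
  )
  if (n_nodes > 3L) {
    extra <- max(1L, n_nodes %/% 4L)
    src <- sample(ids, extra, replace = TRUE)
    tgt <- sample(ids, extra, replace = TRUE)
    keep <- src != tgt
    if (any(keep)) {
      edges <- dplyr::bind_rows(
        edges,
        tibble::tibble(source = src[keep], target = tgt[keep], interaction = "pp")
      )
    }
  }
  network <- new_network(tibble::tibble(id = ids), edges)
  mapping <- tibble::tibble(column = "heatstrip", slot = 1L)
  list(network = network, table = tab, mapping = mapping)
}
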