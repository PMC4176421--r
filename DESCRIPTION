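Package: nodeglyphs
Title: Data-Driven Chart Glyphs on Network Nodes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Draws data-driven charts and gradient paints ("glyphs") on the
    nodes of a biological network and exports the result as scalable SVG.
    Each glyph is specified by a compact instruction string of the form
    'type: name=value ...' stored in a node-table column; supported glyph
    types are linear and radial gradients plus bar, circos (ring), heat
    strip, line, pie, and stripe charts. The package parses and validates
    the instruction mini-language, resolves chart values from scalar and
    list-valued node-table columns, generates palettes and color ramps,
    computes chart geometry in a node-local unit frame, composes up to nine
    glyphs per node at positional slots, and renders deterministic vector
    output. Readers for GraphML and SIF networks, delimited node tables,
    and a YAML slot-mapping configuration are included, together with
    seeded generators for demonstration data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    igraph,
    purrr,
    readr,
    rlang,
    stringr,
    tibble,
    withr,
    yaml,
    grDevices,
    stats,
    utils
Suggests:
    ggplot2,
    jsonlite,
    testthat (>= 3.0.0),
    xml2
Config/testthat/edition: 3
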