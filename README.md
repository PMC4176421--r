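# nodeglyphs

Draws data-driven charts and gradient paints ("glyphs") on the nodes of a
biological network and exports the result as scalable vector graphics.

Network views in systems biology routinely need more than one number per
node: expression of a gene across conditions, the composition of a protein
cluster, domain coverage of a sequence. A single node color cannot carry
that, so `nodeglyphs` renders small charts directly on each node, driven by
columns of a node-attribute table. Every glyph is specified by a compact
**instruction string** stored in a table column:

```
type: name1=value1 name2=value2 ...
```

Eight glyph types are registered — two gradient paints (`lingrad`,
`radgrad`) and six charts (`barchart`, `circoschart`, `heatstripchart`,
`linechart`, `piechart`, `stripechart`). Up to nine glyphs can be composed
on one node at positional slots (center plus eight compass points). Output
is deterministic SVG 1.1, so figures scale to any resolution and identical
inputs produce byte-identical files.

## The model in brief

* **Values** come either from a literal `values="v1,...,vn"` list or from
  node-table columns named in `attributelist="col1,...,coln"` (a single
  list-valued column supplies a whole series; for `circoschart` each
  list column is one concentric ring).
* **Scaling.** With `range="min,max"` every node is normalized on the same
  scale. For a range straddling zero the normalization is symmetric,

  `t = v / max(|min|, |max|)`,  so `t ∈ [-1, 1]` and 0 sits on the chart
  baseline; a non-straddling range maps affinely onto [0, 1]. Without
  `range`, each node autoscales to its own extremes.
* **Colors.** `colorlist` accepts palette keywords (`contrasting`,
  `modulated`, `rainbow`, `random`), explicit colors (`#RRGGBB[AA]` or
  X11 names), up/down colors for signed values
  (`up:red,down:blue[,zero:black]`), or — for heat strips — a gradient
  keyword such as `yellowblue`: each bar is filled with a gradient whose
  tip color is the ramp interpolated at `t` (pure yellow at `t = +1`,
  pure blue at `t = -1`).
* **Angles.** Pie and ring charts start at 12 o'clock and advance
  clockwise; extents are proportional to the values and always close to
  360 degrees.

## Worked example

The classic use case: yeast galactose-induction expression values as heat
strips. All rows of a node table carry the instruction

```
heatstripchart: attributelist="gal1RGexp,gal4RGexp,gal80Rexp"
    colorlist="yellowblue" range="-3.0,3.0"
```

```r
library(nodeglyphs)

spec <- parse_instruction(paste(
  'heatstripchart: attributelist="gal1RGexp,gal4RGexp,gal80Rexp"',
  'colorlist="yellowblue" range="-3.0,3.0"'
))
node <- node_record("YBR020W",
  scalars = list(gal1RGexp = -2.43, gal4RGexp = 0.31, gal80Rexp = 1.76))
series <- resolve_series(spec, node)
strips <- heatstrip_layout(series, 0, ramp_for_keyword("yellowblue"),
                           spec$common$range)
dplyr::select(strips, label, value, t, tip_color)
#> # A tibble: 3 × 4
#>   label     value      t tip_color
#>   <chr>     <dbl>  <dbl> <chr>
#> 1 gal1RGexp -2.43 -0.81  #1818E7FF
#> 2 gal4RGexp  0.31  0.103 #8D8D72FF
#> 3 gal80Rexp  1.76  0.587 #CACA35FF
```

Each row is one bar: `t` is the value normalized by the range (−2.43/3 =
−0.81, a strongly repressed gene), and `tip_color` is the ramp color at the
bar tip — deep blue for repression, yellow-ish for induction, gray near
zero. `render_glyph_network()` turns a whole table plus a network and a
slot mapping into one SVG document; `cmd_demo()` writes two complete demo
figures (a gallery with one node per glyph type, and an expression network
of heat strips):

```r
cmd_demo("figures", seed = 1)
```

## Command line

```sh
Rscript scripts/glyphctl.R render --network net.graphml --table nodes.tsv \
    --config config.yaml --out out.svg
Rscript scripts/glyphctl.R validate --table nodes.tsv --column instr
Rscript scripts/glyphctl.R demo --out figures/
```

`validate` lints every instruction in a column and exits non-zero if any
fails; `render` fails on the first bad node unless `--skip-bad-nodes` is
given. The config is YAML: a `mapping` of instruction columns to slots 1-9,
plus optional `canvas`, `node`, and `seed` keys.

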