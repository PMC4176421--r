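---
title: "Rendering data-driven glyphs on network nodes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rendering data-driven glyphs on network nodes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nodeglyphs)
```

## The problem and the model

A network view gives each node one position, one shape, one color. Most
biological questions attach several numbers to a node — expression across
conditions, cluster composition, ring-structured annotations — and those
numbers change from node to node. `nodeglyphs` treats the node as a small
canvas: a **glyph** (a chart or a gradient paint) is computed from that
node's attribute values and drawn over it.

The whole system is driven by plain text. One **instruction string**,

```
type: name1=value1 name2=value2 ...
```

fully specifies one glyph. Keeping the specification textual has a
practical consequence: instructions live in ordinary table columns, can be
generated by other tools, diffed, and validated row by row
(`cmd_validate()`), and a figure is exactly reproducible from its inputs.

The pipeline is staged, and each stage is an exported, testable surface:

1. **Parse** (`parse_instruction()`): tokenize, type-check every argument,
   reject what the prefix does not accept, fill defaults. The result is a
   `glyph_spec`; `serialize_instruction()` emits its canonical form and
   parsing that form reproduces the spec exactly.
2. **Resolve** (`resolve_series()`): look values up in the node record,
   attach labels and one color per value.
3. **Lay out** (`pie_layout()`, `bar_layout()`, ...): pure geometry in the
   node-local unit box.
4. **Compose** (`compose_node()`): scale, offset to one of nine slots,
   translate to the node's canvas position.
5. **Emit** (`render_svg()`): deterministic SVG text.

## Coordinate and angle conventions

All chart geometry is computed in the **unit box**: x and y in [0, 1],
origin top-left, y increasing downward (the SVG convention). Radii are
relative to the box, so 0.5 touches the edge of the node.

Two conventions are fixed here because the instruction language itself
does not pin them down, and stable golden files need a single answer:

* **Angles**: `arcstart = 0` is 12 o'clock and slices advance clockwise.
* **Ring radii**: the `firstarc`, `firstarcwidth`, and `arcwidth`
  proportions of a circos chart are read as fractions of the node
  *diameter* and therefore halved into radius units; rings that would
  extend past radius 0.5 raise an overflow error instead of clipping.

`separation` (bar gap) and `linewidth` carry no natural unit in the
language, so they are interpreted in reference units of a 100×100 node
box and divided by 100; `separation=2` is 2% of the node width.

## Value normalization

`range="min,max"` exists to put every node on the same scale. With a range
straddling zero the package normalizes symmetrically about zero:

\[ t = v / \max(|min|, |max|), \qquad t \in [-1, 1], \]

so zero always lands on the chart baseline and a +2 bar is exactly as tall
as a −2 bar is deep. A non-straddling range maps affinely onto [0, 1].
Values outside the range **clamp** to ±1 with a warning rather than
erroring: one outlier should not kill a figure, but it should be visible
in the log. When `range` is omitted, each node autoscales to its own
series extremes (a flat series falls back to the sign of each value); this
is deliberate — the language implies the argument's purpose is cross-node
consistency, not a requirement. Missing values (NA/NaN) render as
zero-extent elements with a warning, never as errors.

The `ybase` baseline (`top` = 0, `middle` = 0.5, `bottom` = 1, or any
proportion) relocates the zero line only; it does not flip bar direction.

## The color model

Colors are 8-bit RGBA. Named colors resolve through R's X11 color table;
hex accepts `#RRGGBB` and `#RRGGBBAA`, case-insensitive. Components
outside [0, 255] and stop positions outside [0, 1] are always typed
errors, never silent clamps — a palette bug should fail loudly, a data
outlier (previous section) should not.

Interpolation — between gradient stops and along heat-strip ramps — is
**straight linear RGBA**, alpha like any other channel, quantized with
round-half-up. Perceptual spaces (CIELAB) produce prettier midpoints but
the linear rule is the simplest one a reader can verify by hand
(`yellowblue` at `t = 0` is exactly (128, 128, 128)), and anchor colors
are reproduced exactly.

Two palette keywords have no canonical definition anywhere in the
instruction language, so this package fixes its own and documents them:

* `contrasting`: hues stepped by the golden angle (≈137.5°), a
  deterministic, order-free scheme whose consecutive colors are far apart
  on the wheel;
* `modulated`: rainbow hues with saturation and brightness alternating
  between 1.0 and 0.6.

Both are stand-ins for whatever a particular upstream tool might do;
any figure that depends on exact palette colors should use explicit
colors. `random` draws hues from a seeded generator and is reproducible
across runs and platforms for a fixed seed.

Heat-strip ramps place their first color at the positive extreme
(`yellowblue`: yellow = induced, blue = repressed) — a convention, fixed
and stated because the keyword spelling alone does not decide it. The only
three-color keyword, `bluegreenyellow`, pins its middle color at zero. An
`up:/down:/zero:` colorlist on a heat strip becomes a three-anchor ramp
(up at +1, zero at 0, down at −1), so both colorlist forms behave
uniformly. The optional `zero` color of an up/down list defaults to opaque
black.

## Parser policy

* Values may be bare or double-quoted; quoted values may contain spaces
  and `=`. Single quotes are not special.
* Unknown argument names are hard errors: a silent typo (`colourlist`)
  would otherwise produce a wrong figure with no diagnostic.
* Exactly one of `values` / `attributelist` is required for value-driven
  charts; both together is an error.
* `piechart` and `circoschart` reject `range`, `scale`, and `ybase`;
  `stripechart` accepts only `colorlist`, and only with explicit colors —
  a keyword palette has no value count to size itself from.
* Numeric literals are integer or decimal; scientific notation is
  rejected (nothing in a glyph needs it, and `1e3` is more often a typo).
* Prefixes are lowercased before validation.
* Gradient `start`/`end`/`center`/`radius` default to a left-to-right
  axis and a centered half-radius circle; only `stoplist` is mandatory.

`serialize_instruction()` emits arguments in a fixed order, all values
quoted, defaults omitted; it is a fixed point under re-parsing, which is
what the round-trip property suite exercises.

## Composition and output

Each node exposes nine **slots**: slot 1 at the center, slots 2–9 on the
eight compass points (offsets of one node-size in each direction). A
spec's `scale` is applied once, at composition, about the scene center —
layouts themselves always fill the unit box. The tenth glyph on a node is
a typed overflow error. Later slots draw above earlier ones, so a gradient
in slot 1 underpaints charts in higher slots.

SVG output is deterministic by construction: fixed float formatting,
element ids derived from node id and slot, primitives in scene order.
Gradient paints are emitted as `<linearGradient>`/`<radialGradient>` defs
with coordinates relative to the bounding box of the element they fill,
which is what makes heat-strip bar gradients survive composition without
rewriting. Rasterization (`render_raster()`) is a thin convenience over an
external tool and raises a typed capability error when none is installed;
the SVG is the canonical artifact.

Label text is placed above (or below, for downward bars) the bar tip and
at mid-angle/mid-radius for slices; `labelcircles` ring labels sit at ring
mid-radius on the 12 o'clock axis. Exact label anchoring is this package's
own convention, frozen by the golden-file test. Fonts outside a small
safe list get a sans-serif fallback appended and a warning — font
resolution is renderer-dependent and out of scope.

## The fixture generators

`generate_fixture("gallery")` emulates a demonstration dataset: integer
columns `a`–`d`, list-of-real columns `Values`, `Circle1`, `Circle2`, and
one instruction column per glyph type, each populated on exactly one node,
so the demo renders a one-node-per-type gallery. `generate_fixture
("expression")` emulates a galactose-induction-style expression dataset: a
connected network (ring plus chords) whose nodes carry three expression
columns drawn from a seeded normal (sd 1.2, clamped to [−3, 3] — the
spread of a typical log-ratio experiment) and one shared heat-strip
instruction with `range="-3.0,3.0"`.

Both are synthetic. They reproduce the *shape* of real inputs — column
types, list columns, instruction text, connectivity — but not their
statistical structure: no correlation between interacting genes, no
missingness, no annotation noise. Passing tests therefore demonstrate that
parsing, geometry, composition, and emission are correct and
deterministic on realistically-shaped data; they say nothing about
biological interpretability of any particular figure.

Default problem sizes (20-node expression networks, 8-node gallery,
1000-instruction round-trip sweeps, 100–200-case property loops) were
chosen so the full suite exercises every code path in well under a minute
while keeping property coverage broad.

## Known limitations

* Interpolation is not perceptually uniform (by design, above).
* SIF input carries no attributes, so a node table is mandatory with it.
* Node shapes are rectangles and ellipses only; gradient paints fill the
  shape, but chart glyphs are not clipped to it.
* No PDF/EPS export, no edge glyphs, no interactive output.
* `labelcircles` placement and the exact `contrasting`/`modulated`
  palettes are this package's conventions, not portable definitions.
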