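---
title: "Rendering biological matrices as SVG heat maps: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rendering biological matrices as SVG heat maps: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(svgheatmap)
```

## Scope and model

svgheatmap renders a labeled R x C grid of real values as a heat map: each
cell becomes a colored rectangle, a third data dimension expressed as a color
gradient. The package targets two recurring shapes of biological matrix. In an
**expression view**, rows are experimental conditions and columns are the
probes of a gene, annotated with exon and trans-membrane membership. In a
**mutability landscape**, rows are the 20 standard amino acids and columns are
protein positions; cell (a, p) holds the predicted effect of substituting
position p's residue by amino acid a, and the cell where a equals the native
residue is the *wildtype* cell — it has no meaningful score and is drawn in a
reserved color (black).

The cell model therefore carries a per-cell flag alongside each value:
`NONE` (ordinary scored cell), `WILDTYPE`, or `MISSING`. Missingness is a
flag, not a sentinel value, because uploaded CSV matrices routinely contain
`NA` cells and those must survive write/parse round-trips exactly. The
container invariant is strict: a value is `NA` exactly when its flag is
`MISSING`; a wildtype cell stores a placeholder 0 that is never displayed.

## Value-to-color mapping

Diverging schemes are ordered sRGB stops at fractions 0, 0.5, 1 plus special
colors for flagged cells. A value `v` is clamped into the display range
`[min, max]` and mapped to a fraction that is 0 at `min`, 0.5 at `mid`, and 1
at `max`, linearly on each half; the fraction then interpolates per channel
between the bracketing stops.

Numerical choices, all made for exact testability and cross-platform
determinism rather than perceptual optimality:

* interpolation is in plain sRGB channels, not HSL or CIELab — it matches the
  linear-RGB-ramp behavior users of browser plotting toolkits expect, and an
  independent oracle can reproduce it channel-exactly;
* channel rounding is round-half-up (`floor(x + 0.5)`), because R's default
  `round()` is half-to-even and its behavior at .5 boundaries is a perennial
  source of cross-implementation drift;
* colors serialize as lowercase `#rrggbb`.

Defaults where the display range is left automatic: the range is the data
min/max over unflagged cells, symmetrized about 0 when the data spans 0, so
that the scheme's neutral midpoint keeps its meaning ("no effect" /
"unpredictable") rather than landing on an arbitrary value. The automatic
midpoint is 0 for a sign-spanning range and the arithmetic midpoint
otherwise. A constant matrix gets the degenerate range widened by ±0.5 so
rendering never divides by zero. `range_mid` may equal an endpoint; the empty
half then collapses and the other half covers the whole range.

The scale bar is a horizontal strip of 64 equal-width value segments, each
colored by the same map at its segment midpoint, with ticks at the range
minimum, midpoint and maximum — so the bar is definitionally consistent with
the cells and needs no separate color logic.

## Automatic layout and the zoom panel

All geometry is in SVG user units. Text extents are estimated as 0.6 x
font-size per character at font-size 11 — deterministic, and accurate enough
for gutter sizing without rasterizing fonts. The left gutter is sized to the
longest row label; the top gutter holds the column labels (rotated 90° when
cells are narrower than 12 units) plus one 14-unit strip per annotation
track. Cells are `floor(plot / count)` units on each axis, at least 1, and
deliberately non-square: a 20 x 348 landscape is far wider than tall.

The zoom decision compares the *raw* (pre-floor) cell size against
`min_cell_size` with a strict less-than, on the smaller of the two axes. The
default threshold is 5 units: below that, cells are unusable as hover targets
and labels cannot attach. When triggered, a secondary panel with fixed
20-unit cells renders a column window across **all** rows directly below the
main panel, and a blue frame outlines the window on the main panel. The
window is a half-open, 0-based column interval `[s, s + n)`, clamped by
shrinking `n` to at most C and shifting `s` into `[0, C - n]`. There is no
interactive dragging — the window comes from configuration or the command
line — which keeps the artifact scripting-free while preserving the
information the panel conveys.

With an automatic canvas, the width is 1200 units (a deterministic stand-in
for a typical display width) and the height follows from the content: rows at
`max(min_cell_size, 12)` units each, plus gutters, zoom panel, and scale bar.
When the caller fixes the canvas, its height budgets the gutters, main panel
and scale bar; a zoom panel, if triggered, extends the document below that
budget rather than squeezing the main panel further. A canvas too small to
leave a 1 x 1 plot area is an error, not a silent degenerate figure.

## SVG output contract

Documents are SVG 1.1 with a single flat element list and stable id prefixes
(`cell-`, `zoomcell-`, `xlabel-`, `ylabel-`, `zoomxlabel-`, `track-`,
`trackname-`, `scalebar-`, `scalebartick-`, `zoomframe`), which are part of
the public contract so downstream tools can post-process figures. The
serializer is written in the package — attribute order, number formatting
(two decimals with trailing zeros trimmed) and whitespace are pinned, so
identical documents produce byte-identical files on every platform; the test
suite holds golden references against the demo outputs. Tooltips are native
`<title>` children (`"row / col: value"`, with `NA` for missing and
`wildtype` for wildtype cells); values are formatted with `%.6g`. The SVG
y-axis points down and cell (0,0) is top-left, matching the reading order of
a printed matrix. Raster (PNG) export is optional and probes for a
rasterization backend at call time, failing with a clear `NOT_AVAILABLE`
error when none is installed.

## File formats

The CSV dialect is comma-separated, RFC-4180-quoted UTF-8 with the first
row/column as labels (the corner cell is ignored); this is the most common
dialect for matrix uploads, and the CLI's `--sep` flag overrides the
separator. Decimal parsing accepts scientific notation; locale decimal commas
are rejected rather than guessed, because silently reinterpreting `1,5` is
worse than a positioned error. Bad cells report their row and column labels.

The JSON data schema (`rows`, `cols`, `values`, optional `flags` with
uppercase tokens) and configuration schema (`scheme` required; `range`,
`canvas`, `minCellSize`, `zoomStartCol`, `tooltips`, `target` optional,
absent keys meaning "automatic") are declared conventions of this package,
published as JSON-Schema files in `inst/schemas/`. The `target` field is
recorded verbatim for compatibility with embedding workflows and unused in
file output.

## Synthetic fixtures: what they emulate and what they do not

The generators reproduce the *structure* of the two use-cases, not their
science. All randomness flows through R's Mersenne-Twister with inversion
normals under an explicit seed (caller RNG state is saved and restored), so
fixtures are reproducible across platforms.

**Expression fixture** — `n_conditions` x `n_probes` log2-scale values
(default 2 x 8, rows `control`/`case`): per-probe baselines from
Uniform(5, 10), a Normal(0, 1.2) differential shift applied to a subset of
probes so conditions differ visibly, and Normal(0, 0.3) measurement noise.
Columns carry an exon track (round-robin over 5 exons) and a trans-membrane
track (7 regions, with every fourth probe unassigned, since not all probes
fall in a TM region). These sizes mirror the motivating example: the human
rhodopsin gene (RHO, chr3:129,247,482–129,254,187, 6706 bp; coding region
4985 bp) has 8 array probes, 5 exons, and a 7-TM protein of 348 residues.

**Mutability fixture** — 20 rows (amino acids, alphabetical by one-letter
code — a deterministic convention, since no canonical figure ordering is
legible) by L position columns labeled `<residue><position>`. Exactly one
cell per column is flagged `WILDTYPE`; the other 19 draw from
Normal(region_mean, noise_sd) inside configured high-effect regions and
Normal(baseline_mean, noise_sd) elsewhere. Defaults: baseline −1.5, region
+1.5, noise 0.75 on a [−4, 4] display range — values chosen once so that
region and baseline cells are clearly separated (4 noise SDs) yet overlap
enough to look like real predictor output rather than two flat bands. The
default high-effect regions are seven evenly spaced helical segments over the
central 16–88% of the sequence, echoing the seven-trans-membrane architecture
where high-effect positions concentrate; the accompanying track marks them as
helices (`H`, red). What the fixture does *not* emulate: any actual
effect-prediction method, residue-specific substitution biases, correlation
between neighboring positions, or binding-site hotspots. Passing tests
therefore demonstrate the rendering pipeline and its contracts on
realistically shaped data — they say nothing about the accuracy of any
predictor.

The demo landscape uses L = 60 (a 20 x 1200-cell document) rather than a
full-length 348-residue protein; that length exercises every code path —
narrow rotated labels, wildtype diagonal, track, scale bar — while keeping
golden-reference tests fast and reviewable. Tests that check statistical
properties of the generator use L = 200 with a single [50, 150] region,
where each group mean carries a sampling error of about 0.5/sqrt(1900), two
orders of magnitude below the 3-unit separation being asserted.

## Design choices at genuinely open points

* **Missing values are supported end to end** even though a display component
  could refuse them: real CSV uploads contain `NA`, and a first-class flag
  with a reserved grey is safer than any numeric encoding.
* **The zoom threshold checks both axes** (`min` of raw width and height);
  checking only width would let rows collapse to invisibility on tall
  matrices.
* **Zoom cell size is fixed at 20 units** and the window spans all rows — a
  column window is what a sequence-positional zoom needs, and a fixed
  magnified size keeps the panel legible regardless of how extreme the main
  panel's compression is.
* **Flag precedence in the CLI** is command line > config file > defaults,
  the standard expectation; the JSON config object maps to the middle tier.
* **Genomic coordinates are 1-based inclusive**, the genome-browser display
  convention, so printed spans like 6706 bp reproduce exactly as
  `end - start + 1`.

## Limitations

* No hierarchical clustering or dendrograms; rows and columns render in the
  order given.
* No interactive behavior beyond hover tooltips: no drag, no animation, no
  event hooks. The zoom window is static per render.
* Label metrics are estimates; unusually wide glyphs can overhang gutters
  slightly.
* sRGB interpolation is not perceptually uniform and the built-in schemes are
  not colorblind-safe; both schemes follow entrenched conventions of their
  respective communities.
* Matrices are dense and in-memory; this is a figure renderer, not a
  streaming visualization server.
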