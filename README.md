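# svgheatmap

Biological data frequently arrive as labeled matrices: microarray probes by
experimental conditions, or — in a protein *mutability landscape* — sequence
positions by the 19 non-native amino acids each position can mutate into.
Reading such matrices directly is hopeless; a heat map replaces the third
dimension with a color gradient and makes high- and low-value regions visible
at a glance. **svgheatmap** turns labeled numeric matrices into
self-contained, publication-quality SVG heat maps, for bench scientists and
bioinformaticians who want a figure (or a scriptable figure pipeline) rather
than an interactive web stack.

Features:

* a validated matrix container with per-cell flags — `WILDTYPE` cells (where
  the substituted residue equals the native one) are drawn black and carry no
  score; `MISSING` cells survive round-trips as first-class missing values;
* CSV and JSON readers/writers for matrices and display configurations
  (JSON-Schema files under `inst/schemas/`);
* diverging color schemes (`blue-white-red` for effect scores,
  `green-black-red` for expression) with an exactly specified value→color map
  and a horizontal scale bar;
* fully automatic layout: label gutters, per-track annotation strips (exons,
  trans-membrane regions, secondary structure), and a **zoom panel** that is
  added automatically whenever cells would be smaller than a minimum legible
  size, magnifying a configurable column window below the main panel;
* native SVG tooltips (`<title>` elements) on every cell — hover works in any
  browser with no scripting;
* deterministic, byte-stable output: the same input always serializes to the
  same bytes;
* seeded fixture generators for the two demonstration use-cases and a
  command-line interface.

## The value→color map

For a display range `[min, max]` with midpoint `mid` (by default 0 when the
range spans zero), a value `v` is clamped into the range and mapped to a
fraction

```
f(v) = 0.5 * (v - min) / (mid - min)          for v <= mid
f(v) = 0.5 + 0.5 * (v - mid) / (max - mid)    for v >  mid
```

so `f` is 0 at `min`, 0.5 at `mid`, 1 at `max`, piecewise-linear on each
half. The color is then a per-channel linear interpolation between the
scheme's sRGB stops at `f`, rounded half-up — e.g. halfway between dark blue
`#00008b` and white on the lower half gives `#8080c5`. Flagged cells bypass
the map entirely: wildtype → black, missing → grey.

The zoom panel triggers on a strict comparison: if the raw (pre-rounding)
cell size `min(plot_w / C, plot_h / R)` is smaller than `min_cell_size`
(default 5 SVG user units), a secondary panel with fixed 20-unit cells is
rendered directly below the main heat map, showing all rows of a clamped
column window, which is outlined on the main panel by a blue frame.

## Worked example

```r
library(svgheatmap)

csv <- system.file("extdata", "rho_probes_synthetic.csv", package = "svgheatmap")
m <- read_matrix_csv(csv)
m
#> <heat_matrix> 2 x 8
#>   rows: control, case
#>   cols: probe1, probe2, probe3, probe4, probe5, probe6 ...

doc <- render_heatmap(m, render_config(scheme_name = "green-black-red"))
doc
#> <svg_document> 1200 x 86, 93 top-level elements
write_svg(doc, "expression.svg")
```

The 2 x 8 matrix is a synthetic probe-level expression table (log2 scale,
control vs case rows). The rendered document holds one `cell-<row>-<col>`
rectangle per cell (16 of the 93 elements), axis labels, and a 64-segment
scale bar; opening `expression.svg` in a browser shows the tooltip
`control / probe1: 6.323` on hover. Two spot checks of the machinery:

```r
value_to_color(-1, "NONE", get_scheme("blue-white-red"), -2, 0, 2)
#> [1] "#8080c5"
interval_length(genomic_interval("chr3", 129247482, 129254187))
#> [1] 6706
```

The first is the halfway color between dark blue and white; the second is the
span of the human rhodopsin (RHO) gene, whose probes and mutability landscape
the demo fixtures emulate.

## Command line

```sh
Rscript inst/cli/heatmapviewer.R render --in matrix.csv --out fig.svg \
    --scheme blue-white-red --range -4:4 --min-cell 6 --zoom-start 40
Rscript inst/cli/heatmapviewer.R demo mutability --out landscape.svg --seed 1
```

`render` reads a labeled CSV (first row = column labels, first column = row
labels, `NA`/empty = missing) plus an optional `--config file.json`; inline
flags beat config-file values beat built-in defaults. `demo expression` and
`demo mutability` run the built-in fixtures end to end. Exit codes: 0
success, 1 invalid input, 2 usage error; diagnostics go to standard error.

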