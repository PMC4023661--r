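#' Flag values for heat-map cells
#'
#' A cell is either an ordinary valued cell (`"NONE"`), the wildtype residue of
#' its column in a mutability landscape (`"WILDTYPE"`, drawn in the scheme's
#' special wildtype color and carrying no displayed value), or missing
#' (`"MISSING"`, e.g. an `NA` cell in an uploaded CSV).
#'
#' @format Character vector of the three flag tokens.
#' @export
HM_FLAGS <- c("NONE", "WILDTYPE", "MISSING")

#' Construct a labeled heat-map matrix
#'
#' The central container: an R x C grid of real values with row and column
#' labels and a parallel grid of per-cell flags. Missingness is a first-class
#' flag rather than a sentinel number, so `NA` cells survive CSV/JSON
#' round-trips unambiguously. Row 1 is drawn as the TOP row; column 1 is
#' leftmost.
#'
#' @param values numeric matrix (R x C); `NA` entries are taken as missing
#'   unless `flags` says otherwise.
#' @param row_labels character vector, length R.
#' @param col_labels character vector, length C.
#' @param flags character matrix (R x C) over `"NONE"`, `"WILDTYPE"`,
#'   `"MISSING"`, or `NULL` to derive flags from `is.na(values)`.
#' @return A validated `heat_matrix` object.
#' @examples
#' m <- heat_matrix(matrix(1:4, 2, 2), c("r1", "r2"), c("c1", "c2"))
#' dim(m$values)
#' @export
heat_matrix <- function(values, row_labels, col_labels, flags = NULL) {
  if (is.list(values) && !is.matrix(values)) {
    lens <- lengths(values)
    if (length(unique(lens)) > 1L)
      hm_abort("RAGGED_MATRIX",
               sprintf("rows have unequal lengths (%s)",
                       paste(lens, collapse = ", ")))
    values <- do.call(rbind, lapply(values, as.numeric))
  }
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(flags)) {
    flags <- matrix(ifelse(is.na(values), "MISSING", "NONE"), nrow(values))
  }
  m <- structure(
    list(values = unname(values),
         row_labels = as.character(row_labels),
         col_labels = as.character(col_labels),
         flags = unname(as.matrix(flags))),
    class = "heat_matrix"
  )
  validate_matrix(m)
}

#' Validate a heat-map matrix
#'
#' Checks the container invariants: a rectangular grid with at least one row
#' and column, label vectors matching each dimension, a flags grid of the same
#' shape over the three flag tokens, and the rule that a value is `NA` exactly
#' when its flag is `"MISSING"`. Returns its input unchanged on success
#' (idempotent), and raises a classed error naming the violated invariant
#' otherwise.
#'
#' @param m a `heat_matrix`.
#' @return `m`, unchanged.
#' @export
validate_matrix <- function(m) {
  if (!inherits(m, "heat_matrix"))
    hm_abort("FLAG_SHAPE", "not a heat_matrix object")
  v <- m$values
  if (!is.matrix(v) || nrow(v) < 1L || ncol(v) < 1L)
    hm_abort("RAGGED_MATRIX", "values must form an R x C grid with R, C >= 1")
  if (length(m$row_labels) != nrow(v))
    hm_abort("LABEL_MISMATCH",
             sprintf("%d row labels for %d rows", length(m$row_labels), nrow(v)))
  if (length(m$col_labels) != ncol(v))
    hm_abort("LABEL_MISMATCH",
             sprintf("%d column labels for %d columns",
                     length(m$col_labels), ncol(v)))
  f <- m$flags
  if (!is.matrix(f) || !identical(dim(f), dim(v)))
    hm_abort("FLAG_SHAPE", "flags grid shape differs from values grid shape")
  if (!all(f %in% HM_FLAGS))
    hm_abort("FLAG_SHAPE",
             sprintf("unknown flag token(s): %s",
                     paste(unique(f[!f %in% HM_FLAGS]), collapse = ", ")))
  miss <- f == "MISSING"
  if (any(is.na(v) != miss))
    hm_abort("FLAG_SHAPE",
             "values must be NA exactly where flags == 'MISSING'")
  m
}

#' @export
print.heat_matrix <- function(x, ...) {
  cat(sprintf("<heat_matrix> %d x %d", nrow(x$values), ncol(x$values)), "\n")
  cat("  rows:", paste(utils::head(x$row_labels, 6), collapse = ", "),
      if (length(x$row_labels) > 6) "..." else "", "\n")
  cat("  cols:", paste(utils::head(x$col_labels, 6), collapse = ", "),
      if (length(x$col_labels) > 6) "..." else "", "\n")
  nw <- sum(x$flags == "WILDTYPE"); nm <- sum(x$flags == "MISSING")
  if (nw + nm > 0) cat(sprintf("  flags: %d wildtype, %d missing\n", nw, nm))
  invisible(x)
}

#' Dimensions of a heat matrix
#' @param x a `heat_matrix`.
#' @export
dim.heat_matrix <- function(x) dim(x$values)

#' Is a configuration field set to automatic?
#'
#' Automatic ("compute it from the data / layout") is represented as `NA` in a
#' [render_config()].
#' @param x a scalar config field.
#' @return `TRUE` if the field is unset/automatic.
#' @export
is_auto <- function(x) is.null(x) || (length(x) == 1L && is.na(x))

#' Rendering configuration
#'
#' The display directions for a heat map: the value range to show (with an
#' optional midpoint for diverging schemes), the color scheme, the canvas size
#' in SVG user units, the minimum legible cell size that triggers the zoom
#' panel, the zoom window's first column, tooltips on/off, and annotation
#' tracks. Any field left `NA` (`AUTO`) is computed automatically at render
#' time, mirroring the component's automatic canvas/cell sizing.
#'
#' @param range_min,range_max displayed value range; `NA` = derive from data
#'   (symmetrized about 0 when the data spans 0).
#' @param range_mid midpoint value mapped to the scheme's central stop; `NA` =
#'   0 when the range spans 0, else the arithmetic midpoint.
#' @param scheme_name name of a built-in scheme, see [get_scheme()].
#' @param canvas_w,canvas_h canvas size in SVG user units; `NA` = automatic.
#' @param min_cell_size threshold (user units): when the raw cell size falls
#'   strictly below it, a zoom panel is added; `NA` = default 5.
#' @param zoom_start_col first (0-based) column of the zoom window; `NA` = 0.
#' @param tooltips attach a `<title>` tooltip to every cell?
#' @param tracks list of [track()] annotation strips.
#' @param target verbatim target element identifier; recorded but unused in
#'   file output.
#' @return A `render_config` object.
#' @export
render_config <- function(range_min = NA_real_, range_max = NA_real_,
                          range_mid = NA_real_,
                          scheme_name = "blue-white-red",
                          canvas_w = NA_real_, canvas_h = NA_real_,
                          min_cell_size = NA_real_,
                          zoom_start_col = NA_real_,
                          tooltips = TRUE, tracks = list(),
                          target = NA_character_) {
  cfg <- structure(
    list(range_min = as.numeric(range_min), range_max = as.numeric(range_max),
         range_mid = as.numeric(range_mid),
         scheme_name = as.character(scheme_name),
         canvas_w = as.numeric(canvas_w), canvas_h = as.numeric(canvas_h),
         min_cell_size = as.numeric(min_cell_size),
         zoom_start_col = as.numeric(zoom_start_col),
         tooltips = isTRUE(tooltips), tracks = tracks,
         target = target),
    class = "render_config"
  )
  validate_config(cfg)
}

validate_config <- function(cfg) {
  if (!is_auto(cfg$range_min) && !is_auto(cfg$range_max) &&
      cfg$range_min >= cfg$range_max)
    hm_abort("RANGE_ERROR",
             sprintf("range_min (%g) must be < range_max (%g)",
                     cfg$range_min, cfg$range_max))
  if (!is_auto(cfg$range_mid) && !is_auto(cfg$range_min) &&
      !is_auto(cfg$range_max) &&
      (cfg$range_mid < cfg$range_min || cfg$range_mid > cfg$range_max))
    hm_abort("RANGE_ERROR", "range_mid must lie within [range_min, range_max]")
  for (fld in c("canvas_w", "canvas_h", "min_cell_size")) {
    x <- cfg[[fld]]
    if (!is_auto(x) && x <= 0)
      hm_abort("RANGE_ERROR", sprintf("%s must be positive", fld))
  }
  if (!is_auto(cfg$zoom_start_col) && cfg$zoom_start_col < 0)
    hm_abort("RANGE_ERROR", "zoom_start_col must be >= 0")
  for (tr in cfg$tracks) {
    if (!inherits(tr, "hm_track"))
      hm_abort("SCHEMA_ERROR", "tracks must be a list of track() objects")
  }
  cfg
}

#' Categorical annotation track
#'
#' A one-row strip aligned to the matrix columns, e.g. exon membership,
#' trans-membrane region, or secondary structure (helices in red, beta strands
#' in blue). Each non-`NA` category must have a palette color.
#'
#' @param name track name, drawn left of the strip.
#' @param categories character vector, one per matrix column (`NA` = no
#'   annotation for that column).
#' @param palette named character vector mapping category to `#rrggbb` color.
#' @return An `hm_track` object.
#' @examples
#' track("SecStr", c("H", "H", NA, "E"), c(H = "#ff0000", E = "#0000ff"))
#' @export
track <- function(name, categories, palette) {
  categories <- as.character(categories)
  palette <- unlist(palette)
  seen <- unique(categories[!is.na(categories)])
  missing_pal <- setdiff(seen, names(palette))
  if (length(missing_pal))
    hm_abort("SCHEMA_ERROR",
             sprintf("track '%s': no palette color for category %s",
                     name, paste(missing_pal, collapse = ", ")))
  structure(list(name = as.character(name), categories = categories,
                 palette = palette),
            class = "hm_track")
}

#' Genomic interval (1-based, inclusive)
#'
#' Coordinates follow the genome-browser display convention: both endpoints
#' are counted, so the span of chr3:129,247,482-129,254,187 (the human RHO
#' gene) is 6706 bp.
#'
#' @param chrom chromosome name.
#' @param start,end positive integer endpoints, `start <= end`.
#' @return A `genomic_interval` object.
#' @export
genomic_interval <- function(chrom, start, end) {
  start <- as.numeric(start); end <- as.numeric(end)
  if (is.na(start) || is.na(end) || start < 1 || end < 1)
    hm_abort("RANGE_ERROR", "interval endpoints must be positive integers")
  if (start > end)
    hm_abort("RANGE_ERROR",
             sprintf("interval start (%s) exceeds end (%s)", start, end))
  structure(list(chrom = as.character(chrom), start = start, end = end),
            class = "genomic_interval")
}

#' Length of a genomic interval
#'
#' `end - start + 1` under the 1-based inclusive convention.
#'
#' @param iv a [genomic_interval()].
#' @return Positive integer length in base pairs.
#' @examples
#' interval_length(genomic_interval("chr3", 129247482, 129254187)) # 6706
#' @export
interval_length <- function(iv) {
  stopifnot(inherits(iv, "genomic_interval"))
  iv$end - iv$start + 1
}
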