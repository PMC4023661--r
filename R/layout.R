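# Automatic geometry. All sizes are SVG user units. Text extents are
# estimated as 0.6 x font-size per character (font-size 11), which keeps the
# layout deterministic without font rasterization.

FONT_SIZE <- 11
CHAR_W <- 0.6 * FONT_SIZE
TRACK_H <- 14L
LABEL_PAD <- 4L
PANEL_GAP <- 10L
ZOOM_CELL <- 20L
ROTATE_BELOW <- 12      # column labels rotate 90 degrees when cell_w < this
SCALEBAR_H <- 14L
SCALEBAR_AREA <- 44L    # gap + bar + tick labels
DEFAULT_MIN_CELL <- 5
AUTO_CANVAS_W <- 1200L

label_extent <- function(labels) {
  if (length(labels) == 0L) return(0L)
  as.integer(ceiling(max(nchar(labels)) * CHAR_W))
}

#' Clamp a zoom window into the matrix columns
#'
#' Shifts and shrinks a requested `(start_col, n_cols)` column window (0-based
#' start) so that it lies within a matrix of `C` columns; in-range input is
#' returned unchanged. This is the static analogue of dragging the zoom frame
#' along the main heat map.
#'
#' @param start_col requested first column, 0-based.
#' @param n_cols requested window width in columns, at least 1.
#' @param C number of matrix columns.
#' @return List with elements `start` and `n`.
#' @examples
#' clamp_zoom_region(95, 10, 100) # start shifts to 90
#' @export
clamp_zoom_region <- function(start_col, n_cols, C) {
  stopifnot(n_cols >= 1, C >= 1)
  n <- min(n_cols, C)
  s <- max(0L, min(as.integer(start_col), as.integer(C - n)))
  list(start = s, n = as.integer(n))
}

#' Compute the heat-map layout
#'
#' Resolves gutters, cell sizes, panel rectangles and the zoom-panel decision.
#' The left gutter is sized to the longest row label, the top gutter to the
#' column labels (rotated when cells are narrow) plus one 14-unit strip per
#' annotation track. Cells are `floor(plot / count)` units, at least 1. When
#' the raw (pre-floor) cell size falls strictly below `min_cell_size`
#' (default 5), a zoom panel with fixed 20-unit cells is placed directly below
#' the main panel, showing a column window across all rows; the scale bar sits
#' below everything.
#'
#' @param n_rows,n_cols matrix dimensions, at least 1 each.
#' @param config a [render_config()]; `canvas_w`/`canvas_h` of `NA` trigger
#'   automatic sizing (width 1200; height from the row count at
#'   `max(min_cell_size, 12)` units per row plus panels).
#' @param n_tracks number of annotation tracks (defaults to
#'   `length(config$tracks)`).
#' @param row_labels,col_labels labels used only for gutter sizing; sensible
#'   placeholders are generated when omitted.
#' @return An `hm_layout` list: canvas size, `main_panel` rectangle
#'   (`x`,`y`,`w`,`h`), `cell_w`/`cell_h`, `zoom_needed`, `zoom_panel`,
#'   `zoom_cell`, `zoom_start_col`/`zoom_n_cols`, gutters, `scalebar_rect`,
#'   `track_rects`, and `rotate_col_labels`.
#' @export
compute_layout <- function(n_rows, n_cols, config = render_config(),
                           n_tracks = length(config$tracks),
                           row_labels = NULL, col_labels = NULL) {
  stopifnot(n_rows >= 1, n_cols >= 1)
  if (is.null(row_labels)) row_labels <- paste0("r", seq_len(n_rows))
  if (is.null(col_labels)) col_labels <- paste0("c", seq_len(n_cols))
  min_cell <- if (is_auto(config$min_cell_size)) DEFAULT_MIN_CELL
              else config$min_cell_size

  gutter_left <- label_extent(row_labels) + 2L * LABEL_PAD
  canvas_w <- if (is_auto(config$canvas_w)) AUTO_CANVAS_W
              else as.integer(config$canvas_w)
  plot_w <- canvas_w - gutter_left
  if (plot_w < 1)
    hm_abort("CANVAS_TOO_SMALL",
             sprintf("canvas width %d leaves no room after a %d-unit label gutter",
                     canvas_w, gutter_left))

  cell_w_raw <- plot_w / n_cols
  cell_w <- max(1L, as.integer(floor(cell_w_raw)))
  rotate <- cell_w < ROTATE_BELOW
  col_label_block <- if (rotate) label_extent(col_labels) + LABEL_PAD
                     else as.integer(FONT_SIZE + LABEL_PAD)
  gutter_top <- col_label_block + n_tracks * TRACK_H + LABEL_PAD

  if (is_auto(config$canvas_h)) {
    cell_h_raw <- max(min_cell, 12)
    plot_h <- n_rows * cell_h_raw
  } else {
    plot_h <- as.integer(config$canvas_h) - gutter_top - SCALEBAR_AREA
    if (plot_h < 1)
      hm_abort("CANVAS_TOO_SMALL",
               sprintf("canvas height leaves a %d-unit plot area after gutters",
                       plot_h))
    cell_h_raw <- plot_h / n_rows
  }
  cell_h <- max(1L, as.integer(floor(cell_h_raw)))

  zoom_needed <- min(cell_w_raw, cell_h_raw) < min_cell

  main <- list(x = gutter_left, y = gutter_top,
               w = cell_w * n_cols, h = cell_h * n_rows)
  track_rects <- lapply(seq_len(n_tracks), function(t) {
    list(x = gutter_left,
         y = gutter_top - (n_tracks - t + 1L) * TRACK_H,
         w = main$w, h = TRACK_H)
  })

  zoom_panel <- NULL
  zoom_start <- 0L
  zoom_n <- 0L
  bottom <- main$y + main$h
  if (zoom_needed) {
    zoom_n <- min(n_cols, as.integer(floor(plot_w / ZOOM_CELL)))
    zoom_n <- max(1L, zoom_n)
    want_start <- if (is_auto(config$zoom_start_col)) 0L
                  else as.integer(config$zoom_start_col)
    zr <- clamp_zoom_region(want_start, zoom_n, n_cols)
    zoom_start <- zr$start; zoom_n <- zr$n
    zoom_label_block <- as.integer(FONT_SIZE + LABEL_PAD)
    zoom_panel <- list(x = gutter_left,
                       y = bottom + PANEL_GAP + zoom_label_block,
                       w = ZOOM_CELL * zoom_n, h = ZOOM_CELL * n_rows)
    bottom <- zoom_panel$y + zoom_panel$h
  }

  scalebar_rect <- list(x = gutter_left, y = bottom + PANEL_GAP,
                        w = max(100L, min(main$w, 300L)), h = SCALEBAR_H)
  canvas_h <- scalebar_rect$y + SCALEBAR_H + FONT_SIZE + 2L * LABEL_PAD

  structure(
    list(canvas_w = canvas_w, canvas_h = as.integer(canvas_h),
         main_panel = main, cell_w = cell_w, cell_h = cell_h,
         cell_w_raw = cell_w_raw, cell_h_raw = cell_h_raw,
         zoom_needed = zoom_needed, zoom_panel = zoom_panel,
         zoom_cell = ZOOM_CELL, zoom_start_col = zoom_start,
         zoom_n_cols = zoom_n,
         label_gutter_left = gutter_left, label_gutter_top = gutter_top,
         rotate_col_labels = rotate, min_cell_size = min_cell,
         scalebar_rect = scalebar_rect, track_rects = track_rects,
         n_rows = as.integer(n_rows), n_cols = as.integer(n_cols)),
    class = "hm_layout"
  )
}
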