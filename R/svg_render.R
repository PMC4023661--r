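# SVG document model and renderer. Elements are plain lists (tag, attrs,
# children, text); serialization is a hand-rolled writer so that attribute
# order, number formatting and whitespace are fully under our control and the
# byte output is stable across runs and platforms.
#
# Public element id prefixes (part of the package contract, usable by
# downstream SVG post-processors):
#   cell-<i>-<j>       main-panel cell rectangles (0-based row/col)
#   zoomcell-<i>-<j>   zoom-panel cell rectangles (j = absolute column)
#   xlabel-<j>, ylabel-<i>, zoomxlabel-<j>   axis labels
#   track-<t>-<j>, trackname-<t>            annotation track swatches/names
#   scalebar-<k>, scalebartick-<k>          scale-bar swatches and ticks
#   zoomframe                                the zoom-window frame

svg_node <- function(tag, attrs = list(), children = list(), text = NULL) {
  list(tag = tag, attrs = attrs, children = children, text = text)
}

svg_document <- function(width, height, elements) {
  structure(list(width = as.integer(width), height = as.integer(height),
                 elements = elements),
            class = "svg_document")
}

#' @export
print.svg_document <- function(x, ...) {
  cat(sprintf("<svg_document> %d x %d, %d top-level elements\n",
              x$width, x$height, length(x$elements)))
  invisible(x)
}

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  gsub('"', "&quot;", x, fixed = TRUE)
}

# trim trailing zeros so coordinates like 10 and 10.5 serialize compactly
fmt_coord <- function(x) {
  s <- sprintf("%.2f", x)
  s <- sub("0+$", "", s)
  sub("\\.$", "", s)
}

serialize_node <- function(node, indent = "  ") {
  at <- node$attrs
  attr_str <- if (length(at))
    paste0(" ", paste(sprintf('%s="%s"', names(at),
                              xml_escape(as.character(unlist(at)))),
                      collapse = " "))
  else ""
  open <- paste0(indent, "<", node$tag, attr_str)
  if (is.null(node$text) && length(node$children) == 0L)
    return(paste0(open, "/>"))
  if (length(node$children) == 0L)
    return(paste0(open, ">", xml_escape(node$text), "</", node$tag, ">"))
  kids <- vapply(node$children, serialize_node, character(1),
                 indent = paste0(indent, "  "))
  paste0(open, ">",
         if (!is.null(node$text)) xml_escape(node$text) else "",
         "\n", paste(kids, collapse = "\n"),
         "\n", indent, "</", node$tag, ">")
}

#' Serialize an SVG document to text
#' @param doc an `svg_document` from [render_heatmap()].
#' @return A single UTF-8 string of well-formed SVG 1.1 XML.
#' @export
svg_string <- function(doc) {
  stopifnot(inherits(doc, "svg_document"))
  body <- vapply(doc$elements, serialize_node, character(1))
  paste0(
    '<?xml version="1.0" encoding="UTF-8"?>\n',
    sprintf(paste0('<svg xmlns="http://www.w3.org/2000/svg" version="1.1" ',
                   'width="%d" height="%d" viewBox="0 0 %d %d" ',
                   'font-family="sans-serif" font-size="%d">\n'),
            doc$width, doc$height, doc$width, doc$height, FONT_SIZE),
    if (length(body)) paste0(paste(body, collapse = "\n"), "\n") else "",
    "</svg>\n"
  )
}

#' Write an SVG document to a file or connection
#'
#' Output is UTF-8 XML with byte-for-byte deterministic serialization:
#' rendering the same document twice produces identical files.
#'
#' @param doc an `svg_document`.
#' @param sink file path or writable binary connection.
#' @return `doc`, invisibly.
#' @export
write_svg <- function(doc, sink) {
  text <- svg_string(doc)
  con <- if (inherits(sink, "connection")) sink
         else tryCatch(file(sink, open = "wb"),
                       error = function(e)
                         hm_abort("IO_ERROR",
                                  sprintf("cannot open '%s': %s", sink,
                                          conditionMessage(e))))
  if (!inherits(sink, "connection")) on.exit(close(con))
  writeBin(charToRaw(enc2utf8(text)), con)
  invisible(doc)
}

tooltip_text <- function(row_label, col_label, value, flag) {
  shown <- if (flag == "WILDTYPE") "wildtype"
           else if (flag == "MISSING") "NA"
           else sprintf("%.6g", value)
  sprintf("%s / %s: %s", row_label, col_label, shown)
}

cell_rect <- function(id, x, y, w, h, fill, tooltip = NULL) {
  kids <- if (!is.null(tooltip)) list(svg_node("title", text = tooltip))
          else list()
  svg_node("rect",
           list(id = id, x = fmt_coord(x), y = fmt_coord(y),
                width = fmt_coord(w), height = fmt_coord(h), fill = fill),
           children = kids)
}

text_node <- function(id, x, y, text, anchor = "middle", rotate = FALSE) {
  at <- list(id = id, x = fmt_coord(x), y = fmt_coord(y),
             `text-anchor` = anchor)
  if (rotate)
    at$transform <- sprintf("rotate(-90 %s %s)", fmt_coord(x), fmt_coord(y))
  svg_node("text", at, text = text)
}

render_panel_cells <- function(m, cols_idx, x0, y0, cw, ch, colors,
                               id_prefix, tooltips) {
  nodes <- list()
  R <- nrow(m$values)
  for (i in seq_len(R)) {
    for (k in seq_along(cols_idx)) {
      j <- cols_idx[k]
      tip <- if (tooltips)
        tooltip_text(m$row_labels[i], m$col_labels[j],
                     m$values[i, j], m$flags[i, j])
      nodes[[length(nodes) + 1L]] <- cell_rect(
        sprintf("%s-%d-%d", id_prefix, i - 1L, j - 1L),
        x0 + (k - 1L) * cw, y0 + (i - 1L) * ch, cw, ch,
        colors[i, j], tip)
    }
  }
  nodes
}

#' Render a heat map to an SVG document
#'
#' The full pipeline: resolves the display range and scheme, computes the
#' [compute_layout()] geometry, and emits one filled rectangle per cell
#' (wildtype cells in the scheme's special black, missing cells in grey),
#' row/column labels (column labels rotate 90 degrees when cells are narrower
#' than 12 units), one colored strip per annotation track above the matrix, a
#' zoom frame plus magnified zoom panel below the main panel when cells fall
#' below the minimum legible size, and a horizontal scale bar with tick
#' values. With `config$tooltips`, every cell carries a `<title>` child
#' (`"row / col: value"`) that browsers show on hover without scripting.
#'
#' @param m a valid [heat_matrix()].
#' @param config a [render_config()].
#' @return An `svg_document`; serialize with [write_svg()] or [svg_string()].
#' @examples
#' m <- heat_matrix(matrix(c(-1, 0, 1, 2), 2), c("a", "b"), c("x", "y"))
#' doc <- render_heatmap(m, render_config(scheme_name = "blue-white-red"))
#' substr(svg_string(doc), 1, 54)
#' @export
render_heatmap <- function(m, config = render_config()) {
  validate_matrix(m)
  validate_config(config)
  scheme <- get_scheme(config$scheme_name)
  rng <- resolve_range(m, config)
  R <- nrow(m$values); C <- ncol(m$values)
  if (!is_auto(config$zoom_start_col) && config$zoom_start_col >= C)
    hm_abort("RANGE_ERROR",
             sprintf("zoom_start_col %d is beyond the last column (%d)",
                     as.integer(config$zoom_start_col), C - 1L))
  for (tr in config$tracks)
    if (length(tr$categories) != C)
      hm_abort("LABEL_MISMATCH",
               sprintf("track '%s' has %d categories for %d columns",
                       tr$name, length(tr$categories), C))
  lay <- compute_layout(R, C, config, length(config$tracks),
                        m$row_labels, m$col_labels)

  colors <- matrix("", R, C)
  for (i in seq_len(R)) for (j in seq_len(C))
    colors[i, j] <- value_to_color(m$values[i, j], m$flags[i, j], scheme,
                                   rng$min, rng$mid, rng$max)

  els <- list()
  add <- function(x) els[[length(els) + 1L]] <<- x

  # column labels above the top row (or above the tracks when present)
  label_y <- if (length(lay$track_rects)) lay$track_rects[[1L]]$y - LABEL_PAD
             else lay$main_panel$y - LABEL_PAD
  for (j in seq_len(C)) {
    x <- lay$main_panel$x + (j - 0.5) * lay$cell_w
    add(text_node(sprintf("xlabel-%d", j - 1L),
                  x + if (lay$rotate_col_labels) FONT_SIZE * 0.35 else 0,
                  label_y, m$col_labels[j],
                  anchor = if (lay$rotate_col_labels) "start" else "middle",
                  rotate = lay$rotate_col_labels))
  }
  # row labels left of the first column
  for (i in seq_len(R)) {
    add(text_node(sprintf("ylabel-%d", i - 1L),
                  lay$main_panel$x - LABEL_PAD,
                  lay$main_panel$y + (i - 0.5) * lay$cell_h + FONT_SIZE * 0.35,
                  m$row_labels[i], anchor = "end"))
  }
  # annotation tracks
  for (t in seq_along(config$tracks)) {
    tr <- config$tracks[[t]]
    rect <- lay$track_rects[[t]]
    add(text_node(sprintf("trackname-%d", t - 1L),
                  rect$x - LABEL_PAD, rect$y + rect$h / 2 + FONT_SIZE * 0.35,
                  tr$name, anchor = "end"))
    for (j in seq_len(C)) {
      cat_j <- tr$categories[j]
      if (is.na(cat_j)) next
      add(cell_rect(sprintf("track-%d-%d", t - 1L, j - 1L),
                    rect$x + (j - 1L) * lay$cell_w, rect$y + 1L,
                    lay$cell_w, rect$h - 2L,
                    tolower(tr$palette[[cat_j]]),
                    if (config$tooltips)
                      sprintf("%s / %s: %s", tr$name, m$col_labels[j], cat_j)))
    }
  }
  # main-panel cells
  for (nd in render_panel_cells(m, seq_len(C), lay$main_panel$x,
                                lay$main_panel$y, lay$cell_w, lay$cell_h,
                                colors, "cell", config$tooltips))
    add(nd)

  # zoom frame + zoom panel
  if (lay$zoom_needed) {
    zs <- lay$zoom_start_col; zn <- lay$zoom_n_cols
    add(svg_node("rect", list(
      id = "zoomframe",
      x = fmt_coord(lay$main_panel$x + zs * lay$cell_w),
      y = fmt_coord(lay$main_panel$y),
      width = fmt_coord(zn * lay$cell_w),
      height = fmt_coord(lay$main_panel$h),
      fill = "none", stroke = "#1e90ff", `stroke-width` = "2")))
    zp <- lay$zoom_panel
    win <- seq.int(zs + 1L, zs + zn)
    for (k in seq_along(win)) {
      add(text_node(sprintf("zoomxlabel-%d", win[k] - 1L),
                    zp$x + (k - 0.5) * lay$zoom_cell, zp$y - LABEL_PAD,
                    m$col_labels[win[k]]))
    }
    for (nd in render_panel_cells(m, win, zp$x, zp$y, lay$zoom_cell,
                                  lay$zoom_cell, colors, "zoomcell",
                                  config$tooltips))
      add(nd)
  }

  # scale bar
  sb <- build_scale_bar(scheme, rng$min, rng$mid, rng$max)
  sr <- lay$scalebar_rect
  seg_w <- sr$w / nrow(sb$segments)
  for (k in seq_len(nrow(sb$segments))) {
    add(svg_node("rect", list(
      id = sprintf("scalebar-%d", k - 1L),
      x = fmt_coord(sr$x + (k - 1L) * seg_w), y = fmt_coord(sr$y),
      width = fmt_coord(seg_w), height = fmt_coord(sr$h),
      fill = sb$segments$color[k])))
  }
  for (k in seq_along(sb$tick_values)) {
    tv <- sb$tick_values[k]
    tx <- sr$x + sr$w * (tv - rng$min) / (rng$max - rng$min)
    add(text_node(sprintf("scalebartick-%d", k - 1L), tx,
                  sr$y + sr$h + FONT_SIZE + 2L, sprintf("%.4g", tv),
                  anchor = if (k == 1L) "start"
                           else if (k == length(sb$tick_values)) "end"
                           else "middle"))
  }

  svg_document(lay$canvas_w, lay$canvas_h, els)
}

#' Export an SVG document as a raster image
#'
#' Optional feature: rasterization needs the `rsvg` package. When no raster
#' backend is installed the function fails cleanly with a `NOT_AVAILABLE`
#' error carrying an install hint — it never crashes.
#'
#' @param doc an `svg_document`.
#' @param format raster format; only `"png"`.
#' @param scale positive magnification factor applied to both dimensions.
#' @return Raw vector of PNG bytes.
#' @export
export_raster <- function(doc, format = "png", scale = 1) {
  stopifnot(inherits(doc, "svg_document"))
  if (!identical(tolower(format), "png"))
    hm_abort("NOT_AVAILABLE", sprintf("unsupported raster format '%s'", format))
  if (!is.numeric(scale) || length(scale) != 1L || is.na(scale) || scale <= 0)
    hm_abort("BAD_SCALE", "scale must be a positive number")
  if (!requireNamespace("rsvg", quietly = TRUE))
    hm_abort("NOT_AVAILABLE",
             "PNG export needs the 'rsvg' package; install it with install.packages(\"rsvg\")")
  rsvg::rsvg_png(charToRaw(svg_string(doc)),
                 width = round(doc$width * scale),
                 height = round(doc$height * scale))
}
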