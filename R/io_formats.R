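# CSV dialect: comma separator, RFC-4180 quoting, UTF-8. First row holds the
# column labels (corner cell ignored), first column the row labels. Empty
# string / "NA" / "NaN" (case-insensitive) are missing-value tokens. The
# tokenizer is utils::read.csv; cell-level number validation is ours so that
# bad tokens are reported with their row/column position.

MISSING_TOKENS <- c("", "na", "nan")

#' Parse a labeled matrix from CSV text
#'
#' @param text a single string (or character vector of lines) of CSV: first
#'   row = column labels with the corner cell ignored, first column = row
#'   labels, remaining cells decimal numbers (scientific notation accepted) or
#'   a missing token (`""`, `"NA"`, `"NaN"`, case-insensitive).
#' @param sep field separator, comma by default.
#' @return A validated [heat_matrix()].
#' @examples
#' parse_matrix_csv(",c1,c2\nr1,1.5,-2\nr2,0,3")
#' @export
parse_matrix_csv <- function(text, sep = ",") {
  if (length(text) > 1L) text <- paste(text, collapse = "\n")
  if (length(text) == 0L || is.na(text) || !nzchar(trimws(text)))
    hm_abort("EMPTY_INPUT", "CSV input is empty")
  df <- tryCatch(
    utils::read.csv(text = text, header = FALSE, sep = sep,
                    colClasses = "character", check.names = FALSE,
                    na.strings = character(0),
                    blank.lines.skip = TRUE, fill = FALSE,
                    strip.white = FALSE),
    error = function(e) hm_abort("RAGGED_MATRIX",
                                 sprintf("rows of unequal length: %s",
                                         conditionMessage(e)))
  )
  if (nrow(df) < 2L || ncol(df) < 2L)
    hm_abort("EMPTY_INPUT",
             "CSV needs a label row, a label column and at least one data cell")
  col_labels <- as.character(df[1L, -1L])
  row_labels <- as.character(df[-1L, 1L])
  cells <- as.matrix(df[-1L, -1L, drop = FALSE])
  R <- nrow(cells); C <- ncol(cells)
  values <- matrix(NA_real_, R, C)
  flags <- matrix("NONE", R, C)
  for (i in seq_len(R)) {
    for (j in seq_len(C)) {
      tok <- trimws(cells[i, j])
      if (tolower(tok) %in% MISSING_TOKENS) {
        flags[i, j] <- "MISSING"
      } else {
        num <- suppressWarnings(as.numeric(tok))
        if (is.na(num))
          hm_abort("BAD_NUMBER",
                   sprintf("cell (row %s, col %s): '%s' is not a number",
                           row_labels[i], col_labels[j], tok),
                   row = row_labels[i], col = col_labels[j])
        values[i, j] <- num
      }
    }
  }
  heat_matrix(values, row_labels, col_labels, flags)
}

#' Read a labeled matrix from a CSV file
#' @param path file path.
#' @inheritParams parse_matrix_csv
#' @return A validated [heat_matrix()].
#' @export
read_matrix_csv <- function(path, sep = ",") {
  if (!file.exists(path))
    hm_abort("IO_ERROR", sprintf("no such file: %s", path))
  parse_matrix_csv(readLines(path, warn = FALSE, encoding = "UTF-8"), sep = sep)
}

csv_quote <- function(x) {
  needs <- grepl('[",\n\r]', x)
  x[needs] <- paste0('"', gsub('"', '""', x[needs]), '"')
  x
}

# Shortest decimal representation that round-trips a double; R's default
# 15-significant-digit format is exact for every value we generate.
fmt_value <- function(v) {
  out <- vapply(v, function(x) format(x, digits = 15, scientific = FALSE,
                                      trim = TRUE),
                character(1))
  out
}

#' Write a labeled matrix as CSV text
#'
#' The inverse of [parse_matrix_csv()]: labels are RFC-4180-quoted when they
#' contain commas, quotes or newlines; `MISSING` cells are written as `"NA"`.
#' `WILDTYPE` flags are a display property with no CSV representation, so the
#' wildtype cell's numeric value is written (flag information travels via the
#' JSON format instead).
#'
#' @param m a valid [heat_matrix()].
#' @param path optional file path; when given, the text is also written there
#'   as UTF-8.
#' @return The CSV text, a single string (invisibly when `path` is given).
#' @export
write_matrix_csv <- function(m, path = NULL) {
  validate_matrix(m)
  vals <- matrix(fmt_value(m$values), nrow(m$values))
  vals[m$flags == "MISSING"] <- "NA"
  header <- paste(c("", csv_quote(m$col_labels)), collapse = ",")
  body <- vapply(seq_len(nrow(vals)), function(i) {
    paste(c(csv_quote(m$row_labels[i]), vals[i, ]), collapse = ",")
  }, character(1))
  text <- paste0(paste(c(header, body), collapse = "\n"), "\n")
  if (!is.null(path)) {
    con <- file(path, open = "wb")
    on.exit(close(con))
    writeBin(charToRaw(text), con)
    return(invisible(text))
  }
  text
}

json_require <- function(obj, key, where = "data object") {
  if (is.null(obj[[key]]))
    hm_abort("SCHEMA_ERROR", sprintf("%s: required key '%s' is missing",
                                     where, key),
             key = key)
  obj[[key]]
}

as_grid <- function(rows_list, what) {
  if (!is.list(rows_list) || length(rows_list) == 0L)
    hm_abort("SCHEMA_ERROR", sprintf("'%s' must be a non-empty array of arrays",
                                     what), key = what)
  lens <- lengths(rows_list)
  if (length(unique(lens)) > 1L)
    hm_abort("RAGGED_MATRIX",
             sprintf("'%s' rows have unequal lengths (%s)", what,
                     paste(lens, collapse = ", ")))
  rows_list
}

#' Parse a heat-map matrix from a JSON data object
#'
#' Schema: `{"rows": [...], "cols": [...], "values": [[...]],
#' "flags": [[...]]}` with `flags` optional (default all `"NONE"`; tokens are
#' the uppercase strings `"NONE"`, `"WILDTYPE"`, `"MISSING"`). A JSON `null`
#' value cell is treated as missing.
#'
#' @param text JSON text.
#' @return A validated [heat_matrix()].
#' @examples
#' parse_data_json('{"rows":["a"],"cols":["x","y"],"values":[[1,2]]}')
#' @export
parse_data_json <- function(text) {
  j <- tryCatch(jsonlite::fromJSON(text, simplifyVector = FALSE),
                error = function(e)
                  hm_abort("SCHEMA_ERROR",
                           sprintf("not well-formed JSON: %s",
                                   conditionMessage(e))))
  rows <- json_require(j, "rows")
  cols <- json_require(j, "cols")
  vrows <- as_grid(json_require(j, "values"), "values")
  R <- length(vrows); C <- length(vrows[[1L]])
  values <- matrix(NA_real_, R, C)
  for (i in seq_len(R)) {
    for (jj in seq_len(C)) {
      cell <- vrows[[i]][[jj]]
      if (is.null(cell)) next
      if (!is.numeric(cell))
        hm_abort("SCHEMA_ERROR",
                 sprintf("values[%d][%d] is not a number or null", i, jj),
                 key = "values")
      values[i, jj] <- cell
    }
  }
  flags <- matrix(ifelse(is.na(values), "MISSING", "NONE"), R)
  if (!is.null(j$flags)) {
    frows <- as_grid(j$flags, "flags")
    if (length(frows) != R || length(frows[[1L]]) != C)
      hm_abort("FLAG_SHAPE", "'flags' shape differs from 'values' shape")
    flags <- matrix(unlist(lapply(frows, as.character)), R, C, byrow = TRUE)
    values[flags == "MISSING"] <- NA_real_
  }
  heat_matrix(values, unlist(rows), unlist(cols), flags)
}

num_or_abort <- function(x, key) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x))
    hm_abort("SCHEMA_ERROR", sprintf("'%s' must be a number", key), key = key)
  x
}

#' Parse a rendering configuration from a JSON config object
#'
#' Schema: `{"target": str?, "range": {"min", "max", "mid"?}?, "scheme": str,
#' "canvas": {"width", "height"}?, "minCellSize": num?, "zoomStartCol": num?,
#' "tooltips": bool?}`. `scheme` is required; absent optional keys become
#' automatic defaults. `target` is stored verbatim and unused in file output.
#'
#' @param text JSON text.
#' @return A [render_config()].
#' @examples
#' parse_config_json('{"scheme":"blue-white-red","range":{"min":-1,"max":1}}')
#' @export
parse_config_json <- function(text) {
  j <- tryCatch(jsonlite::fromJSON(text, simplifyVector = FALSE),
                error = function(e)
                  hm_abort("SCHEMA_ERROR",
                           sprintf("not well-formed JSON: %s",
                                   conditionMessage(e))))
  if (!is.list(j))
    hm_abort("SCHEMA_ERROR", "config object: top level must be a JSON object")
  scheme <- json_require(j, "scheme", "config object")
  if (!is.character(scheme) || length(scheme) != 1L)
    hm_abort("SCHEMA_ERROR", "'scheme' must be a string", key = "scheme")
  rmin <- rmax <- rmid <- NA_real_
  if (!is.null(j$range)) {
    rmin <- num_or_abort(json_require(j$range, "min", "'range'"), "range.min")
    rmax <- num_or_abort(json_require(j$range, "max", "'range'"), "range.max")
    if (rmin >= rmax)
      hm_abort("RANGE_ERROR",
               sprintf("range.min (%g) must be < range.max (%g)", rmin, rmax))
    if (!is.null(j$range$mid)) rmid <- num_or_abort(j$range$mid, "range.mid")
  }
  cw <- ch <- NA_real_
  if (!is.null(j$canvas)) {
    cw <- num_or_abort(json_require(j$canvas, "width", "'canvas'"),
                       "canvas.width")
    ch <- num_or_abort(json_require(j$canvas, "height", "'canvas'"),
                       "canvas.height")
  }
  render_config(
    range_min = rmin, range_max = rmax, range_mid = rmid,
    scheme_name = scheme, canvas_w = cw, canvas_h = ch,
    min_cell_size = if (is.null(j$minCellSize)) NA_real_
                    else num_or_abort(j$minCellSize, "minCellSize"),
    zoom_start_col = if (is.null(j$zoomStartCol)) NA_real_
                     else num_or_abort(j$zoomStartCol, "zoomStartCol"),
    tooltips = if (is.null(j$tooltips)) TRUE else isTRUE(j$tooltips),
    target = if (is.null(j$target)) NA_character_ else as.character(j$target)
  )
}
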