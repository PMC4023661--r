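small_matrix <- function() {
  heat_matrix(matrix(c(-1, 0, 0.5, 1, -0.5, 0.25), 2, byrow = TRUE),
              c("a", "b"), c("x", "y", "z"))
}

test_that("every cell gets one rectangle and, with tooltips, one title", {
  doc <- render_heatmap(small_matrix(),
                        render_config(range_min = -1, range_max = 1))
  xml <- svg_xml(doc)
  expect_equal(count_id_prefix(xml, "cell-"), 6L)
  titles <- xml2::xml_find_all(
    xml, '//*[starts-with(@id, "cell-")]/*[local-name() = "title"]')
  expect_length(titles, 6L)
  expect_identical(xml2::xml_text(titles[[1]]), "a / x: -1")
  off <- render_heatmap(small_matrix(),
                        render_config(range_min = -1, range_max = 1,
                                      tooltips = FALSE))
  expect_equal(length(xml2::xml_find_all(
    svg_xml(off), '//*[local-name() = "title"]')), 0L)
})

test_that("wildtype cells are filled black and missing cells grey", {
  m <- heat_matrix(matrix(c(0.7, NA, 0.1, 0.9), 2), c("a", "b"), c("x", "y"),
                   flags = matrix(c("WILDTYPE", "MISSING", "NONE", "NONE"), 2))
  m$values[1, 1] <- 0.7
  doc <- render_heatmap(m, render_config(range_min = 0, range_max = 1))
  xml <- svg_xml(doc)
  expect_identical(fill_of_id(xml, "cell-0-0"), "#000000")
  expect_identical(fill_of_id(xml, "cell-1-0"), "#cccccc")
  tip <- xml2::xml_text(xml2::xml_find_first(
    xml, '//*[@id = "cell-0-0"]/*[local-name() = "title"]'))
  expect_identical(tip, "a / x: wildtype")
  tip_na <- xml2::xml_text(xml2::xml_find_first(
    xml, '//*[@id = "cell-1-0"]/*[local-name() = "title"]'))
  expect_identical(tip_na, "b / x: NA")
})

test_that("cell fills agree with value_to_color across random matrices", {
  set.seed(21)
  s <- get_scheme("blue-white-red")
  for (k in 1:5) {
    m <- random_heat_matrix(R = 10, C = 10)
    cfg <- render_config(range_min = -100, range_max = 100, range_mid = 0)
    xml <- svg_xml(render_heatmap(m, cfg))
    for (i in 0:9) for (j in 0:9) {
      expect_identical(
        fill_of_id(xml, sprintf("cell-%d-%d", i, j)),
        value_to_color(m$values[i + 1, j + 1], m$flags[i + 1, j + 1],
                       s, -100, 0, 100))
    }
  }
})

test_that("a forced zoom adds one frame and a full-height zoom window", {
  cfg <- render_config(range_min = -1, range_max = 1,
                       min_cell_size = 10000, zoom_start_col = 0)
  doc <- render_heatmap(small_matrix(), cfg)
  xml <- svg_xml(doc)
  frames <- xml2::xml_find_all(xml, '//*[@id = "zoomframe"]')
  expect_length(frames, 1L)
  expect_identical(xml2::xml_attr(frames[[1]], "fill"), "none")
  # window clamps to all 3 columns: 2 rows x 3 cols of zoom cells
  expect_equal(count_id_prefix(xml, "zoomcell-"), 6L)
  # zoom cells sit strictly below every main-panel cell
  main_y <- as.numeric(xml2::xml_attr(xml2::xml_find_all(
    xml, '//*[starts-with(@id, "cell-")]'), "y"))
  zoom_y <- as.numeric(xml2::xml_attr(xml2::xml_find_all(
    xml, '//*[starts-with(@id, "zoomcell-")]'), "y"))
  expect_true(min(zoom_y) > max(main_y))
})

test_that("annotation tracks render one swatch per annotated column", {
  trs <- list(track("SecStr", c("H", "H", NA), c(H = "#ff0000")),
              track("Exon", c("E1", "E2", "E1"),
                    c(E1 = "#112233", E2 = "#445566")))
  cfg <- render_config(range_min = -1, range_max = 1, tracks = trs)
  xml <- svg_xml(render_heatmap(small_matrix(), cfg))
  expect_equal(count_id_prefix(xml, "track-"), 2L + 3L)
  expect_identical(fill_of_id(xml, "track-0-0"), "#ff0000")
  expect_identical(fill_of_id(xml, "track-1-1"), "#445566")
  # NA category draws nothing
  expect_true(is.na(fill_of_id(xml, "track-0-2")))
  expect_error(render_heatmap(small_matrix(), render_config(
    range_min = -1, range_max = 1,
    tracks = list(track("bad", c("H", "H"), c(H = "#ff0000"))))),
    class = "svgheatmap_label_mismatch")
})

test_that("the scale bar and labels are present and inside the canvas", {
  cfg <- render_config(range_min = -2, range_max = 2)
  doc <- render_heatmap(small_matrix(), cfg)
  xml <- svg_xml(doc)
  expect_equal(count_id_prefix(xml, "scalebar-"), 64L)
  ticks <- xml2::xml_find_all(xml, '//*[starts-with(@id, "scalebartick-")]')
  expect_setequal(xml2::xml_text(ticks), c("-2", "0", "2"))
  expect_equal(count_id_prefix(xml, "xlabel-"), 3L)
  expect_equal(count_id_prefix(xml, "ylabel-"), 2L)
  rects <- xml2::xml_find_all(xml, '//*[local-name() = "rect"]')
  x1 <- as.numeric(xml2::xml_attr(rects, "x")) +
    as.numeric(xml2::xml_attr(rects, "width"))
  y1 <- as.numeric(xml2::xml_attr(rects, "y")) +
    as.numeric(xml2::xml_attr(rects, "height"))
  expect_true(all(x1 <= doc$width + 1e-9))
  expect_true(all(y1 <= doc$height + 1e-9))
  expect_true(all(as.numeric(xml2::xml_attr(rects, "x")) >= 0))
  expect_true(all(as.numeric(xml2::xml_attr(rects, "y")) >= 0))
})

test_that("serialization round-trips through an XML parser and is byte-stable", {
  doc <- render_heatmap(small_matrix(), render_config(range_min = -1,
                                                      range_max = 1))
  f1 <- tempfile(fileext = ".svg"); f2 <- tempfile(fileext = ".svg")
  write_svg(doc, f1); write_svg(doc, f2)
  b1 <- readBin(f1, "raw", file.size(f1))
  b2 <- readBin(f2, "raw", file.size(f2))
  expect_identical(b1, b2)
  x1 <- xml2::read_xml(f1)
  expect_identical(xml2::xml_name(x1), "svg")
  expect_identical(xml2::xml_ns(x1)[[1]], "http://www.w3.org/2000/svg")
  # re-serialize from the parsed tree: same element names and ids in order
  ids_parsed <- xml2::xml_attr(xml2::xml_find_all(x1, "//*[@id]"), "id")
  ids_doc <- unlist(lapply(doc$elements, function(e) e$attrs$id))
  expect_identical(ids_parsed, ids_doc)
})

test_that("labels with XML metacharacters are escaped, not corrupted", {
  m <- heat_matrix(matrix(1:2, 1), 'r "<&>"', c("a<b", "c&d"))
  xml <- svg_xml(render_heatmap(m, render_config(range_min = 0,
                                                 range_max = 3)))
  labs <- xml2::xml_text(xml2::xml_find_all(
    xml, '//*[starts-with(@id, "xlabel-")]'))
  expect_identical(labs, c("a<b", "c&d"))
})

test_that("an empty document serializes to minimal valid SVG", {
  doc <- svgheatmap:::svg_document(1, 1, list())
  txt <- svg_string(doc)
  x <- xml2::read_xml(txt)
  expect_identical(xml2::xml_name(x), "svg")
  expect_length(xml2::xml_children(x), 0L)
})

test_that("raster export degrades cleanly and validates its scale", {
  doc <- render_heatmap(small_matrix(), render_config(range_min = -1,
                                                      range_max = 1))
  expect_error(export_raster(doc, "png", scale = 0),
               class = "svgheatmap_bad_scale")
  expect_error(export_raster(doc, "bmp"),
               class = "svgheatmap_not_available")
  if (!requireNamespace("rsvg", quietly = TRUE)) {
    err <- tryCatch(export_raster(doc, "png", 2), condition = identity)
    expect_s3_class(err, "svgheatmap_not_available")
    expect_match(conditionMessage(err), "rsvg")
  } else {
    png <- export_raster(doc, "png", 2)
    expect_true(is.raw(png) && length(png) > 0)
  }
})
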