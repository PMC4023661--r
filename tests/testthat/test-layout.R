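# Second call reuses the gutters reported by a first call so tests can pin
# the plot area exactly.
layout_for_plot_area <- function(R, C, plot_w, plot_h, min_cell = 5,
                                 zoom_start = NA_real_) {
  labels <- list(rows = rep("r", R), cols = rep("c", C))
  probe <- compute_layout(R, C, render_config(min_cell_size = min_cell),
                          row_labels = labels$rows, col_labels = labels$cols)
  compute_layout(R, C,
                 render_config(min_cell_size = min_cell,
                               canvas_w = probe$label_gutter_left + plot_w,
                               canvas_h = probe$label_gutter_top + plot_h + 44,
                               zoom_start_col = zoom_start),
                 row_labels = labels$rows, col_labels = labels$cols)
}

test_that("ample plot area gives large cells and no zoom panel", {
  lay <- layout_for_plot_area(10, 10, 500, 500)
  expect_equal(lay$cell_w, 50L)
  expect_equal(lay$cell_h, 50L)
  expect_false(lay$zoom_needed)
  expect_null(lay$zoom_panel)
  expect_equal(lay$main_panel$w, 500L)
  expect_equal(lay$main_panel$h, 500L)
})

test_that("a wide matrix in a narrow plot area triggers the zoom panel", {
  lay <- layout_for_plot_area(20, 348, 1000, 400)
  expect_equal(lay$cell_w, 2L)                 # floor(1000 / 348)
  expect_equal(lay$cell_h, 20L)                # floor(400 / 20)
  expect_true(lay$zoom_needed)                 # 1000/348 ~ 2.87 < 5
  expect_equal(lay$zoom_n_cols, 50L)           # min(348, floor(1000 / 20))
  expect_equal(lay$zoom_cell, 20L)
  # zoom panel sits strictly below the main panel
  expect_gte(lay$zoom_panel$y, lay$main_panel$y + lay$main_panel$h)
  # scale bar below everything
  expect_gte(lay$scalebar_rect$y, lay$zoom_panel$y + lay$zoom_panel$h)
})

test_that("the zoom trigger uses a strict smaller-than comparison", {
  # raw cell width exactly 5 with min_cell_size 5: no zoom
  lay <- layout_for_plot_area(4, 100, 500, 400, min_cell = 5)
  expect_equal(lay$cell_w_raw, 5)
  expect_false(lay$zoom_needed)
  lay2 <- layout_for_plot_area(4, 100, 499, 400, min_cell = 5)
  expect_true(lay2$zoom_needed)
})

test_that("zoom triggering is monotone non-decreasing in min_cell_size", {
  set.seed(3)
  for (k in 1:30) {
    R <- sample(1:40, 1); C <- sample(1:400, 1)
    trig <- vapply(c(1, 2, 5, 10, 25, 60), function(mc)
      layout_for_plot_area(R, C, 800, 300, min_cell = mc)$zoom_needed,
      logical(1))
    expect_true(all(diff(trig) >= 0))
  }
})

test_that("clamp_zoom_region shifts and shrinks windows into range", {
  expect_equal(clamp_zoom_region(5, 10, 100), list(start = 5L, n = 10L))
  expect_equal(clamp_zoom_region(95, 10, 100), list(start = 90L, n = 10L))
  expect_equal(clamp_zoom_region(0, 10, 4), list(start = 0L, n = 4L))
  expect_equal(clamp_zoom_region(-3, 2, 10), list(start = 0L, n = 2L))
  set.seed(5)
  for (k in 1:100) {
    C <- sample(1:200, 1)
    z <- clamp_zoom_region(sample(-50:250, 1), sample(1:250, 1), C)
    expect_gte(z$start, 0L)
    expect_lte(z$start + z$n, C)
    expect_gte(z$n, 1L)
  }
})

test_that("cell rectangles tile the main panel exactly", {
  set.seed(17)
  for (k in 1:40) {
    R <- sample(1:30, 1); C <- sample(1:60, 1)
    lay <- layout_for_plot_area(R, C, sample(100:900, 1), sample(80:600, 1))
    # the grid is an exact partition: cell (i,j) occupies
    # [x + j*cw, x + (j+1)*cw) x [y + i*ch, y + (i+1)*ch)
    xs <- lay$main_panel$x + lay$cell_w * (0:C)
    ys <- lay$main_panel$y + lay$cell_h * (0:R)
    expect_equal(xs[1], lay$main_panel$x)
    expect_equal(xs[C + 1] - xs[1], lay$main_panel$w)
    expect_equal(ys[R + 1] - ys[1], lay$main_panel$h)
    expect_true(all(diff(xs) == lay$cell_w))   # equal, gap-free columns
    expect_true(all(diff(ys) == lay$cell_h))
    expect_gte(lay$cell_w, 1L)
    expect_gte(lay$cell_h, 1L)
  }
})

test_that("layout is deterministic and respects configured zoom start", {
  cfg <- render_config(min_cell_size = 30, canvas_w = 600,
                       zoom_start_col = 12)
  a <- compute_layout(6, 50, cfg)
  b <- compute_layout(6, 50, cfg)
  expect_identical(a, b)
  expect_true(a$zoom_needed)
  expect_equal(a$zoom_start_col, 12L)
  expect_lte(a$zoom_start_col + a$zoom_n_cols, 50L)
})

test_that("an impossible canvas raises CANVAS_TOO_SMALL", {
  expect_error(compute_layout(5, 5, render_config(canvas_w = 10),
                              row_labels = c("a_very_long_rowlabel",
                                             "b", "c", "d", "e")),
               class = "svgheatmap_canvas_too_small")
  expect_error(compute_layout(5, 5, render_config(canvas_h = 30)),
               class = "svgheatmap_canvas_too_small")
})

test_that("track strips stack above the matrix inside the top gutter", {
  trs <- list(track("t1", rep("H", 8), c(H = "#ff0000")),
              track("t2", rep("E", 8), c(E = "#0000ff")))
  lay <- compute_layout(3, 8, render_config(tracks = trs))
  expect_length(lay$track_rects, 2L)
  ys <- vapply(lay$track_rects, `[[`, numeric(1), "y")
  expect_true(all(diff(ys) > 0))
  expect_equal(max(ys) + 14L, lay$main_panel$y)
})
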