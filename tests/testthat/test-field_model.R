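test_that("rectangles translate additively and keep their dimensions", {
  r <- pixel_rect(0, 0, 10, 10)
  expect_equal(unclass(translate_rect(r, c(5, -2))),
               unclass(pixel_rect(5, -2, 15, 8)))
  expect_equal(translate_rect(r, c(0, 0)), r)
  set.seed(42)
  for (i in 1:20) {
    t1 <- runif(2, -30, 30); t2 <- runif(2, -30, 30)
    r2 <- translate_rect(translate_rect(r, t1), t2)
    expect_equal(unclass(r2), unclass(translate_rect(r, t1 + t2)))
    expect_equal(rect_width(r2), rect_width(r))
    expect_equal(rect_height(r2), rect_height(r))
  }
})

test_that("layout files round-trip and enforce the map invariants", {
  fld <- toy_field()
  path <- withr::local_tempfile(fileext = ".json")
  write_map(fld$map, path)
  m <- load_map(path)
  expect_s3_class(m, "microplot_map")
  expect_equal(nrow(m), 12)
  expect_equal(as.character(m$plot_id), as.character(fld$map$plot_id))
  expect_equal(m$x_min, fld$map$x_min, tolerance = 1e-12)
  expect_equal(attr(m, "gap_y"), attr(fld$map, "gap_y"))
  # column-major id order: ids increase down each column, left to right
  expect_equal(order(m$column, m$row), seq_len(nrow(m)))

  # single 1 m x 1 m plot at the origin
  one <- withr::local_tempfile(fileext = ".json")
  writeLines(jsonlite::toJSON(list(
    units = "meters", gap_within_column = 0.5, gap_between_columns = 0.5,
    blocks = list(list(columns = list(list(
      list(id = "p1", x_min = 0, y_min = 0, x_max = 1, y_max = 1)))))),
    auto_unbox = TRUE), one)
  m1 <- load_map(one)
  expect_equal(unname(unlist(m1[1, c("x_min", "y_min", "x_max", "y_max")])),
               c(0, 0, 1, 1))

  # overlapping plots are rejected
  bad <- withr::local_tempfile(fileext = ".json")
  writeLines(jsonlite::toJSON(list(
    units = "meters", gap_within_column = 0.5, gap_between_columns = 0.5,
    blocks = list(list(columns = list(list(
      list(x_min = 0, y_min = 0, x_max = 1, y_max = 1),
      list(x_min = 0, y_min = 0.5, x_max = 1, y_max = 1.5)))))),
    auto_unbox = TRUE), bad)
  expect_error(load_map(bad), "overlap")
})

test_that("the canola-like layout has 234 plots in three two-column blocks", {
  map <- generate_field(field_preset("canola_like"))$map
  expect_equal(nrow(map), 234)          # 39 rows x 6 columns
  expect_equal(length(unique(map$block)), 3)
  expect_equal(as.integer(table(map$block)), rep(78L, 3))
  expect_equal(length(unique(map$column)), 6)
})

test_that("scale_map multiplies coordinates by the pixel-per-meter scales", {
  df <- data.frame(block = 1, column = 1, row = 1,
                   x_min = 0, y_min = 0, x_max = 1, y_max = 2)
  m <- microplot_map(df, units = "meters", gap_y = 0.3048, gap_x = 0.5)
  p <- scale_map(m, scale_spec(10, 20))
  expect_equal(unname(unlist(p[1, c("x_min", "y_min", "x_max", "y_max")])),
               c(0, 0, 10, 40))
  expect_equal(attr(p, "units"), "pixels")
  expect_error(scale_map(p, scale_spec(1)), "already")

  # identity scale
  p1 <- scale_map(m, scale_spec(1, 1))
  expect_equal(p1$x_max, m$x_max)

  # a 1 ft gap at 50 px/m scales to 15.24 px
  expect_equal(attr(scale_map(m, scale_spec(50)), "gap_y"), 15.24)

  # scaling then the inverse scale recovers coordinates to 1e-9 relative
  fld <- toy_field()
  up <- scale_map(fld$map, scale_spec(7.3, 11.9))
  back <- up
  back$x_min <- up$x_min / 7.3; back$x_max <- up$x_max / 7.3
  back$y_min <- up$y_min / 11.9; back$y_max <- up$y_max / 11.9
  expect_equal(back$x_max, fld$map$x_max, tolerance = 1e-9)
  expect_equal(back$y_max, fld$map$y_max, tolerance = 1e-9)
})

test_that("column bounding boxes equal the brute-force corner extremes", {
  two <- list(pixel_rect(0, 0, 10, 10), pixel_rect(0, 15, 10, 25))
  expect_equal(unclass(bounding_rect(two)),
               unclass(pixel_rect(0, 0, 10, 25)))
  fld <- generate_field(field_preset("toy", n_rows = 6, n_cols = 3,
                                     block_splits = c(2, 4)))
  map <- scale_map(fld$map, fld$scale)
  for (cc in unique(map$column)) {
    sub <- map[map$column == cc, ]
    box <- column_bounding_box(map, cc)
    expect_equal(box[["x_min"]], min(sub$x_min))
    expect_equal(box[["y_max"]], max(sub$y_max))
  }
  expect_error(column_bounding_box(map, 99), "no plots")
})

test_that("results write as CSV and Pascal VOC and round-trip", {
  fld <- toy_field()
  map <- scale_map(fld$map, fld$scale)
  out <- withr::local_tempfile(fileext = ".csv")
  paths <- write_results(map, out, image_dim = c(fld$image$h, fld$image$w))
  csv <- utils::read.csv(paths[["csv"]])
  expect_equal(nrow(csv), nrow(map))
  voc <- read_voc(paths[["xml"]])
  expect_equal(nrow(voc), nrow(map))
  expect_equal(voc$x_min, round_half_up(map$x_min))
  expect_equal(voc$y_max, round_half_up(map$y_max))
  # writing the integer boxes again reproduces them exactly
  out2 <- withr::local_tempfile(fileext = ".xml")
  write_voc(voc, out2)
  expect_identical(read_voc(out2), voc)
})
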