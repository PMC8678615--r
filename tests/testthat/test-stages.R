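test_that("block bounds are the image slack around the full map extent", {
  img <- veg_image(matrix(0.5, 100, 100))
  rects <- list(pixel_rect(0, 0, 25, 30), pixel_rect(30, 0, 40, 30))
  b <- block_bounds(img, rects)     # extent 40 x 30 at the origin
  expect_equal(b$dx, c(0, 60))
  expect_equal(b$dy, c(0, 70))
  # extent equal to the image forces a degenerate box
  full <- block_bounds(img, list(pixel_rect(0, 0, 100, 100)))
  expect_equal(full$dx, c(0, 0))
  expect_equal(full$dy, c(0, 0))
  expect_error(block_bounds(img, list(pixel_rect(0, 0, 120, 50))), "extent")
})

test_that("the block stage recovers a known rigid offset within a pixel", {
  fld <- toy_field(offset = c(12, 7), seed = 5)
  map <- scale_map(fld$map, fld$scale)
  m1 <- optimize_block(fld$image, map, fast_de(2))
  shift <- attr(m1, "block_shifts")
  expected <- fld$spec$margin + c(12, 7)
  expect_lt(abs(shift[1, "dx"] - expected[1]), 1)
  expect_lt(abs(shift[1, "dy"] - expected[2]), 1)
  # vegetation overlap never degrades relative to the unshifted start
  rects <- list(bounding_rect(map_rects_for_test(m1)))
  expect_gte(phi_veg(fld$image, bounding_rect(map_rects_for_test(m1))),
             phi_veg(fld$image, bounding_rect(map_rects_for_test(map))))
})

test_that("a flat image leaves the block stage deterministic", {
  img <- veg_image(matrix(1, 60, 60))
  df <- data.frame(block = 1, column = 1, row = 1:2,
                   x_min = 0, y_min = c(0, 15), x_max = 20, y_max = c(10, 25))
  map0 <- microplot_map(df, units = "meters", gap_y = 5, gap_x = 5)
  map <- scale_map(map0, scale_spec(1))
  a <- optimize_block(img, map, de_config(seed = 4, max_iter = 30))
  b <- optimize_block(img, map, de_config(seed = 4, max_iter = 30))
  expect_identical(a$x_min, b$x_min)
  expect_equal(phi_veg(img, map_rects_for_test(a)), 1)
})

test_that("the column stage pulls a displaced column back to the field", {
  fld <- toy_field(offset = c(0, 0), seed = 9)
  map <- scale_map(fld$map, fld$scale)
  # truth sits at margin; place the map there, then knock column 2 down 0.6 g
  aligned <- map
  aligned$x_min <- fld$truth$x_min; aligned$x_max <- fld$truth$x_max
  aligned$y_min <- fld$truth$y_min; aligned$y_max <- fld$truth$y_max
  g <- attr(map, "gap_y")
  bad <- aligned
  i2 <- bad$column == 2
  bad$y_min[i2] <- bad$y_min[i2] + 0.6 * g
  bad$y_max[i2] <- bad$y_max[i2] + 0.6 * g
  m2 <- optimize_columns(fld$image, bad, fast_de(3))
  expect_lt(max(abs(m2$y_min[i2] - aligned$y_min[i2])), 1)
  # widths and heights unchanged by the stage
  expect_equal(m2$x_max - m2$x_min, bad$x_max - bad$x_min, tolerance = 1e-9)
  expect_equal(m2$y_max - m2$y_min, bad$y_max - bad$y_min, tolerance = 1e-9)
  # already-aligned map stays put (within the rasterization plateau)
  m0 <- optimize_columns(fld$image, aligned, fast_de(3))
  expect_lt(max(abs(m0$y_min - aligned$y_min)), 1)
})

test_that("overlap removal restores the initial inter-column spacing", {
  mk <- function(xmins, w = 10) {
    df <- do.call(rbind, lapply(seq_along(xmins), function(j)
      data.frame(block = 1, column = j, row = 1,
                 x_min = xmins[j], y_min = 0, x_max = xmins[j] + w, y_max = 30)))
    out <- structure(df, units = "pixels", gap_y = 5, gap_x = 4,
                     plot_w = w, plot_h = 30,
                     class = c("microplot_map", "data.frame"))
    out
  }
  two <- mk(c(0, 8))
  fixed <- fix_column_overlaps(two, s = 4)
  expect_equal(fixed$x_min[1], -6)   # right edge 4 px left of neighbour
  expect_equal(fixed$x_max[1], 4)
  # no overlap: untouched
  ok <- mk(c(0, 20))
  expect_equal(fix_column_overlaps(ok, s = 4)$x_min, c(0, 20))
  # cascading overlaps: all adjacent gaps equal s afterwards
  three <- fix_column_overlaps(mk(c(0, 6, 12)), s = 4)
  gaps <- three$x_min[-1] - three$x_max[-3]
  expect_equal(gaps, c(4, 4))
})

test_that("column boxes are disjoint after the stage on a closed canopy", {
  # heavy blur merges the inter-column soil gaps
  fld <- toy_field(offset = c(5, 3), seed = 13, blur_sigma = 2.5,
                   noise_sd = 0.03)
  map <- scale_map(fld$map, fld$scale)
  m1 <- optimize_block(fld$image, map, fast_de(5))
  m2 <- optimize_columns(fld$image, m1, fast_de(5))
  cols <- sort(unique(m2$column))
  for (j in seq_len(length(cols) - 1)) {
    left <- column_bounding_box(m2, cols[j])
    right <- column_bounding_box(m2, cols[j + 1])
    expect_lte(left[["x_max"]], right[["x_min"]] + 1e-9)
  }
})
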