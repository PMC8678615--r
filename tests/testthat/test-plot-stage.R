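bounds22 <- list(dx = c(-15, 15), dy = c(-10, 10))

test_that("even-spacing cost follows its exponential form", {
  expect_equal(phi_ec(10, 10, bounds22), 0)
  # normalized gap error of 1 and 0.5
  expect_equal(phi_ec(20, 10, bounds22), 1 - exp(-4), tolerance = 1e-12)
  expect_equal(phi_ec(15, 10, bounds22), 1 - exp(-2), tolerance = 1e-12)
  # strictly increasing in |g_k - g|
  g <- 12
  errs <- sapply(c(0, 1, 2, 4, 8), function(e) phi_ec(g + e, g, bounds22))
  expect_true(all(diff(errs) > 0))
  expect_equal(errs, sapply(c(0, 1, 2, 4, 8),
                            function(e) phi_ec(g - e, g, bounds22)))
  expect_error(phi_ec(1, 1, list(dx = c(-1, 1), dy = c(0, 0))), "normalizer")
})

test_that("alignment cost is linear and vanishes when centers align", {
  expect_equal(phi_ac(100, 0, 100, bounds22), 0)
  expect_equal(phi_ac(100, 5, 100, bounds22), 5 / 15)
  expect_equal(phi_ac(95, 5, 100, bounds22), 0)  # shift restores alignment
})

test_that("translation cost is the normalized Manhattan shift", {
  expect_equal(phi_tc(c(0, 0), bounds22), 0)
  expect_equal(phi_tc(c(15, 10), bounds22), 1)
  expect_equal(phi_tc(c(-15, 10), bounds22), 1)
  b <- list(dx = c(-10, 10), dy = c(-10, 10))
  expect_equal(phi_tc(c(3, 4), b), 0.35)
})

test_that("edge cost reads the border row/column vegetation", {
  ones <- veg_image(matrix(1, 10, 10))
  zeros <- veg_image(matrix(0, 10, 10))
  r <- pixel_rect(2, 2, 8, 8)
  expect_equal(phi_edc(ones, r, 1, 1), 0)
  expect_equal(phi_edc(zeros, r, 0.3, 0.6), 0.9)
  # 4x4 ones except a zero last column: c_min = 0, r_min = 0.75
  m <- matrix(1, 4, 4); m[, 4] <- 0
  img <- veg_image(m)
  expect_equal(phi_edc(img, pixel_rect(0, 0, 4, 4), 1, 1), 1.25)
  expect_error(phi_edc(ones, pixel_rect(0.2, 0, 0.3, 4), 1, 1), "zero area")
})

test_that("cost components stay inside their ranges on random inputs", {
  set.seed(21)
  img <- veg_image(matrix(runif(400), 20, 20))
  for (i in 1:1000) {
    b <- list(dx = sort(runif(2, -20, 20)), dy = sort(runif(2, -20, 20)))
    if (max(abs(b$dx)) == 0 || max(abs(b$dy)) == 0) next
    ec <- phi_ec(runif(1, 0, 40), runif(1, 1, 20), b)
    expect_gte(ec, 0); expect_lte(ec, 1)  # ==1 only at underflow of exp(-4*gbar)
    ac <- phi_ac(runif(1, 0, 20), runif(1, b$dx[1], b$dx[2]), runif(1, 0, 20), b)
    expect_gte(ac, 0); expect_lt(ac, 1)
    tc <- phi_tc(c(runif(1, b$dx[1], b$dx[2]), runif(1, b$dy[1], b$dy[2])), b)
    expect_gte(tc, 0); expect_lte(tc, 1)
    w4 <- runif(1); w5 <- runif(1)
    edc <- phi_edc(img, random_int_rect(18, 18), w4, w5)
    expect_gte(edc, 0); expect_lte(edc, w4 + w5 + 1e-12)
  }
})

test_that("the composite objective is zero for a perfectly placed plot", {
  fld <- toy_field(offset = c(0, 0), seed = 2)
  map <- scale_map(fld$map, fld$scale)
  # place the map exactly on the (binary, un-blurred) truth
  img <- binary_field_image(fld$image$h, fld$image$w,
                            map_rects_for_test(fld$truth))
  g <- attr(map, "gap_y")
  i <- which(map$column == 1 & map$row == 2)
  p <- which(map$column == 1 & map$row == 1)
  cur <- pixel_rect(fld$truth$x_min[i], fld$truth$y_min[i],
                    fld$truth$x_max[i], fld$truth$y_max[i])
  prev <- pixel_rect(fld$truth$x_min[p], fld$truth$y_min[p],
                     fld$truth$x_max[p], fld$truth$y_max[p])
  ctx <- plot_context(cur, prev, g, list(dx = c(-g, g), dy = c(-g, g)))
  expect_equal(plot_objective(img, ctx, c(0, 0), weights_canola()), 0)
  # moving to a bound corner costs the TC term plus spacing/alignment
  w <- weight_vector(c(1, 1, 1, 1, 0, 0))
  off <- plot_objective(binary_field_image(fld$image$h, fld$image$w,
                                           list(pixel_rect(0, 0, fld$image$w,
                                                           fld$image$h))),
                        ctx, c(g, g), w)
  expect_equal(off, 1 * phi_ec(g + g, g, ctx$bounds) +
                 phi_ac(rect_center(cur)[["x"]], g,
                        rect_center(prev)[["x"]], ctx$bounds) + 1)
})

test_that("warp observed in the previous column propagates to the start rect", {
  start <- pixel_rect(50, 100, 90, 112)
  prev_init <- pixel_rect(0, 100, 40, 112)
  # neighbour optimized 6 px lower, plot height 40 -> shift applied
  shifted <- update_initial_points(start, translate_rect(prev_init, c(0, 6)),
                                   prev_init, g_hm = 40)
  expect_equal(shifted[["y_min"]], 106)
  # zero displacement -> unchanged
  expect_equal(update_initial_points(start, prev_init, prev_init, 40), start)
  # displacement beyond half the plot height -> not applied
  big <- update_initial_points(start, translate_rect(prev_init, c(0, 24)),
                               prev_init, g_hm = 40)
  expect_equal(big, start)
  expect_error(update_initial_points(start, NULL, prev_init, 40), "previous")
})

test_that("vertical overlaps with the neighbour above are resolved", {
  prev <- pixel_rect(0, 0, 10, 40)
  cur <- pixel_rect(0, 35, 10, 75)   # overlap 5, drifted up (d = 35 - 40 < g)
  r <- resolve_overlap(cur, prev, g = 10)
  expect_equal(unclass(r$current), unclass(pixel_rect(0, 40, 10, 80)))
  # disjoint and touching rects unchanged
  apart <- pixel_rect(0, 50, 10, 90)
  expect_equal(resolve_overlap(apart, prev, 10)$current, apart)
  touch <- pixel_rect(0, 40, 10, 80)
  expect_equal(resolve_overlap(touch, prev, 10)$current, touch)
  # neighbour drifted down into the current plot (its initial bottom was
  # far above the current top) -> current moves up
  r2 <- resolve_overlap(pixel_rect(0, 35, 10, 75), prev, g = 10,
                        prev_initial_bottom = 20)
  expect_equal(r2$current[["y_min"]], 30)
})

test_that("per-plot refinement keeps a zero-warp field in place", {
  fld <- toy_field(offset = c(6, 4), seed = 4)
  aligned <- scale_map(fld$map, fld$scale)
  aligned$x_min <- fld$truth$x_min; aligned$x_max <- fld$truth$x_max
  aligned$y_min <- fld$truth$y_min; aligned$y_max <- fld$truth$y_max
  s3 <- optimize_all_plots(fld$image, aligned, weights_canola(), fast_de(6))
  expect_lt(max(abs(as.matrix(s3$map[, c("x_min", "y_min", "x_max", "y_max")]) -
                    as.matrix(aligned[, c("x_min", "y_min", "x_max", "y_max")]))), 1)
  # dimensions unchanged, no same-column vertical overlaps
  expect_equal(s3$map$x_max - s3$map$x_min, aligned$x_max - aligned$x_min,
               tolerance = 1e-9)
  for (cc in unique(s3$map$column)) {
    sub <- s3$map[s3$map$column == cc, ]
    sub <- sub[order(sub$y_min), ]
    expect_true(all(head(sub$y_max, -1) <= tail(sub$y_min, -1) + 1e-9))
  }
  expect_equal(s3$total_objective, sum(s3$objectives))
})

test_that("refinement recovers jittered plots and tolerates missing ones", {
  fld <- generate_field(field_preset("toy", n_rows = 3, n_cols = 2,
                                     global_offset = c(0, 0), seed = 8))
  aligned <- scale_map(fld$map, fld$scale)
  aligned$x_min <- fld$truth$x_min; aligned$x_max <- fld$truth$x_max
  aligned$y_min <- fld$truth$y_min; aligned$y_max <- fld$truth$y_max
  g <- attr(aligned, "gap_y")
  jit <- aligned
  set.seed(10)
  jx <- runif(nrow(jit), -0.4, 0.4) * g
  jy <- runif(nrow(jit), -0.3, 0.3) * g
  jit$x_min <- jit$x_min + jx; jit$x_max <- jit$x_max + jx
  jit$y_min <- jit$y_min + jy; jit$y_max <- jit$y_max + jy
  s3 <- optimize_all_plots(fld$image, jit, weights_canola(), fast_de(9))
  rep <- match_and_score(s3$map, fld$truth)
  expect_true(all(rep$per_plot$dsc >= 0.9))

  # a missing (unsown) plot leaves its neighbours' recovery intact
  fld2 <- toy_field(offset = c(5, 3), seed = 6, missing_fraction = 0.2)
  res <- localize(fld2$image, fld2$map, fld2$scale, config = fast_de(12),
                  restarts = 1)
  rep2 <- match_and_score(res$plots, fld2$truth)
  present <- !fld2$truth$missing
  expect_true(any(!present))  # the draw did remove at least one plot
  expect_true(all(rep2$per_plot$dsc[present] >= 0.95))
})
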