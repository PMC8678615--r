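#' Objective weights for the per-microplot refinement
#'
#' The composite per-plot objective has six weights `w0..w5`, each in
#' `[0, 1]`: `w0` scales the vegetation-overlap term, `w1` the
#' even-spacing cost, `w2` the alignment cost, `w3` the translation cost,
#' and `w4`, `w5` the column-edge and row-edge components of the edge
#' cost.  Two reference vectors are shipped, tuned for a canola trial
#' (large inter-column gaps, ExG index) and a wheat trial (severe
#' stitching warp, NDVI index).
#'
#' @param w Numeric vector of length 6 (`w0..w5`), all in `[0, 1]`.
#' @return A named numeric vector of class `weight_vector`.
#' @export
weight_vector <- function(w) {
  w <- as.numeric(w)
  if (length(w) != 6 || any(!is.finite(w)) || any(w < 0) || any(w > 1))
    stop("weight_vector: need 6 finite weights in [0, 1]")
  structure(stats::setNames(w, paste0("w", 0:5)), class = "weight_vector")
}

#' @rdname weight_vector
#' @export
weights_canola <- function() {
  weight_vector(c(0.639, 0.627, 0.520, 0.0118, 0.0138, 0.624))
}

#' @rdname weight_vector
#' @export
weights_wheat <- function() {
  weight_vector(c(0.976, 0.873, 0.975, 0.0918, 0.421, 0.822))
}

#' Even-spacing cost
#'
#' Penalizes deviation of the vertical gap `g_k` between a plot and its
#' already-optimized neighbour above from the expected gap `g`:
#' `phi_EC = 1 - exp(-4 * |g_k - g| / max(|dy_min|, |dy_max|))`.  The
#' exponential shape makes small spacing errors already costly.
#'
#' @param g_k Current vertical gap (pixels) at the candidate translation.
#' @param g Expected gap from the layout (pixels).
#' @param bounds Stage search bounds: `list(dx = c(min, max), dy = c(min, max))`.
#' @return Cost in `[0, 1)`; 0 iff `g_k == g`.
#' @export
phi_ec <- function(g_k, g, bounds) {
  norm <- max(abs(bounds$dy))
  if (norm <= 0) stop("phi_ec: degenerate dy bounds (zero normalizer)")
  gbar <- abs(g_k - g) / norm
  1 - exp(-4 * gbar)
}

#' Alignment cost
#'
#' Penalizes horizontal misalignment of the shifted plot center against
#' the center of the previously optimized plot above it in the column:
#' `|x_cur + dx - x_prev| / (max(|dx_min|, |dx_max|) + |x_cur - x_prev|)`.
#' The cost is linear in the misalignment; 0 iff the shifted centers
#' align.
#'
#' @param x_center_current Pre-shift horizontal center of the current plot.
#' @param dx Horizontal component of the candidate translation.
#' @param x_center_prev Horizontal center of the previous plot in the column.
#' @param bounds Stage search bounds (see [phi_ec()]).
#' @return Cost in `[0, 1)`.
#' @export
phi_ac <- function(x_center_current, dx, x_center_prev, bounds) {
  den <- max(abs(bounds$dx)) + abs(x_center_current - x_center_prev)
  if (den <= 0) stop("phi_ac: zero normalizer")
  abs(x_center_current + dx - x_center_prev) / den
}

#' Translation cost
#'
#' The normalized Manhattan length of the candidate shift:
#' `(|dx| + |dy|) / (max(|dx_min|, |dx_max|) + max(|dy_min|, |dy_max|))`.
#' Minimized at `t = (0, 0)`, which keeps well-placed plots in place and
#' breaks ties on flat vegetation.
#'
#' @param t Translation `c(dx, dy)`.
#' @param bounds Stage search bounds (see [phi_ec()]).
#' @return Cost in `[0, 1]`.
#' @export
phi_tc <- function(t, bounds) {
  den <- max(abs(bounds$dx)) + max(abs(bounds$dy))
  if (den <= 0) stop("phi_tc: zero normalizer")
  (abs(t[1]) + abs(t[2])) / den
}

#' Edge cost
#'
#' Discourages placements whose border rows or columns hang over soil.
#' With `M` the vegetation-index subimage under the rasterized rectangle
#' (height `h`, width `w`), the smallest normalized column sum
#' `c_min = min_j (1/h) sum_i M_ij` and row sum
#' `r_min = min_i (1/w) sum_j M_ij` give
#' `phi_EdC = w4 * (1 - c_min) + w5 * (1 - r_min)`.  A rectangle entirely
#' outside the image is treated as fully on soil (maximum cost).
#'
#' @param img A [veg_image()].
#' @param rect A [pixel_rect()].
#' @param w4,w5 Edge-cost weights.
#' @return Cost in `[0, w4 + w5]`.
#' @export
phi_edc <- function(img, rect, w4, w5) {
  b <- rect_raster(rect)
  if (b[["x1"]] <= b[["x0"]] || b[["y1"]] <= b[["y0"]])
    stop("phi_edc: rectangle rasterizes to zero area")
  x0 <- max(b[["x0"]], 0); x1 <- min(b[["x1"]], img$w)
  y0 <- max(b[["y0"]], 0); y1 <- min(b[["y1"]], img$h)
  if (x0 >= x1 || y0 >= y1) return(w4 + w5)
  M <- img$values[(y0 + 1):y1, (x0 + 1):x1, drop = FALSE]
  c_min <- min(.colMeans(M, nrow(M), ncol(M)))
  r_min <- min(.rowMeans(M, nrow(M), ncol(M)))
  w4 * (1 - c_min) + w5 * (1 - r_min)
}

#' Context of one microplot during the per-plot refinement
#'
#' Bundles what the composite objective needs to know about a plot: its
#' starting rectangle, the already-optimized plot above it in the column
#' (if any), the vertical gap between them before this plot's
#' optimization, the expected layout gap, and the stage search bounds.
#'
#' @param current_rect Starting `pixel_rect` of the plot.
#' @param prev_rect Optimized `pixel_rect` of the plot above in the same
#'   column, or `NULL` for the top of a column.
#' @param expected_gap Nominal within-column gap `g` (pixels).
#' @param bounds `list(dx = c(min, max), dy = c(min, max))`.
#' @return A `plot_context` list; `g_i_local` (the pre-optimization gap)
#'   is derived from the rectangles.
#' @export
plot_context <- function(current_rect, prev_rect = NULL, expected_gap, bounds) {
  structure(list(
    current_rect = current_rect,
    prev_rect = prev_rect,
    g_i_local = if (is.null(prev_rect)) NA_real_
                else current_rect[["y_min"]] - prev_rect[["y_max"]],
    expected_gap = expected_gap,
    bounds = bounds), class = "plot_context")
}

#' Composite per-microplot objective
#'
#' The refinement cost minimized for each plot:
#' `w0 * (1 - phi_veg) + w1 * phi_EC + w2 * phi_AC + w3 * phi_TC + phi_EdC`,
#' evaluated at the translated rectangle.  Plots at the top of a column
#' have no optimized neighbour above, so the even-spacing and alignment
#' terms are skipped for them.
#'
#' @param img A [veg_image()].
#' @param ctx A [plot_context()].
#' @param t Candidate translation `c(dx, dy)`.
#' @param w A [weight_vector()].
#' @return Non-negative finite cost.
#' @export
plot_objective <- function(img, ctx, t, w) {
  rect_t <- translate_rect(ctx$current_rect, t)
  cost <- w[1] * (1 - phi_veg(img, rect_t))
  if (!is.null(ctx$prev_rect)) {
    g_k <- ctx$g_i_local + t[2]
    cost <- cost + w[2] * phi_ec(g_k, ctx$expected_gap, ctx$bounds)
    cost <- cost + w[3] * phi_ac(rect_center(ctx$current_rect)[["x"]], t[1],
                                 rect_center(ctx$prev_rect)[["x"]], ctx$bounds)
  }
  unname(cost + w[4] * phi_tc(t, ctx$bounds) + phi_edc(img, rect_t, w[5], w[6]))
}

#' Propagate observed warp to a plot's starting position
#'
#' Before optimizing a plot (not in the first column and not at the top
#' of its column), the vertical displacement `g_d` observed at the
#' same-row plot of the previously optimized column — its optimized
#' bottom minus its pre-refinement bottom — is applied to the current
#' plot's starting rectangle, provided `|g_d| <= g_hm / 2` (half the plot
#' height).  Larger apparent displacements are more likely to mean the
#' neighbour snapped to a different plot, so the start is left unchanged.
#'
#' @param start_rect The plot's starting `pixel_rect`.
#' @param prev_col_final Optimized rect of the same-row plot in the
#'   previous column.
#' @param prev_col_initial That plot's rect before the per-plot stage.
#' @param g_hm Nominal plot height (pixels).
#' @return The (possibly shifted) starting rectangle.
#' @export
update_initial_points <- function(start_rect, prev_col_final,
                                  prev_col_initial, g_hm) {
  if (is.null(prev_col_final) || is.null(prev_col_initial))
    stop("update_initial_points: previous-column information required")
  g_d <- prev_col_final[["y_max"]] - prev_col_initial[["y_max"]]
  if (abs(g_d) <= g_hm / 2) translate_rect(start_rect, c(0, g_d))
  else start_rect
}

#' Refine one microplot position
#'
#' Minimizes [plot_objective()] over the stage search box with
#' differential evolution; the zero translation is seeded into the
#' initial population so a perfect starting placement cannot be degraded.
#'
#' @param img A [veg_image()].
#' @param ctx A [plot_context()].
#' @param w A [weight_vector()].
#' @param config A [de_config()].
#' @return `list(rect, t, value)`: the refined rectangle, the optimal
#'   shift and the objective value.
#' @export
optimize_plot <- function(img, ctx, w, config = de_config()) {
  fit <- de_minimize(function(t) plot_objective(img, ctx, t, w),
                     lower = c(ctx$bounds$dx[1], ctx$bounds$dy[1]),
                     upper = c(ctx$bounds$dx[2], ctx$bounds$dy[2]),
                     config = config, init = rbind(c(0, 0)))
  list(rect = translate_rect(ctx$current_rect, fit$par),
       t = fit$par, value = fit$value)
}

#' Remove a vertical overlap between a plot and its neighbour above
#'
#' If the optimized plot overlaps the already-optimized plot above it by
#' `dO = y_max(prev) - y_min(current) > 0`, the current plot is shifted
#' vertically by `dO`: downwards when the pre-resolution distance `d`
#' between the current plot's top and the neighbour's pre-refinement
#' bottom is at most the expected gap `g` (the current plot drifted up
#' into its neighbour), upwards otherwise (the neighbour drifted down).
#' Touching or disjoint plots are returned unchanged.
#'
#' @param current Optimized `pixel_rect` of the current plot.
#' @param prev Optimized `pixel_rect` of the plot above it.
#' @param g Expected within-column gap (pixels).
#' @param prev_initial_bottom The neighbour's bottom edge before its own
#'   refinement; defaults to its current bottom.
#' @return `list(current, prev)` with disjoint y-extents.
#' @export
resolve_overlap <- function(current, prev, g,
                            prev_initial_bottom = prev[["y_max"]]) {
  dO <- prev[["y_max"]] - current[["y_min"]]
  if (dO <= 0) return(list(current = current, prev = prev))
  d <- current[["y_min"]] - prev_initial_bottom
  shift <- if (d <= g) dO else -dO
  list(current = translate_rect(current, c(0, shift)), prev = prev)
}

# internal: per-plot search bounds under a profile
plot_bounds <- function(g, profile, first_row_or_col) {
  if (profile == "severe-warp" && !first_row_or_col)
    list(dx = c(-g, g), dy = c(-g / 2, g / 2))
  else
    list(dx = c(-g, g), dy = c(-g, g))
}

#' Stage 3: refine every microplot
#'
#' Traverses the map column-major (columns left to right, plots top to
#' bottom within a column).  For each plot it propagates the warp
#' observed in the previous column ([update_initial_points()]; skipped in
#' the first column and the first row), minimizes the composite objective
#' ([optimize_plot()]), and resolves any vertical overlap with the plot
#' above ([resolve_overlap()]).
#'
#' @param img A [veg_image()].
#' @param map A `microplot_map` in pixels, already through stages 1-2.
#' @param w A [weight_vector()].
#' @param config A [de_config()]; per-plot seeds derive from `config$seed`.
#' @param bounds_profile `"default"` (`dx, dy in [-g, g]` everywhere) or
#'   `"severe-warp"` (`dy in [-g/2, g/2]` outside the first row/column,
#'   for heavily warped orthomosaics).
#' @return `list(map, objectives, total_objective)`: the refined map, the
#'   per-plot objective values (named by `plot_id`), and their sum.
#' @export
optimize_all_plots <- function(img, map, w = weights_canola(),
                               config = de_config(),
                               bounds_profile = c("default", "severe-warp")) {
  bounds_profile <- match.arg(bounds_profile)
  if (attr(map, "units") != "pixels")
    stop("optimize_all_plots: map must be in pixel units")
  w <- weight_vector(w)
  g <- attr(map, "gap_y")
  g_hm <- attr(map, "plot_h")
  cols <- sort(unique(map$column))
  out <- map
  objectives <- stats::setNames(numeric(nrow(map)), map$plot_id)
  # per-plot pre-refinement rects, for warp propagation and overlap tests
  initial <- map
  plot_counter <- 0L
  for (jc in seq_along(cols)) {
    rows_in_col <- which(map$column == cols[jc])
    rows_in_col <- rows_in_col[order(map$row[rows_in_col])]
    prev_i <- NA_integer_
    for (k in seq_along(rows_in_col)) {
      i <- rows_in_col[k]
      plot_counter <- plot_counter + 1L
      start <- df_rect(initial[i, ])
      # warp propagation from the previous column's same-row plot
      if (jc > 1 && k > 1) {
        pc <- which(map$column == cols[jc - 1] & map$row == map$row[i])
        if (length(pc) == 1) {
          start <- update_initial_points(start,
                                         df_rect(out[pc, ]),
                                         df_rect(initial[pc, ]),
                                         g_hm)
        }
      }
      first_rc <- (jc == 1 || k == 1)
      bnds <- plot_bounds(g, bounds_profile, first_rc)
      prev_rect <- if (is.na(prev_i)) NULL else df_rect(out[prev_i, ])
      ctx <- plot_context(start, prev_rect, g, bnds)
      cfg <- config
      if (!is.null(config$seed))
        cfg$seed <- derive_seed(config$seed, "plot", plot_counter)
      res <- optimize_plot(img, ctx, w, cfg)
      rect <- res$rect
      if (!is.na(prev_i)) {
        fixed <- resolve_overlap(rect, df_rect(out[prev_i, ]), g,
                                 prev_initial_bottom = initial$y_max[prev_i])
        rect <- fixed$current
      }
      out$x_min[i] <- rect[["x_min"]]; out$x_max[i] <- rect[["x_max"]]
      out$y_min[i] <- rect[["y_min"]]; out$y_max[i] <- rect[["y_max"]]
      objectives[i] <- res$value
      prev_i <- i
    }
  }
  list(map = out, objectives = objectives,
       total_objective = sum(objectives))
}
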