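#' Search bounds for the per-block translation
#'
#' The block translation is searched over `dx in [0, W - map width]`,
#' `dy in [0, H - map height]` for an origin-anchored map: the slack is
#' the image extent minus the extent of *all* microplots including their
#' inter-plot and inter-column spacing.  Every block shares this box, so
#' when a map is split into several blocks each block stays near its
#' nominal position inside the layout instead of wandering to another,
#' similar-looking band of the field.  For a map whose top-left corner is
#' not at the image origin the box is shifted so that admissible
#' translations keep the full extent inside the image.
#'
#' @param img A [veg_image()].
#' @param block_rects List of the block's plot rectangles (pixels).
#' @param extent_rects Rectangles defining the overall extent the bounds
#'   are computed from; defaults to `block_rects` (single-block case) and
#'   is the whole map in [optimize_block()].
#' @return `list(dx = c(min, max), dy = c(min, max))`.
#' @export
block_bounds <- function(img, block_rects, extent_rects = block_rects) {
  hull <- bounding_rect(extent_rects)
  if (rect_width(hull) > img$w || rect_height(hull) > img$h)
    stop("block_bounds: map extent exceeds the image extent")
  list(dx = c(-hull[["x_min"]], img$w - hull[["x_max"]]),
       dy = c(-hull[["y_min"]], img$h - hull[["y_max"]]))
}

#' Stage 1: per-block translation maximizing enclosed vegetation
#'
#' Each block of the scaled map is translated independently to maximize
#' the normalized vegetation overlap [phi_veg()].  Because a grid block's
#' convex hull is a rectangle, the overlap is evaluated over the block's
#' minimal bounding rectangle by default (`objective = "hull"`), which is
#' what makes coarse placement cheap; `objective = "plots"` sums the
#' member plot rectangles instead, for ragged blocks.  The zero
#' translation is seeded into the initial population, so the optimized
#' overlap can never fall below the overlap of the starting placement.
#'
#' @param img A [veg_image()].
#' @param map A `microplot_map` in pixels; the `block` column defines the
#'   block grouping.
#' @param config A [de_config()]; per-block seeds are derived from
#'   `config$seed` so blocks are independent but reproducible.
#' @param objective `"hull"` or `"plots"`.
#' @return The map with every block translated by its optimal shift; an
#'   attribute `"block_shifts"` records the per-block translations.
#' @export
optimize_block <- function(img, map, config = de_config(),
                           objective = c("hull", "plots")) {
  objective <- match.arg(objective)
  if (attr(map, "units") != "pixels")
    stop("optimize_block: map must be in pixel units (see scale_map)")
  blocks <- sort(unique(map$block))
  shifts <- matrix(NA_real_, length(blocks), 2,
                   dimnames = list(blocks, c("dx", "dy")))
  out <- map
  all_rects <- map_rects(map)
  for (bi in seq_along(blocks)) {
    rows <- which(map$block == blocks[bi])
    if (length(rows) == 0) stop("optimize_block: empty block ", blocks[bi])
    rects <- map_rects(map, rows)
    B <- if (objective == "hull") list(bounding_rect(rects)) else rects
    bnds <- block_bounds(img, rects, extent_rects = all_rects)
    cfg <- config
    if (!is.null(config$seed))
      cfg$seed <- derive_seed(config$seed, "block", bi)
    fit <- de_minimize(function(t) 1 - phi_veg(img, B, t),
                       lower = c(bnds$dx[1], bnds$dy[1]),
                       upper = c(bnds$dx[2], bnds$dy[2]),
                       config = cfg,
                       init = rbind(c(0, 0)))
    shifts[bi, ] <- fit$par
    out <- shift_map_rows(out, rows, fit$par)
  }
  attr(out, "block_shifts") <- shifts
  out
}
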