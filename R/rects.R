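#' Axis-aligned pixel rectangle
#'
#' Rectangles are the universal geometric unit of the package: microplots,
#' columns and blocks are all `pixel_rect`s.  Coordinates are real-valued
#' 0-based image coordinates with `x` the column (horizontal) axis and `y`
#' the row (vertical) axis, origin at the top-left of the image.  When a
#' rectangle is rasterized, the covered pixel set is the half-open box
#' `[round(x_min), round(x_max)) x [round(y_min), round(y_max))` with
#' half-up rounding.
#'
#' @param x_min,y_min,x_max,y_max Rectangle corners in pixels (real-valued).
#' @return An object of class `pixel_rect`: a named numeric vector with
#'   elements `x_min`, `y_min`, `x_max`, `y_max`.
#' @examples
#' r <- pixel_rect(0, 0, 10, 5)
#' rect_width(r)   # 10
#' rect_area_px(r) # 50 pixels
#' @export
pixel_rect <- function(x_min, y_min, x_max, y_max) {
  v <- c(x_min = as.numeric(x_min), y_min = as.numeric(y_min),
         x_max = as.numeric(x_max), y_max = as.numeric(y_max))
  if (any(!is.finite(v))) stop("pixel_rect: coordinates must be finite")
  if (v["x_min"] >= v["x_max"] || v["y_min"] >= v["y_max"])
    stop("pixel_rect: requires x_min < x_max and y_min < y_max")
  structure(v, class = "pixel_rect")
}

#' Half-up rounding
#'
#' `round()` in R rounds half to even; rasterization here uses half-up
#' rounding so that pixel membership is stable under translation by whole
#' pixels.
#' @param x Numeric vector.
#' @return `floor(x + 0.5)`.
#' @export
round_half_up <- function(x) floor(x + 0.5)

#' @rdname pixel_rect
#' @param r A `pixel_rect`.
#' @export
rect_width <- function(r) unname(r[["x_max"]] - r[["x_min"]])

#' @rdname pixel_rect
#' @export
rect_height <- function(r) unname(r[["y_max"]] - r[["y_min"]])

#' @rdname pixel_rect
#' @export
rect_center <- function(r) {
  c(x = (r[["x_min"]] + r[["x_max"]]) / 2, y = (r[["y_min"]] + r[["y_max"]]) / 2)
}

#' Rasterized pixel extent of a rectangle
#'
#' @param r A `pixel_rect`.
#' @return Integer vector `c(x0, x1, y0, y1)`: the 0-based half-open pixel
#'   ranges `[x0, x1)` and `[y0, y1)`.
#' @export
rect_raster <- function(r) {
  c(x0 = round_half_up(r[["x_min"]]), x1 = round_half_up(r[["x_max"]]),
    y0 = round_half_up(r[["y_min"]]), y1 = round_half_up(r[["y_max"]]))
}

#' @rdname rect_raster
#' @return `rect_area_px`: the number of pixels covered by the rasterized
#'   rectangle.
#' @export
rect_area_px <- function(r) {
  b <- rect_raster(r)
  max(0, b[["x1"]] - b[["x0"]]) * max(0, b[["y1"]] - b[["y0"]])
}

#' Translate rectangles
#'
#' Shifts one rectangle or a list of rectangles by `t = (dx, dy)`; widths
#' and heights are unchanged.
#'
#' @param rects A `pixel_rect` or a list of them.
#' @param t Numeric length-2 translation `c(dx, dy)` in pixels.
#' @return Object(s) of the same shape, translated.
#' @examples
#' translate_rect(pixel_rect(0, 0, 10, 10), c(5, -2))
#' @export
translate_rect <- function(rects, t) {
  stopifnot(length(t) == 2, all(is.finite(t)))
  shift1 <- function(r) {
    r[c("x_min", "x_max")] <- r[c("x_min", "x_max")] + t[1]
    r[c("y_min", "y_max")] <- r[c("y_min", "y_max")] + t[2]
    r
  }
  if (inherits(rects, "pixel_rect")) shift1(rects) else lapply(rects, shift1)
}

#' Minimal bounding rectangle of a set of rectangles
#'
#' @param rects Non-empty list of `pixel_rect`s.
#' @return A `pixel_rect` enclosing them all.
#' @export
bounding_rect <- function(rects) {
  if (inherits(rects, "pixel_rect")) return(rects)
  if (length(rects) == 0) stop("bounding_rect: empty rectangle set")
  m <- do.call(rbind, rects)
  pixel_rect(min(m[, "x_min"]), min(m[, "y_min"]),
             max(m[, "x_max"]), max(m[, "y_max"]))
}

#' Pixel overlap of two rasterized rectangles
#'
#' @param a,b `pixel_rect`s.
#' @return Number of pixels in the intersection of the rasterized boxes.
#' @export
rect_intersection_px <- function(a, b) {
  ra <- rect_raster(a); rb <- rect_raster(b)
  max(0, min(ra[["x1"]], rb[["x1"]]) - max(ra[["x0"]], rb[["x0"]])) *
    max(0, min(ra[["y1"]], rb[["y1"]]) - max(ra[["y0"]], rb[["y0"]]))
}

#' @export
print.pixel_rect <- function(x, ...) {
  cat(sprintf("<pixel_rect (%.3f, %.3f) -- (%.3f, %.3f)>\n",
              x[["x_min"]], x[["y_min"]], x[["x_max"]], x[["y_max"]]))
  invisible(x)
}

# internal: rect from a one-row data frame with x_min..y_max columns
df_rect <- function(row) {
  pixel_rect(row$x_min, row$y_min, row$x_max, row$y_max)
}
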