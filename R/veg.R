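#' Vegetation-index image
#'
#' A `veg_image` is a single-channel image whose values lie in `[0, 1]`,
#' with larger values on vegetation than on soil, stored as an `h x w`
#' matrix (row = image row `y`, column = image column `x`).  A summed-area
#' table is attached so that rectangular sums — evaluated thousands of
#' times by the optimizer — cost O(1) each.
#'
#' @param values Numeric `h x w` matrix with all values in `[0, 1]`.
#' @return An object of class `veg_image`: `list(values, sat, h, w)`.
#' @export
veg_image <- function(values) {
  if (!is.matrix(values)) stop("veg_image: values must be a matrix")
  if (anyNA(values)) stop("veg_image: ", sum(is.na(values)), " NA pixel(s)")
  if (min(values) < -1e-9 || max(values) > 1 + 1e-9)
    stop("veg_image: values outside [0, 1]; normalize the index first")
  values <- pmin(pmax(values, 0), 1)
  h <- nrow(values); w <- ncol(values)
  sat <- matrix(0, h + 1, w + 1)
  cs <- apply(values, 2, cumsum)
  if (h == 1) cs <- matrix(cs, nrow = 1)
  cs2 <- t(apply(cs, 1, cumsum))
  if (w == 1) cs2 <- matrix(cs, ncol = 1)
  sat[-1, -1] <- cs2
  structure(list(values = values, sat = sat, h = h, w = w),
            class = "veg_image")
}

#' @export
print.veg_image <- function(x, ...) {
  cat(sprintf("<veg_image %d x %d, mean index %.3f>\n", x$h, x$w,
              mean(x$values)))
  invisible(x)
}

#' Excess Green index of an RGB image
#'
#' Converts an RGB orthomosaic to the Excess Green vegetation index in
#' chromatic coordinates: with `r = R/(R+G+B)`, `g = G/(R+G+B)`,
#' `b = B/(R+G+B)`, the index is `2g - r - b`, clipped to `[0, 1]`.
#' Black pixels (`R+G+B = 0`) get index 0.  Clipping rather than min-max
#' rescaling keeps bare soil near 0 regardless of scene content, which the
#' overlap objective relies on.
#'
#' @param rgb Numeric `h x w x 3` array of non-negative channel values
#'   (any common scale; chromatic coordinates are scale-free).
#' @return A [veg_image()].
#' @examples
#' px <- array(c(0, 255, 0), dim = c(1, 1, 3))
#' excess_green(px)$values  # pure green -> 1
#' @export
excess_green <- function(rgb) {
  if (length(dim(rgb)) != 3 || dim(rgb)[3] < 3)
    stop("excess_green: expected an h x w x 3 array")
  if (min(rgb, na.rm = TRUE) < 0) stop("excess_green: negative channel values")
  R <- rgb[, , 1]; G <- rgb[, , 2]; B <- rgb[, , 3]
  s <- R + G + B
  s[s == 0] <- Inf  # black pixel -> all chromatic coords 0 -> index 0
  exg <- (2 * G - R - B) / s
  dim(exg) <- dim(rgb)[1:2]  # single-row/column slices drop to vectors
  veg_image(pmin(pmax(exg, 0), 1))
}

#' Normalize a single-channel index image into [0, 1]
#'
#' For `kind = "ndvi"` input values in `[-1, 1]` have their negative part
#' (water, bare soil) clipped to 0; for `kind = "unit"` the image is
#' asserted to already be in `[0, 1]` (values within a small tolerance are
#' clipped).
#'
#' @param raw Numeric matrix.
#' @param kind `"ndvi"` or `"unit"`.
#' @return A [veg_image()].
#' @export
normalize_index <- function(raw, kind = c("unit", "ndvi")) {
  kind <- match.arg(kind)
  if (!is.matrix(raw)) stop("normalize_index: raw must be a matrix")
  if (anyNA(raw)) stop("normalize_index: ", sum(is.na(raw)), " NA pixel(s)")
  if (kind == "ndvi") {
    if (min(raw) < -1 - 1e-9 || max(raw) > 1 + 1e-9)
      stop("normalize_index: NDVI values outside [-1, 1]")
    veg_image(pmax(raw, 0))
  } else {
    if (min(raw) < -1e-6 || max(raw) > 1 + 1e-6)
      stop("normalize_index: values outside [0, 1]; not a unit-range index")
    veg_image(pmin(pmax(raw, 0), 1))
  }
}

#' Read an orthomosaic raster
#'
#' Reads a PNG or TIFF raster.  Multi-channel images are converted with
#' [excess_green()] (channel order R, G, B in the first three channels);
#' single-channel images are treated as an already-computed vegetation
#' index and passed through [normalize_index()].
#'
#' @param path Raster path (`.png`, `.tif`, `.tiff`).
#' @param kind Index interpretation for single-channel input: `"unit"` or
#'   `"ndvi"`.
#' @return A [veg_image()].
#' @export
read_ortho <- function(path, kind = c("unit", "ndvi")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("read_ortho: no such file: ", path)
  ext <- tolower(tools::file_ext(path))
  arr <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("read_ortho: unsupported raster format: .", ext))
  if (length(dim(arr)) == 3 && dim(arr)[3] >= 3) excess_green(arr[, , 1:3])
  else normalize_index(if (length(dim(arr)) == 3) arr[, , 1] else arr, kind)
}

#' Sum of the vegetation index over a rectangle
#'
#' The rectangle is rasterized (half-open, half-up rounding), intersected
#' with the image bounds, and the index values summed via the summed-area
#' table.  A rectangle fully outside the image sums to 0.
#'
#' @param img A [veg_image()].
#' @param rect A [pixel_rect()].
#' @return The sum (a scalar).
#' @export
region_sum <- function(img, rect) {
  b <- rect_raster(rect)
  x0 <- max(b[["x0"]], 0); x1 <- min(b[["x1"]], img$w)
  y0 <- max(b[["y0"]], 0); y1 <- min(b[["y1"]], img$h)
  if (x0 >= x1 || y0 >= y1) return(0)
  # sat[i+1, j+1] holds the sum over 0-based pixel rows 0..i-1, cols 0..j-1
  img$sat[y1 + 1, x1 + 1] - img$sat[y0 + 1, x1 + 1] -
    img$sat[y1 + 1, x0 + 1] + img$sat[y0 + 1, x0 + 1]
}

# internal fast path: region sum from raw raster bounds c(x0,x1,y0,y1)
region_sum_raster <- function(img, x0, x1, y0, y1) {
  x0 <- max(x0, 0); x1 <- min(x1, img$w)
  y0 <- max(y0, 0); y1 <- min(y1, img$h)
  if (x0 >= x1 || y0 >= y1) return(0)
  img$sat[y1 + 1, x1 + 1] - img$sat[y0 + 1, x1 + 1] -
    img$sat[y1 + 1, x0 + 1] + img$sat[y0 + 1, x0 + 1]
}

#' Normalized vegetation overlap of a set of rectangles
#'
#' The stage objective of the localization algorithm: the sum of the
#' vegetation index under all (translated) rectangles, divided by the
#' number of pixels the rasterized rectangles themselves enclose.  Pixels
#' pushed outside the image contribute zero vegetation but still count in
#' the area, so translations that move plots off the image are penalized.
#' With an index in `[0, 1]` and in-bounds rectangles the value lies in
#' `[0, 1]`.
#'
#' @param img A [veg_image()].
#' @param rects A `pixel_rect` or non-empty list of them.
#' @param t Translation `c(dx, dy)` applied to every rectangle
#'   (default no shift).
#' @return The normalized overlap (scalar).
#' @export
phi_veg <- function(img, rects, t = c(0, 0)) {
  if (inherits(rects, "pixel_rect")) rects <- list(rects)
  if (length(rects) == 0) stop("phi_veg: empty rectangle set")
  total <- 0; area <- 0
  for (r in rects) {
    x0 <- round_half_up(r[["x_min"]] + t[1]); x1 <- round_half_up(r[["x_max"]] + t[1])
    y0 <- round_half_up(r[["y_min"]] + t[2]); y1 <- round_half_up(r[["y_max"]] + t[2])
    area <- area + max(0, x1 - x0) * max(0, y1 - y0)
    total <- total + region_sum_raster(img, x0, x1, y0, y1)
  }
  if (area == 0) stop("phi_veg: rectangles rasterize to zero area")
  total / area
}
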