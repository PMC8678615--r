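#' Microplot map: the to-scale field layout
#'
#' A `microplot_map` holds the known trial layout: one rectangle per
#' microplot, grouped into columns and blocks, together with the nominal
#' gaps of the design.  It is stored as a data frame with one row per plot
#' and columns `plot_id`, `block`, `column`, `row`, `x_min`, `y_min`,
#' `x_max`, `y_max`, where `column` is the global column index (shared
#' across blocks that are stacked vertically) and `row` is the top-to-bottom
#' position within the column.  Plot ids enumerate plots column-major:
#' down the first column, then down the second, and so on.
#'
#' Units are either `"meters"` (as drawn from the trial design, origin at
#' the top-left-most plot corner) or `"pixels"` (after [scale_map()]).
#'
#' @param plots Data frame with the columns listed above (`plot_id` may be
#'   absent and is then assigned column-major).
#' @param units `"meters"` or `"pixels"`.
#' @param gap_y Nominal vertical gap between adjacent plots in a column
#'   (same units as coordinates).
#' @param gap_x Nominal horizontal gap between adjacent columns.
#' @param plot_w,plot_h Nominal plot width and height; defaults are the
#'   medians of the rectangle dimensions.
#' @return An object of class `microplot_map` (a data frame with layout
#'   attributes).
#' @seealso [load_map()], [scale_map()], [column_bounding_box()]
#' @export
microplot_map <- function(plots, units = c("meters", "pixels"),
                          gap_y, gap_x, plot_w = NULL, plot_h = NULL) {
  units <- match.arg(units)
  need <- c("block", "column", "row", "x_min", "y_min", "x_max", "y_max")
  if (!all(need %in% names(plots)))
    stop("microplot_map: plots must have columns ",
         paste(setdiff(need, names(plots)), collapse = ", "))
  plots <- plots[order(plots$column, plots$y_min), , drop = FALSE]
  if (is.null(plots$plot_id) || all(is.na(plots$plot_id)))
    plots$plot_id <- seq_len(nrow(plots))
  rownames(plots) <- NULL
  if (is.null(plot_w)) plot_w <- stats::median(plots$x_max - plots$x_min)
  if (is.null(plot_h)) plot_h <- stats::median(plots$y_max - plots$y_min)
  out <- structure(plots,
                   units = units, gap_y = gap_y, gap_x = gap_x,
                   plot_w = plot_w, plot_h = plot_h,
                   class = c("microplot_map", "data.frame"))
  validate_map(out)
  out
}

#' Validate a microplot map
#'
#' Checks the structural invariants: positive-size rectangles, unique
#' column-major plot ids, within-column vertical ordering without overlap,
#' and globally disjoint rasterized plots.
#'
#' @param map A `microplot_map`.
#' @return `map`, invisibly; stops with a descriptive error on violation.
#' @export
validate_map <- function(map) {
  if (anyDuplicated(map$plot_id))
    stop("microplot_map: duplicated plot_id(s): ",
         paste(unique(map$plot_id[duplicated(map$plot_id)]), collapse = ", "))
  if (any(map$x_min >= map$x_max) || any(map$y_min >= map$y_max))
    stop("microplot_map: degenerate rectangle (x_min >= x_max or y_min >= y_max)")
  for (cc in unique(map$column)) {
    sub <- map[map$column == cc, , drop = FALSE]
    sub <- sub[order(sub$y_min), , drop = FALSE]
    if (nrow(sub) > 1) {
      if (any(utils::head(sub$y_max, -1) > utils::tail(sub$y_min, -1) + 1e-9))
        stop(sprintf("microplot_map: plots overlap vertically in column %s", cc))
    }
  }
  # pairwise disjointness of rasterized plots (columns already checked
  # vertically; cross-column pairs can only collide horizontally)
  n <- nrow(map)
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      j <- which(map$x_min[(i + 1):n] < map$x_max[i] &
                 map$x_max[(i + 1):n] > map$x_min[i] &
                 map$y_min[(i + 1):n] < map$y_max[i] &
                 map$y_max[(i + 1):n] > map$y_min[i]) + i
      for (jj in j) {
        if (rect_intersection_px(df_rect(map[i, ]), df_rect(map[jj, ])) > 0)
          stop(sprintf("microplot_map: plots %s and %s overlap",
                       map$plot_id[i], map$plot_id[jj]))
      }
    }
  }
  invisible(map)
}

#' @export
print.microplot_map <- function(x, ...) {
  cat(sprintf("<microplot_map: %d plots, %d columns, %d blocks, units=%s>\n",
              nrow(x), length(unique(x$column)), length(unique(x$block)),
              attr(x, "units")))
  invisible(x)
}

#' Read a microplot layout file
#'
#' The layout file is JSON with keys `units`, `gap_within_column`,
#' `gap_between_columns`, and `blocks`; each block is a list of columns and
#' each column a list of `{id, x_min, y_min, x_max, y_max}` records (the
#' `id` may be omitted, in which case ids are assigned column-major).
#' Columns from different blocks that occupy the same horizontal span are
#' merged into one global column, so that row-wise blocks (stacked
#' vertically) share column indices across blocks.
#'
#' @param path Path to a layout JSON file.
#' @return A `microplot_map` (usually in meters).
#' @export
load_map <- function(path) {
  if (!file.exists(path)) stop("load_map: no such file: ", path)
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  for (key in c("units", "gap_within_column", "gap_between_columns", "blocks"))
    if (is.null(doc[[key]])) stop("load_map: layout file missing key '", key, "'")
  rows <- list()
  col_spans <- list()  # per block-column horizontal span, for global indexing
  k <- 0L
  for (bi in seq_along(doc$blocks)) {
    blk <- doc$blocks[[bi]]
    cols <- if (!is.null(blk$columns)) blk$columns else blk
    for (ci in seq_along(cols)) {
      col <- cols[[ci]]
      if (length(col) == 0) stop("load_map: empty column in block ", bi)
      for (pi in seq_along(col)) {
        p <- col[[pi]]
        for (f in c("x_min", "y_min", "x_max", "y_max"))
          if (is.null(p[[f]]) || !is.numeric(p[[f]]))
            stop(sprintf("load_map: malformed plot record (block %d, column %d, plot %d): missing numeric '%s'",
                         bi, ci, pi, f))
        k <- k + 1L
        rows[[k]] <- data.frame(
          plot_id = if (is.null(p$id)) NA else p$id,
          block = bi, block_col = ci,
          x_min = p$x_min, y_min = p$y_min, x_max = p$x_max, y_max = p$y_max)
      }
      xs <- range(vapply(col, function(p) c(p$x_min, p$x_max), numeric(2)))
      col_spans[[length(col_spans) + 1L]] <-
        data.frame(block = bi, block_col = ci, x_lo = xs[1], x_hi = xs[2])
    }
  }
  plots <- do.call(rbind, rows)
  spans <- do.call(rbind, col_spans)
  # global column index: block-columns whose spans overlap belong to the
  # same field column (vertically stacked blocks); otherwise they are
  # distinct columns ordered left to right.
  spans <- spans[order(spans$x_lo), , drop = FALSE]
  gcol <- integer(nrow(spans)); cur <- 0L; hi <- -Inf
  for (i in seq_len(nrow(spans))) {
    if (spans$x_lo[i] >= hi - 1e-9) { cur <- cur + 1L; hi <- spans$x_hi[i] }
    else hi <- max(hi, spans$x_hi[i])
    gcol[i] <- cur
  }
  spans$column <- gcol
  plots <- merge(plots, spans[, c("block", "block_col", "column")],
                 by = c("block", "block_col"), sort = FALSE)
  plots$block_col <- NULL
  plots <- plots[order(plots$column, plots$y_min), , drop = FALSE]
  plots$row <- stats::ave(seq_len(nrow(plots)), plots$column,
                          FUN = seq_along)
  if (anyNA(plots$plot_id)) plots$plot_id <- seq_len(nrow(plots))
  microplot_map(plots, units = doc$units,
                gap_y = doc$gap_within_column,
                gap_x = doc$gap_between_columns)
}

#' Write a microplot layout file
#'
#' Inverse of [load_map()]: serializes a map to the JSON layout schema.
#'
#' @param map A `microplot_map`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_map <- function(map, path) {
  blocks <- lapply(split(seq_len(nrow(map)), map$block), function(ix) {
    sub <- map[ix, , drop = FALSE]
    cols <- lapply(split(seq_len(nrow(sub)), sub$column), function(jx) {
      s <- sub[jx, , drop = FALSE]
      s <- s[order(s$y_min), , drop = FALSE]
      lapply(seq_len(nrow(s)), function(i)
        list(id = s$plot_id[i], x_min = s$x_min[i], y_min = s$y_min[i],
             x_max = s$x_max[i], y_max = s$y_max[i]))
    })
    list(columns = unname(cols))
  })
  doc <- list(units = attr(map, "units"),
              gap_within_column = attr(map, "gap_y"),
              gap_between_columns = attr(map, "gap_x"),
              blocks = unname(blocks))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Pixels-per-meter scale of an orthomosaic
#'
#' @param sx,sy Horizontal and vertical scale in pixels per meter (> 0).
#' @return A `scale_spec` object.
#' @export
scale_spec <- function(sx, sy = sx) {
  if (!is.finite(sx) || !is.finite(sy) || sx <= 0 || sy <= 0)
    stop("scale_spec: scales must be positive and finite")
  structure(list(sx = sx, sy = sy), class = "scale_spec")
}

#' Scale a map from meters into image pixel coordinates
#'
#' Multiplies every horizontal coordinate by `sx` and every vertical
#' coordinate by `sy` (pixels per meter); nominal gaps and plot dimensions
#' are scaled likewise.  Ordering, grouping and ids are preserved.
#'
#' @param map A `microplot_map` in meters.
#' @param scale A [scale_spec()].
#' @return The map in pixel units.
#' @export
scale_map <- function(map, scale) {
  stopifnot(inherits(scale, "scale_spec"))
  if (attr(map, "units") != "meters")
    stop("scale_map: map is already in pixel units")
  out <- map
  out$x_min <- map$x_min * scale$sx
  out$x_max <- map$x_max * scale$sx
  out$y_min <- map$y_min * scale$sy
  out$y_max <- map$y_max * scale$sy
  attr(out, "units") <- "pixels"
  attr(out, "gap_y") <- attr(map, "gap_y") * scale$sy
  attr(out, "gap_x") <- attr(map, "gap_x") * scale$sx
  attr(out, "plot_w") <- attr(map, "plot_w") * scale$sx
  attr(out, "plot_h") <- attr(map, "plot_h") * scale$sy
  out
}

#' Bounding box of a field column across all blocks
#'
#' @param map A `microplot_map`.
#' @param column_index Global column index.
#' @return The minimal `pixel_rect` enclosing every plot with that column
#'   index in every block.
#' @export
column_bounding_box <- function(map, column_index) {
  sub <- map[map$column == column_index, , drop = FALSE]
  if (nrow(sub) == 0)
    stop("column_bounding_box: no plots in column ", column_index)
  pixel_rect(min(sub$x_min), min(sub$y_min), max(sub$x_max), max(sub$y_max))
}

# internal: list of pixel_rects for a subset of map rows
map_rects <- function(map, rows = seq_len(nrow(map))) {
  lapply(rows, function(i) df_rect(map[i, , drop = FALSE]))
}

# internal: shift a subset of map rows by t = c(dx, dy)
shift_map_rows <- function(map, rows, t) {
  map$x_min[rows] <- map$x_min[rows] + t[1]
  map$x_max[rows] <- map$x_max[rows] + t[1]
  map$y_min[rows] <- map$y_min[rows] + t[2]
  map$y_max[rows] <- map$y_max[rows] + t[2]
  map
}
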