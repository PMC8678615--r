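#' Stage 2: per-column translation
#'
#' Each field column — all plots sharing a global column index, across
#' every block — is re-translated to maximize the vegetation overlap of
#' its bounding box, with the search restricted by the layout gaps:
#' `dx in [-g_i, g_i]` (the expected inter-column gap) and
#' `dy in [-g, g]` (the expected within-column gap).  Columns are
#' processed left to right; every plot in a column moves by the column's
#' shift.  A second pass, [fix_column_overlaps()], then removes any
#' horizontal overlaps the independent column moves may have created.
#'
#' @param img A [veg_image()].
#' @param map A `microplot_map` in pixels (normally the output of
#'   [optimize_block()]).
#' @param config A [de_config()]; per-column seeds are derived from
#'   `config$seed`.
#' @param fix_overlaps Run the overlap-removal pass (default `TRUE`).
#' @param scope `"global"` treats a column as spanning all blocks;
#'   `"per-block"` optimizes each block's columns separately (for ragged
#'   layouts).
#' @return The translated map, with attribute `"column_shifts"`.
#' @export
optimize_columns <- function(img, map, config = de_config(),
                             fix_overlaps = TRUE,
                             scope = c("global", "per-block")) {
  scope <- match.arg(scope)
  if (attr(map, "units") != "pixels")
    stop("optimize_columns: map must be in pixel units")
  g <- attr(map, "gap_y"); gi <- attr(map, "gap_x")
  # inter-column gaps of the incoming (initial scaled) map drive the
  # overlap-removal spacing s
  init_gaps <- column_gaps(map)
  groups <- if (scope == "global") {
    lapply(sort(unique(map$column)), function(cc) which(map$column == cc))
  } else {
    key <- interaction(map$block, map$column, drop = TRUE)
    ord <- order(vapply(split(map$x_min, key), min, 0))
    unname(split(seq_len(nrow(map)), key))[ord]
  }
  out <- map
  shifts <- matrix(NA_real_, length(groups), 2,
                   dimnames = list(NULL, c("dx", "dy")))
  for (ci in seq_along(groups)) {
    rows <- groups[[ci]]
    box <- bounding_rect(map_rects(out, rows))
    cfg <- config
    if (!is.null(config$seed))
      cfg$seed <- derive_seed(config$seed, "column", ci)
    fit <- de_minimize(function(t) 1 - phi_veg(img, box, t),
                       lower = c(-gi, -g), upper = c(gi, g),
                       config = cfg, init = rbind(c(0, 0)))
    shifts[ci, ] <- fit$par
    out <- shift_map_rows(out, rows, fit$par)
  }
  attr(out, "column_shifts") <- shifts
  if (fix_overlaps && scope == "global")
    out <- fix_column_overlaps(out, s = init_gaps)
  out
}

# internal: horizontal gaps between adjacent column bounding boxes,
# left to right (length = n columns - 1)
column_gaps <- function(map) {
  cols <- sort(unique(map$column))
  if (length(cols) < 2) return(numeric(0))
  boxes <- lapply(cols, function(cc) column_bounding_box(map, cc))
  xmin <- vapply(boxes, function(b) b[["x_min"]], 0)
  xmax <- vapply(boxes, function(b) b[["x_max"]], 0)
  xmin[-1] - xmax[-length(xmax)]
}

#' Remove horizontal overlaps between adjacent columns
#'
#' Columns are visited right to left (excluding the right-most, which is
#' fixed); whenever a column's bounding box overlaps the box of the column
#' to its right, the whole column is shifted left so that its right edge
#' sits exactly `s` pixels left of the neighbour's left edge, where `s` is
#' the inter-column gap of the initial scaled map.  Right-to-left order
#' means every column is compared against an already-final right
#' neighbour, so one pass suffices.
#'
#' @param map A `microplot_map` in pixels.
#' @param s The spacing(s) to restore: a scalar or one value per adjacent
#'   column pair (left to right).  Defaults to the map's nominal
#'   inter-column gap.
#' @return The map with non-overlapping column boxes.
#' @export
fix_column_overlaps <- function(map, s = NULL) {
  cols <- sort(unique(map$column))
  nc <- length(cols)
  if (nc < 2) return(map)
  if (is.null(s)) s <- attr(map, "gap_x")
  s <- rep_len(s, nc - 1)
  out <- map
  for (j in seq(nc - 1, 1)) {
    box_l <- column_bounding_box(out, cols[j])
    box_r <- column_bounding_box(out, cols[j + 1])
    if (box_l[["x_max"]] > box_r[["x_min"]]) {
      shift <- (box_r[["x_min"]] - s[j]) - box_l[["x_max"]]
      out <- shift_map_rows(out, which(out$column == cols[j]), c(shift, 0))
    }
  }
  out
}
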