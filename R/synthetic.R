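#' Specification of a synthetic orthomosaic field
#'
#' Describes a simulated vegetation-index orthomosaic with known ground
#' truth: a grid of bright (high-index) plot rectangles on a dark soil
#' background, arranged in blocks, displaced by a smooth stitching-like
#' warp, degraded by intensity noise and optional blur (canopy closure),
#' with occasional missing (unsown) plots.  All geometry parameters are
#' in meters; `scale` converts to pixels.
#'
#' @param n_rows,n_cols Grid dimensions (plots per column, number of
#'   columns).
#' @param block_splits Row indices after which a new row-block starts
#'   (e.g. `c(15, 30)` for blocks of 15/15/17 rows); empty for none.
#' @param col_block_splits Column indices after which a new column-block
#'   starts (e.g. `c(2, 4)` for three two-column blocks); empty for none.
#' @param plot_w,plot_h Plot width and height (m).
#' @param gap_y Vertical gap between plots within a column (m).
#' @param gap_x Horizontal gap between adjacent columns (m).
#' @param block_gap_y,block_gap_x Extra gap inserted between row-blocks /
#'   column-blocks beyond the regular gap (m).
#' @param scale A [scale_spec()] (pixels per meter).
#' @param margin Background margin around the field (pixels).
#' @param veg_level,soil_level Mean index inside plots / on soil.
#' @param noise_sd Gaussian intensity noise SD.
#' @param warp_amplitude_y,warp_amplitude_x Warp displacement amplitudes
#'   (pixels).
#' @param warp_wavelength Warp wavelength (pixels).
#' @param warp_phase Phase of the warp field (radians); lets replicate
#'   fields carry different warp realizations.
#' @param block_offsets_y Optional per-row-block extra vertical offsets
#'   (pixels), emulating stitching seams between field sub-regions.
#' @param blur_sigma Gaussian blur sigma in pixels (0 = none); emulates
#'   canopy closure blurring the soil gaps.
#' @param missing_fraction Fraction of plots left unsown (drawn as soil
#'   but retained in the ground truth, flagged `missing`).
#' @param global_offset Translation `c(dx, dy)` in pixels applied to the
#'   whole field (on top of the margin), emulating the unknown placement
#'   of the map over the orthomosaic.
#' @param seed Integer seed; generation is bit-reproducible.
#' @return A `synthetic_field_spec` list.
#' @export
synthetic_field_spec <- function(n_rows, n_cols,
                                 block_splits = integer(0),
                                 col_block_splits = integer(0),
                                 plot_w, plot_h, gap_y, gap_x,
                                 block_gap_y = 0, block_gap_x = 0,
                                 scale = scale_spec(10),
                                 margin = 20,
                                 veg_level = 0.8, soil_level = 0.1,
                                 noise_sd = 0,
                                 warp_amplitude_y = 0, warp_amplitude_x = 0,
                                 warp_wavelength = 400,
                                 warp_phase = 0,
                                 block_offsets_y = NULL,
                                 blur_sigma = 0,
                                 missing_fraction = 0,
                                 global_offset = c(0, 0),
                                 seed = 1L) {
  stopifnot(n_rows >= 1, n_cols >= 1, plot_w > 0, plot_h > 0,
            gap_y >= 0, gap_x >= 0, margin >= 0,
            veg_level > soil_level, missing_fraction < 1,
            warp_wavelength > 0)
  structure(as.list(environment()), class = "synthetic_field_spec")
}

#' Ready-made synthetic field presets
#'
#' * `"toy"`: a 4-row by 3-column grid under 200x200 px, for fast tests
#'   and examples.
#' * `"canola_like"`: 39 rows x 6 columns in three side-by-side blocks of
#'   two columns; 5 x 20 ft plots (1.524 x 6.096 m, long edge horizontal)
#'   with a 1 ft (0.3048 m) gap within columns.
#' * `"wheat_like"`: 47 rows x 12 columns in three row-blocks of 15, 15
#'   and 17 rows; 3.5 x 13.5 ft plots with a 2 ft gap.
#'
#' @param name Preset name.
#' @param ... Overrides passed to [synthetic_field_spec()] fields.
#' @return A `synthetic_field_spec`.
#' @export
field_preset <- function(name = c("toy", "canola_like", "wheat_like"), ...) {
  name <- match.arg(name)
  base <- switch(name,
    toy = list(n_rows = 4, n_cols = 3,
               plot_w = 4.0, plot_h = 1.2, gap_y = 0.4, gap_x = 1.0,
               scale = scale_spec(10), margin = 12,
               veg_level = 0.8, soil_level = 0.1),
    canola_like = list(n_rows = 39, n_cols = 6,
                       col_block_splits = c(2, 4),
                       plot_w = 6.096, plot_h = 1.524,
                       gap_y = 0.3048, gap_x = 0.3048,
                       block_gap_x = 1.2192,
                       scale = scale_spec(10), margin = 30,
                       veg_level = 0.8, soil_level = 0.1),
    wheat_like = list(n_rows = 47, n_cols = 12,
                      block_splits = c(15, 30),
                      plot_w = 4.1148, plot_h = 1.0668,
                      gap_y = 0.6096, gap_x = 0.6096,
                      block_gap_y = 1.8288,
                      scale = scale_spec(10), margin = 30,
                      veg_level = 0.8, soil_level = 0.1))
  args <- utils::modifyList(base, list(...))
  do.call(synthetic_field_spec, args)
}

# internal: nominal layout in meters for a spec (origin = top-left plot corner)
nominal_layout <- function(spec) {
  row_block <- findInterval(seq_len(spec$n_rows) - 1, spec$block_splits) + 1
  col_block <- findInterval(seq_len(spec$n_cols) - 1, spec$col_block_splits) + 1
  x0 <- (seq_len(spec$n_cols) - 1) * (spec$plot_w + spec$gap_x) +
    (col_block - 1) * spec$block_gap_x
  y0 <- (seq_len(spec$n_rows) - 1) * (spec$plot_h + spec$gap_y) +
    (row_block - 1) * spec$block_gap_y
  plots <- expand.grid(row = seq_len(spec$n_rows), column = seq_len(spec$n_cols))
  plots <- plots[order(plots$column, plots$row), , drop = FALSE]
  plots$x_min <- x0[plots$column]
  plots$x_max <- plots$x_min + spec$plot_w
  plots$y_min <- y0[plots$row]
  plots$y_max <- plots$y_min + spec$plot_h
  # block identity: row-blocks for vertically split fields, column-blocks
  # for horizontally split ones, single block otherwise
  plots$block <- if (length(spec$block_splits) > 0) row_block[plots$row]
                 else if (length(spec$col_block_splits) > 0) col_block[plots$column]
                 else 1L
  plots$plot_id <- seq_len(nrow(plots))
  plots
}

#' Generate a synthetic orthomosaic with ground truth
#'
#' Builds the nominal grid of the spec, displaces every plot's true box
#' by the smooth warp field evaluated at its center (plus any per-block
#' offset and the global offset), renders plot interiors at `veg_level`
#' on a `soil_level` background, adds Gaussian noise, applies optional
#' blur, and clips to `[0, 1]`.  Missing plots are left as soil but kept
#' in the ground truth with `missing = TRUE`.
#'
#' @param spec A [synthetic_field_spec()].
#' @return A `synthetic_field`: `list(image, truth, map, scale,
#'   warp_record, spec)` where `image` is a [veg_image()], `truth` a data
#'   frame of true pixel boxes, `map` the nominal (unwarped)
#'   `microplot_map` in meters, and `warp_record` the per-plot true
#'   displacements.
#' @export
generate_field <- function(spec) {
  stopifnot(inherits(spec, "synthetic_field_spec"))
  nom <- nominal_layout(spec)
  sx <- spec$scale$sx; sy <- spec$scale$sy
  # nominal pixel geometry
  px <- nom
  px$x_min <- nom$x_min * sx; px$x_max <- nom$x_max * sx
  px$y_min <- nom$y_min * sy; px$y_max <- nom$y_max * sy
  extent_w <- max(px$x_max); extent_h <- max(px$y_max)
  W <- ceiling(extent_w + 2 * spec$margin +
                 max(0, spec$global_offset[1]) + spec$warp_amplitude_x)
  H <- ceiling(extent_h + 2 * spec$margin +
                 max(0, spec$global_offset[2]) + spec$warp_amplitude_y +
                 max(0, abs(if (is.null(spec$block_offsets_y)) 0
                            else max(abs(spec$block_offsets_y)))))
  if (spec$margin < abs(spec$global_offset[1]) ||
      spec$margin < abs(spec$global_offset[2]))
    warning("generate_field: |global_offset| exceeds margin; ",
            "plots may touch the image border")
  cx <- (px$x_min + px$x_max) / 2
  cy <- (px$y_min + px$y_max) / 2
  wx <- spec$warp_amplitude_x *
    sin(2 * pi * cy / spec$warp_wavelength + spec$warp_phase)
  wy <- spec$warp_amplitude_y *
    sin(2 * pi * (cx / spec$warp_wavelength + cy / (3 * spec$warp_wavelength)) +
          spec$warp_phase)
  if (!is.null(spec$block_offsets_y)) {
    bo <- rep_len(spec$block_offsets_y, max(nom$block))
    wy <- wy + bo[nom$block]
  }
  truth <- nom
  truth$x_min <- px$x_min + spec$margin + spec$global_offset[1] + wx
  truth$x_max <- px$x_max + spec$margin + spec$global_offset[1] + wx
  truth$y_min <- px$y_min + spec$margin + spec$global_offset[2] + wy
  truth$y_max <- px$y_max + spec$margin + spec$global_offset[2] + wy
  render <- with_local_seed(spec$seed, {
    missing <- stats::runif(nrow(truth)) < spec$missing_fraction
    values <- matrix(spec$soil_level, H, W)
    for (i in seq_len(nrow(truth))) {
      if (missing[i]) next
      b <- rect_raster(df_rect(truth[i, ]))
      values[(b[["y0"]] + 1):b[["y1"]], (b[["x0"]] + 1):b[["x1"]]] <-
        spec$veg_level
    }
    if (spec$noise_sd > 0)
      values <- values + matrix(stats::rnorm(H * W, 0, spec$noise_sd), H, W)
    if (spec$blur_sigma > 0)
      values <- EBImage::gblur(values, sigma = spec$blur_sigma)
    list(values = values, missing = missing)
  })
  truth$missing <- render$missing
  img <- veg_image(pmin(pmax(render$values, 0), 1))
  map <- microplot_map(nom, units = "meters",
                       gap_y = spec$gap_y, gap_x = spec$gap_x,
                       plot_w = spec$plot_w, plot_h = spec$plot_h)
  structure(list(
    image = img,
    truth = truth,
    map = map,
    scale = spec$scale,
    warp_record = data.frame(plot_id = nom$plot_id, dx = wx, dy = wy,
                             missing = truth$missing),
    spec = spec), class = "synthetic_field")
}

#' @export
print.synthetic_field <- function(x, ...) {
  cat(sprintf("<synthetic_field: %d plots, image %d x %d px, %d missing>\n",
              nrow(x$truth), x$image$h, x$image$w, sum(x$truth$missing)))
  invisible(x)
}

#' Write a synthetic field to disk
#'
#' Writes the index image (8-bit grayscale PNG), the ground truth as
#' Pascal VOC
#' XML, and the layout JSON — the same trio of inputs the localization
#' pipeline consumes.
#'
#' @param field A `synthetic_field`.
#' @param dir Output directory (created if needed).
#' @param name Basename for the files.
#' @return Named vector of paths, invisibly.
#' @export
write_field <- function(field, dir, name = "field") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  img_path <- file.path(dir, paste0(name, ".png"))
  voc_path <- file.path(dir, paste0(name, "_truth.xml"))
  map_path <- file.path(dir, paste0(name, "_map.json"))
  scale_path <- file.path(dir, paste0(name, "_scale.json"))
  png::writePNG(field$image$values, img_path)
  write_voc(field$truth, voc_path,
            image_dim = c(field$image$h, field$image$w))
  write_map(field$map, map_path)
  jsonlite::write_json(list(sx = field$scale$sx, sy = field$scale$sy),
                       scale_path, auto_unbox = TRUE, digits = NA)
  invisible(c(image = img_path, truth = voc_path, map = map_path,
              scale = scale_path))
}
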