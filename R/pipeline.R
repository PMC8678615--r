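#' Full hierarchical localization pipeline
#'
#' Runs the complete coarse-to-fine chain on a vegetation-index image and
#' a metric field map: scale the map into pixels, translate each block to
#' maximize enclosed vegetation (stage 1), re-translate each column under
#' the layout gap constraints (stage 2, with overlap removal), then
#' refine every microplot with the composite objective (stage 3).
#' Because differential evolution is stochastic, the whole chain is
#' repeated `restarts` times with distinct derived seeds and the run with
#' the smallest total per-plot objective is kept.
#'
#' @param img A [veg_image()] (or an array/matrix convertible to one, or
#'   a raster path readable by [read_ortho()]).
#' @param map A `microplot_map` in meters (or a layout JSON path).
#' @param scale A [scale_spec()].
#' @param weights A [weight_vector()] for stage 3.
#' @param config A [de_config()]; `config$seed` is the master seed.
#' @param restarts Number of independent runs (default 5).
#' @param bounds_profile Stage-3 bounds profile (see
#'   [optimize_all_plots()]).
#' @param block_objective Stage-1 overlap target, `"hull"` or `"plots"`.
#' @param column_scope `"global"` or `"per-block"` (see
#'   [optimize_columns()]).
#' @param index_kind Index interpretation when `img` is a single-channel
#'   raster path.
#' @return A `localization_result`: `list(plots, snapshots,
#'   total_objective, restart_index, restart_objectives, master_seed)`.
#'   `plots` has one row per microplot with its final rectangle and
#'   objective value; `snapshots` holds the map after each stage of the
#'   selected run.
#' @examples
#' \donttest{
#' fld <- generate_field(field_preset("toy", global_offset = c(6, 4)))
#' res <- localize(fld$image, fld$map, fld$scale,
#'                 config = de_config(seed = 1, max_iter = 40), restarts = 1)
#' match_and_score(res$plots, fld$truth)
#' }
#' @export
localize <- function(img, map, scale,
                     weights = weights_canola(),
                     config = de_config(seed = 1L),
                     restarts = 5L,
                     bounds_profile = "default",
                     block_objective = "hull",
                     column_scope = "global",
                     index_kind = "unit") {
  if (is.character(img)) img <- read_ortho(img, kind = index_kind)
  if (is.matrix(img)) img <- veg_image(img)
  if (!inherits(img, "veg_image")) stop("localize: img must be a veg_image")
  if (is.character(map)) map <- load_map(map)
  if (attr(map, "units") == "meters") map <- scale_map(map, scale)
  if (max(map$x_max) - min(map$x_min) > img$w ||
      max(map$y_max) - min(map$y_min) > img$h)
    stop("localize: scaled map extent exceeds the image; check the scale")
  master <- if (is.null(config$seed)) 0L else config$seed
  best <- NULL
  restart_obj <- numeric(restarts)
  for (r in seq_len(restarts)) {
    cfg <- config
    cfg$seed <- derive_seed(master, "restart", r)
    m1 <- optimize_block(img, map, cfg, objective = block_objective)
    m2 <- optimize_columns(img, m1, cfg, scope = column_scope)
    s3 <- optimize_all_plots(img, m2, weights, cfg,
                             bounds_profile = bounds_profile)
    restart_obj[r] <- s3$total_objective
    if (is.null(best) || s3$total_objective < best$total_objective) {
      plots <- s3$map[, c("plot_id", "block", "column", "row",
                          "x_min", "y_min", "x_max", "y_max")]
      plots$objective <- unname(s3$objectives)
      best <- list(plots = plots,
                   snapshots = list(block = m1, column = m2, plot = s3$map),
                   total_objective = s3$total_objective,
                   restart_index = r)
    }
  }
  best$restart_objectives <- restart_obj
  best$master_seed <- master
  class(best) <- "localization_result"
  best
}

#' @export
print.localization_result <- function(x, ...) {
  cat(sprintf(
    "<localization_result: %d plots | total objective %.4f | restart %d/%d>\n",
    nrow(x$plots), x$total_objective, x$restart_index,
    length(x$restart_objectives)))
  invisible(x)
}

#' Per-stage evaluation of a localization result
#'
#' Scores the stage snapshots of a result against ground truth, giving
#' the block / column / plot stage progression of mean DSC, median
#' displacement and detection.
#'
#' @param result A `localization_result` with snapshots.
#' @param truth Ground-truth data frame (`plot_id`, corners) or VOC XML
#'   path.
#' @param t_dsc Detection threshold.
#' @param image_dim,scale,units Passed to [match_and_score()].
#' @return Named list of `eval_report`s (`block`, `column`, `plot`).
#' @export
evaluate_stages <- function(result, truth, t_dsc = 0.5, image_dim = NULL,
                            scale = NULL, units = "px") {
  if (is.character(truth)) truth <- read_voc(truth)
  lapply(result$snapshots, function(snap)
    match_and_score(snap, truth, t_dsc = t_dsc, image_dim = image_dim,
                    scale = scale, units = units))
}

#' Read a pipeline configuration file
#'
#' YAML with optional keys `index` (`unit`/`ndvi`), `weights` (list of
#' six), `bounds_profile`, `block_objective`, `column_scope`, `restarts`,
#' `t_dsc`, and `de` (fields of [de_config()]).  Missing keys take the
#' package defaults.
#'
#' @param path YAML file path, or `NULL` for pure defaults.
#' @return A named list of localization arguments.
#' @export
load_config <- function(path = NULL) {
  cfg <- if (is.null(path)) list() else yaml::read_yaml(path)
  de <- do.call(de_config, c(cfg$de, list()))
  list(weights = if (is.null(cfg$weights)) weights_canola()
                 else weight_vector(unlist(cfg$weights)),
       config = de,
       restarts = if (is.null(cfg$restarts)) 5L else as.integer(cfg$restarts),
       bounds_profile = cfg$bounds_profile %||% "default",
       block_objective = cfg$block_objective %||% "hull",
       column_scope = cfg$column_scope %||% "global",
       index_kind = cfg$index %||% "unit",
       t_dsc = cfg$t_dsc %||% 0.5)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
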