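#' Dice similarity coefficient of two rectangles
#'
#' `DSC = 2 |A intersect B| / (|A| + |B|)`, computed analytically from the
#' rasterized (half-open, half-up rounded) pixel boxes; identical to
#' counting pixels but O(1).
#'
#' @param a,b `pixel_rect`s with positive rasterized area.
#' @return DSC in `[0, 1]`: 1 for identical boxes, 0 for disjoint ones.
#' @export
dsc <- function(a, b) {
  pa <- rect_area_px(a); pb <- rect_area_px(b)
  if (pa == 0 || pb == 0) stop("dsc: zero-area rasterized rectangle")
  2 * rect_intersection_px(a, b) / (pa + pb)
}

#' Center displacement between two rectangles
#'
#' Euclidean distance between rectangle centers, in pixels or converted
#' to meters/feet through the orthomosaic scale.
#'
#' @param a,b `pixel_rect`s.
#' @param scale A [scale_spec()] (required for `units != "px"`).
#' @param units `"px"`, `"m"` or `"ft"`.
#' @return The displacement (scalar).
#' @export
displacement <- function(a, b, scale = NULL, units = c("px", "m", "ft")) {
  units <- match.arg(units)
  ca <- rect_center(a); cb <- rect_center(b)
  dx <- ca[["x"]] - cb[["x"]]; dy <- ca[["y"]] - cb[["y"]]
  if (units == "px") return(sqrt(dx^2 + dy^2))
  if (is.null(scale)) stop("displacement: scale required for unit conversion")
  dm <- sqrt((dx / scale$sx)^2 + (dy / scale$sy)^2)
  if (units == "m") dm else dm / 0.3048
}

#' Score a localization result against ground truth
#'
#' Matches predicted and ground-truth boxes by `plot_id` (the pipeline
#' outputs exactly one box per known plot) and reports per-plot DSC,
#' center displacement and detection at the DSC threshold, plus
#' aggregate detection and pixel-level confusion metrics.  A pixel counts
#' as true positive when a predicted box covers it and it belongs to that
#' same plot's ground-truth box; predicted pixels outside the matching
#' truth box are false positives, truth pixels missed by the matching
#' prediction are false negatives, and everything else is true negative.
#'
#' @param result Data frame with `plot_id, x_min, y_min, x_max, y_max`
#'   (e.g. the `plots` element of a localization result, or a map).
#' @param truth Data frame of the same shape.
#' @param t_dsc Detection threshold on DSC (default 0.5).
#' @param image_dim `c(h, w)` of the image, needed for the true-negative
#'   count; without it TN and specificity are `NA`.
#' @param scale,units Passed to [displacement()].
#' @return An `eval_report`: `list(per_plot, mean_dsc,
#'   median_displacement, n_undetected, detection_rate, pixel_counts,
#'   sensitivity, specificity, precision, recall)`.
#' @export
match_and_score <- function(result, truth, t_dsc = 0.5, image_dim = NULL,
                            scale = NULL, units = "px") {
  if (!setequal(result$plot_id, truth$plot_id)) {
    miss <- c(setdiff(truth$plot_id, result$plot_id),
              setdiff(result$plot_id, truth$plot_id))
    stop("match_and_score: unmatched plot ids: ",
         paste(utils::head(miss, 10), collapse = ", "))
  }
  truth <- truth[match(result$plot_id, truth$plot_id), , drop = FALSE]
  n <- nrow(result)
  d <- numeric(n); disp <- numeric(n); tp <- 0; parea <- 0; tarea <- 0
  for (i in seq_len(n)) {
    a <- df_rect(result[i, ]); b <- df_rect(truth[i, ])
    d[i] <- dsc(a, b)
    disp[i] <- displacement(a, b, scale = scale, units = units)
    tp <- tp + rect_intersection_px(a, b)
    parea <- parea + rect_area_px(a)
    tarea <- tarea + rect_area_px(b)
  }
  fp <- parea - tp
  fn <- tarea - tp
  tn <- if (is.null(image_dim)) NA_real_
        else prod(image_dim) - tp - fp - fn
  detected <- d >= t_dsc
  per_plot <- data.frame(plot_id = result$plot_id, dsc = d,
                         displacement = disp, detected = detected)
  structure(list(
    per_plot = per_plot,
    mean_dsc = mean(d),
    median_displacement = stats::median(disp),
    n_undetected = sum(!detected),
    detection_rate = mean(detected),
    pixel_counts = c(TP = tp, TN = tn, FP = fp, FN = fn),
    sensitivity = tp / (tp + fn),
    recall = tp / (tp + fn),
    specificity = tn / (tn + fp),
    precision = tp / (tp + fp),
    t_dsc = t_dsc), class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf(
    "<eval_report: %d plots | mean DSC %.4f | undetected %d (T_DSC=%.2f) | median displacement %.3f>\n",
    nrow(x$per_plot), x$mean_dsc, x$n_undetected, x$t_dsc,
    x$median_displacement))
  invisible(x)
}

#' Detection counts across DSC thresholds
#'
#' Counts undetected plots (`DSC < threshold`) for each threshold; the
#' count is non-decreasing in the threshold.
#'
#' @param result,truth As in [match_and_score()].
#' @param thresholds Numeric thresholds in `[0, 1]`.
#' @return Data frame `(threshold, n_undetected)`.
#' @export
threshold_sweep <- function(result, truth, thresholds = seq(0, 1, by = 0.05)) {
  if (any(thresholds < 0 | thresholds > 1))
    stop("threshold_sweep: thresholds must lie in [0, 1]")
  rep0 <- match_and_score(result, truth, t_dsc = 0)
  d <- rep0$per_plot$dsc
  data.frame(threshold = thresholds,
             n_undetected = vapply(thresholds,
                                   function(tt) sum(d < tt), 0L))
}

#' Write localization results
#'
#' Writes the per-plot rectangles both as CSV
#' (`plot_id,x_min,y_min,x_max,y_max`) and as Pascal VOC XML (integer
#' boxes, one `<object>` per plot, `<name>` = plot id) so that results
#' and LabelImg-style ground truth share a dialect.
#'
#' @param result A localization result, `microplot_map`, or plain data
#'   frame with `plot_id, x_min, y_min, x_max, y_max`.
#' @param path Output path; `.csv` and `.xml` siblings are written (the
#'   extension of `path` is replaced).
#' @param image_dim Optional `c(h, w)` recorded in the VOC `<size>` tag.
#' @return Named character vector of the two files written, invisibly.
#' @export
write_results <- function(result, path, image_dim = NULL) {
  df <- if (inherits(result, "localization_result")) result$plots else result
  df <- as.data.frame(df)[, c("plot_id", "x_min", "y_min", "x_max", "y_max")]
  base <- sub("\\.(csv|xml)$", "", path)
  csv <- paste0(base, ".csv"); xml <- paste0(base, ".xml")
  utils::write.csv(df, csv, row.names = FALSE)
  write_voc(df, xml, image_dim = image_dim)
  invisible(c(csv = csv, xml = xml))
}

#' Pascal VOC annotation I/O
#'
#' Reads and writes microplot bounding boxes in the Pascal VOC XML
#' dialect produced by LabelImg: one `<object>` per plot with `<name>`
#' holding the plot id and an integer `<bndbox>`.
#'
#' @param path XML file path.
#' @return `read_voc`: data frame `(plot_id, x_min, y_min, x_max, y_max)`
#'   with integer coordinates.
#' @export
read_voc <- function(path) {
  if (!file.exists(path)) stop("read_voc: no such file: ", path)
  doc <- xml2::read_xml(path)
  objs <- xml2::xml_find_all(doc, ".//object")
  if (length(objs) == 0) stop("read_voc: no <object> records in ", path)
  get_num <- function(o, tag)
    as.numeric(xml2::xml_text(xml2::xml_find_first(o, paste0(".//", tag))))
  data.frame(
    plot_id = vapply(objs, function(o)
      xml2::xml_text(xml2::xml_find_first(o, ".//name")), ""),
    x_min = vapply(objs, get_num, 0, tag = "xmin"),
    y_min = vapply(objs, get_num, 0, tag = "ymin"),
    x_max = vapply(objs, get_num, 0, tag = "xmax"),
    y_max = vapply(objs, get_num, 0, tag = "ymax"))
}

#' @rdname read_voc
#' @param df Data frame with `plot_id, x_min, y_min, x_max, y_max`;
#'   coordinates are rounded half-up to integers on output.
#' @param image_dim Optional `c(h, w)` for the `<size>` element.
#' @export
write_voc <- function(df, path, image_dim = NULL) {
  doc <- xml2::xml_new_root("annotation")
  if (!is.null(image_dim)) {
    size <- xml2::xml_add_child(doc, "size")
    xml2::xml_add_child(size, "height", as.character(image_dim[1]))
    xml2::xml_add_child(size, "width", as.character(image_dim[2]))
    xml2::xml_add_child(size, "depth", "1")
  }
  for (i in seq_len(nrow(df))) {
    obj <- xml2::xml_add_child(doc, "object")
    xml2::xml_add_child(obj, "name", as.character(df$plot_id[i]))
    bb <- xml2::xml_add_child(obj, "bndbox")
    xml2::xml_add_child(bb, "xmin", as.character(as.integer(round_half_up(df$x_min[i]))))
    xml2::xml_add_child(bb, "ymin", as.character(as.integer(round_half_up(df$y_min[i]))))
    xml2::xml_add_child(bb, "xmax", as.character(as.integer(round_half_up(df$x_max[i]))))
    xml2::xml_add_child(bb, "ymax", as.character(as.integer(round_half_up(df$y_max[i]))))
  }
  xml2::write_xml(doc, path)
  invisible(path)
}
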