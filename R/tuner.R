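#' Tune the objective weights by differential evolution
#'
#' Searches the six stage-3 weights `w0..w5` over `[0, 1]^6`, minimizing
#' `1 - mean DSC` of the full three-stage pipeline on a small set of
#' annotated images (typically one early-, one mid- and one late-season
#' orthomosaic).  The default weight vector is seeded into the initial
#' population, so the tuned weights can never score below the defaults
#' on the tuning images.  Because every candidate evaluation runs the
#' whole pipeline on every image, the inner pipeline runs with a single
#' restart and a reduced DE budget.
#'
#' @param fields List of annotated inputs; each element is a list with
#'   `image` (a [veg_image()]), `map` (a `microplot_map`), `scale` (a
#'   [scale_spec()]; may be omitted when the map is already in pixels)
#'   and `truth` (ground-truth data frame).  A `synthetic_field` works
#'   directly.
#' @param config Outer DE settings (a [de_config()]); defaults to a
#'   small budget (population 6, 4 generations).
#' @param default_weights Seeded starting vector.
#' @param inner_config DE settings for the pipeline runs inside the
#'   objective.
#' @param bounds_profile Stage-3 bounds profile for the inner runs.
#' @return `list(weights, mean_dsc, default_mean_dsc)`.
#' @export
tune_weights <- function(fields,
                         config = de_config(pop_size = 6, max_iter = 4,
                                            tol = 0, seed = 1L),
                         default_weights = weights_canola(),
                         inner_config = de_config(pop_size = 12,
                                                  max_iter = 30),
                         bounds_profile = "default") {
  if (length(fields) == 0) stop("tune_weights: need at least one annotated image")
  fields <- lapply(fields, function(f) {
    if (inherits(f, "synthetic_field"))
      list(image = f$image, map = f$map, scale = f$scale, truth = f$truth)
    else f
  })
  objective <- function(w) {
    1 - mean(vapply(seq_along(fields), function(i) {
      f <- fields[[i]]
      cfg <- inner_config
      cfg$seed <- derive_seed(config$seed %||% 0L, "tune", i)
      res <- localize(f$image, f$map,
                      scale = f$scale %||% scale_spec(1),
                      weights = weight_vector(pmin(pmax(w, 0), 1)),
                      config = cfg, restarts = 1L,
                      bounds_profile = bounds_profile)
      match_and_score(res$plots, f$truth)$mean_dsc
    }, 0))
  }
  default_val <- objective(as.numeric(default_weights))
  fit <- de_minimize(objective, lower = rep(0, 6), upper = rep(1, 6),
                     config = config,
                     init = rbind(as.numeric(default_weights)))
  list(weights = weight_vector(fit$par),
       mean_dsc = 1 - fit$value,
       default_mean_dsc = 1 - default_val)
}
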