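# Shared fixtures, all built in code.

# brute-force DSC by explicit pixel enumeration (oracle for the analytic form)
brute_dsc <- function(a, b) {
  px_set <- function(r) {
    v <- rect_raster(r)
    if (v[["x1"]] <= v[["x0"]] || v[["y1"]] <= v[["y0"]]) return(character(0))
    as.vector(outer(seq(v[["x0"]], v[["x1"]] - 1),
                    seq(v[["y0"]], v[["y1"]] - 1), paste))
  }
  pa <- px_set(a); pb <- px_set(b)
  2 * length(intersect(pa, pb)) / (length(pa) + length(pb))
}

# brute-force region sum by nested indexing (oracle for the summed-area table)
brute_region_sum <- function(values, rect) {
  v <- rect_raster(rect)
  x0 <- max(v[["x0"]], 0); x1 <- min(v[["x1"]], ncol(values))
  y0 <- max(v[["y0"]], 0); y1 <- min(v[["y1"]], nrow(values))
  if (x0 >= x1 || y0 >= y1) return(0)
  sum(values[(y0 + 1):y1, (x0 + 1):x1])
}

# a small binary (0/1) field: ones inside the given rects, zeros elsewhere
binary_field_image <- function(h, w, rects) {
  m <- matrix(0, h, w)
  for (r in rects) {
    v <- rect_raster(r)
    m[(v[["y0"]] + 1):v[["y1"]], (v[["x0"]] + 1):v[["x1"]]] <- 1
  }
  veg_image(m)
}

# random integer-cornered rect within [0, w] x [0, h]
random_int_rect <- function(w = 30, h = 30) {
  x <- sort(sample(0:w, 2)); y <- sort(sample(0:h, 2))
  if (x[1] == x[2]) x[2] <- x[2] + 1
  if (y[1] == y[2]) y[2] <- y[2] + 1
  pixel_rect(x[1], y[1], x[2], y[2])
}

# a clean toy field (no warp/noise) with a known global offset
toy_field <- function(offset = c(6, 4), seed = 1, ...) {
  generate_field(field_preset("toy", global_offset = offset, seed = seed, ...))
}

# fast DE settings for tests
fast_de <- function(seed = 1) de_config(seed = seed, max_iter = 60)

# all plot rectangles of a map as a list of pixel_rects
map_rects_for_test <- function(map) {
  lapply(seq_len(nrow(map)), function(i)
    pixel_rect(map$x_min[i], map$y_min[i], map$x_max[i], map$y_max[i]))
}
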