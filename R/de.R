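#' Differential-evolution optimizer configuration
#'
#' Settings for the box-constrained global minimizer used by every
#' optimization stage.  The strategy is classic DE/rand/1/bin with
#' per-generation dithered mutation.
#'
#' @param pop_size Population size; default `15 * D` (at least 20), set at
#'   call time when `NULL`.
#' @param max_iter Maximum number of generations.
#' @param mutation Mutation factor F: a scalar, or a length-2 range from
#'   which F is drawn uniformly each generation (dithering).
#' @param recombination Crossover probability CR in `[0, 1]`.
#' @param tol Relative convergence tolerance: the run stops when the
#'   population spread `sd(f)` falls below `tol * |mean(f)| + 1e-12`.
#' @param seed Integer seed; identical seed, config and objective give a
#'   bit-identical result.  `NULL` uses the current RNG state.
#' @return An object of class `de_config`.
#' @export
de_config <- function(pop_size = NULL, max_iter = 1000,
                      mutation = c(0.5, 1.0), recombination = 0.7,
                      tol = 0.01, seed = NULL) {
  if (!is.null(pop_size) && pop_size < 4)
    stop("de_config: pop_size must be at least 4")
  if (tol < 0) stop("de_config: tol must be non-negative")
  stopifnot(length(mutation) %in% c(1, 2),
            recombination >= 0, recombination <= 1)
  structure(list(pop_size = pop_size, max_iter = max_iter,
                 mutation = mutation, recombination = recombination,
                 tol = tol, seed = seed),
            class = "de_config")
}

# run expr with a locally seeded RNG, restoring the caller's RNG state
with_local_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# deterministic per-call seed from a master seed and a (stage, unit) label;
# kept below 2^31 - 1
derive_seed <- function(master, stage, unit = 0L) {
  stage_code <- sum(utf8ToInt(stage)) %% 1000L
  as.integer((as.double(master) * 7919 + stage_code * 104729 +
                as.double(unit) * 131) %% 2147483647)
}

#' Minimize a function over a box by differential evolution
#'
#' @param f Objective `f(x)` mapping a length-`D` numeric vector to a
#'   scalar; must be finite on the box.
#' @param lower,upper Per-dimension bounds (`lower <= upper`; equal bounds
#'   pin a dimension).
#' @param config A [de_config()].
#' @param init Optional numeric matrix (rows = candidate vectors) seeded
#'   into the initial population, e.g. the zero translation; rows are
#'   clipped to the box.
#' @return `list(par, value, iterations, evaluations)` with `par` inside
#'   the box and `value = f(par)`.
#' @examples
#' de_minimize(function(x) (x - 0.3)^2, 0, 1, de_config(seed = 1))$par
#' @export
de_minimize <- function(f, lower, upper, config = de_config(), init = NULL) {
  D <- length(lower)
  if (length(upper) != D || any(lower > upper))
    stop("de_minimize: invalid bounds")
  with_local_seed(config$seed, {
    NP <- if (is.null(config$pop_size)) max(15L * D, 20L) else config$pop_size
    span <- upper - lower
    pop <- matrix(stats::runif(NP * D), NP, D)
    pop <- sweep(sweep(pop, 2, span, "*"), 2, lower, "+")
    if (!is.null(init)) {
      init <- matrix(init, ncol = D)
      ni <- min(nrow(init), NP)
      for (i in seq_len(ni))
        pop[i, ] <- pmin(pmax(init[i, ], lower), upper)
    }
    vals <- apply(pop, 1, f)
    nev <- NP
    iter <- 0L
    while (iter < config$max_iter) {
      if (stats::sd(vals) <= config$tol * abs(mean(vals)) + 1e-12) break
      iter <- iter + 1L
      Fmut <- if (length(config$mutation) == 2)
        stats::runif(1, config$mutation[1], config$mutation[2])
      else config$mutation
      for (i in seq_len(NP)) {
        r <- sample(seq_len(NP)[-i], 3L)
        mutant <- pop[r[1], ] + Fmut * (pop[r[2], ] - pop[r[3], ])
        mutant <- pmin(pmax(mutant, lower), upper)
        cross <- stats::runif(D) < config$recombination
        cross[sample.int(D, 1L)] <- TRUE
        trial <- ifelse(cross, mutant, pop[i, ])
        fv <- f(trial)
        nev <- nev + 1L
        if (fv <= vals[i]) {
          pop[i, ] <- trial
          vals[i] <- fv
        }
      }
    }
    best <- which.min(vals)
    list(par = pop[best, ], value = vals[best],
         iterations = iter, evaluations = nev)
  })
}

#' Exhaustive lattice search (validation oracle)
#'
#' Evaluates `f` on the regular lattice of spacing `step` inside the box
#' and returns the exact lattice minimum.  Ties are broken by the
#' lexicographically smallest argmin.  Used as an independent check of
#' [de_minimize()] on small problems.
#'
#' @inheritParams de_minimize
#' @param step Lattice spacing (> 0).
#' @return `list(par, value)`.
#' @export
grid_search <- function(f, lower, upper, step) {
  if (step <= 0) stop("grid_search: step must be positive")
  D <- length(lower)
  axes <- lapply(seq_len(D), function(d) seq(lower[d], upper[d], by = step))
  grid <- as.matrix(expand.grid(axes, KEEP.OUT.ATTRS = FALSE))
  vals <- apply(grid, 1, f)
  best <- min(vals)
  cand <- which(vals <= best)
  if (length(cand) > 1) {
    sub <- grid[cand, , drop = FALSE]
    cand <- cand[do.call(order, lapply(seq_len(D), function(d) sub[, d]))[1]]
  }
  list(par = unname(grid[cand[1], ]), value = best)
}
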