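---
title: "Hierarchical microplot localization in UAV orthomosaics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hierarchical microplot localization in UAV orthomosaics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

## The problem

Breeding trials subdivide a field into hundreds of *microplots*, each
growing one genetic line. Drone imagery of such trials is stitched into a
single orthomosaic, and every downstream phenotype (canopy cover, vigour,
senescence, yield proxies) is computed per microplot — so the first step
of any analysis is knowing precisely where each microplot sits in the
image. GPS-based placement is often unavailable or off by meters, and the
stitching itself introduces low-frequency *warping*, so rows and columns
of plots are not perfectly straight. `plotgrid` solves this by image
analysis alone: it takes the known, to-scale layout of the trial (the
*microplot map*, in meters) and the image scale in pixels per meter, and
refines the map's placement against a vegetation-index image in three
coarse-to-fine stages.

## The model

All stages maximize the same basic quantity, the normalized vegetation
overlap of a set of rectangles $B$ shifted by a translation
$t = (\Delta x, \Delta y)$:

$$\phi_{veg}(B, t) = \frac{\sum_{b \in B} \mathrm{veg}(b + t)}{\mathrm{area}(B)},$$

where $\mathrm{veg}(\cdot)$ sums a vegetation index over a rectangle and
$\mathrm{area}(B)$ counts the pixels the rasterized rectangles enclose.
With an index in $[0, 1]$, $\phi_{veg} \in [0, 1]$. The index is Excess
Green ($2g - r - b$ in chromatic coordinates, clipped to $[0,1]$) for RGB
input, or NDVI with negatives clipped to zero for red/NIR input; in both
cases bare soil scores near zero, which is what makes overlap a useful
placement signal.

1. **Per-block stage.** Each block of the map (the whole map, if it is
   one block) is translated to maximize $\phi_{veg}$ of its bounding
   rectangle. The search box is the image slack around the *full map*
   extent — image width minus the width of all microplots and their
   expected spacing, likewise for height — so that, when a map is split
   into blocks, each block stays near its nominal place in the layout
   instead of latching onto another, similar-looking band of plots.
2. **Per-column stage.** Each field column (spanning all blocks) is
   re-translated with $\Delta x \in [-g_i, g_i]$ and
   $\Delta y \in [-g, g]$, where $g$ is the expected within-column gap
   and $g_i$ the expected inter-column gap. A second, right-to-left pass
   shifts any column whose bounding box overlaps its right neighbour back
   to the initial map spacing $s$ — needed in late-season images where
   canopy closure hides the soil between columns.
3. **Per-microplot stage.** Plots are visited column-major (top to
   bottom, left to right). Each plot's translation minimizes a composite
   cost
   $$\phi(t) = w_0\,(1 - \phi_{veg}) + w_1\,\phi_{EC} + w_2\,\phi_{AC}
     + w_3\,\phi_{TC} + \phi_{EdC},$$
   combining vegetation overlap with layout priors:
   * *even spacing* $\phi_{EC} = 1 - e^{-4\bar g}$ with
     $\bar g = |g_k - g| / \max(|\Delta y_{min}|, |\Delta y_{max}|)$,
     where $g_k$ is the gap to the already-optimized plot above — the
     exponential makes even small spacing errors costly;
   * *alignment* $\phi_{AC}$, the normalized horizontal center offset
     from the plot above (linear, so that it stays gentle relative to
     $\phi_{EC}$);
   * *translation* $\phi_{TC}$, the normalized Manhattan length of $t$,
     which breaks ties in favour of staying put;
   * *edge cost* $\phi_{EdC} = w_4 (1 - c_{min}) + w_5 (1 - r_{min})$,
     where $c_{min}$ and $r_{min}$ are the smallest normalized column and
     row sums of the index under the box — it nudges boxes whose border
     row or column hangs over soil.

   Before a plot is optimized, the vertical displacement $g_d$ observed
   at the same-row plot of the previous column is propagated to its
   starting rectangle when $|g_d| \le g_{hm}/2$ (half the plot height);
   larger displacements more likely mean the neighbour snapped to the
   wrong plot and are ignored. First-column and top-row plots have no
   such reference and start unshifted. After optimization, a vertical
   overlap of $\Delta O$ pixels with the plot above is resolved by
   shifting the current plot down by $\Delta O$ if it drifted up into its
   neighbour (pre-resolution distance at most $g$), else up by
   $\Delta O$.

All translations are found with differential evolution (DE/rand/1/bin,
population $15 D$, dithered mutation in $(0.5, 1)$, crossover $0.7$,
relative tolerance $0.01$) — the objectives are non-differentiable
because of rasterization, so a derivative-free global optimizer is the
natural fit. Every DE call is seeded deterministically from a master
seed and the stage/unit index, and the zero translation is inserted into
every initial population, so a perfect starting placement can never be
degraded and identical seeds give bit-identical results. Because DE is
stochastic, the whole pipeline is run `restarts` times (default 5) and
the run with the smallest total per-plot objective is kept.

## Parameters that matter

* **Weights `w0..w5`** (unitless, each in $[0,1]$): two tuned reference
  vectors ship with the package — `weights_canola()`
  `(0.639, 0.627, 0.520, 0.0118, 0.0138, 0.624)` for trials with large
  inter-column gaps and an ExG index, and `weights_wheat()`
  `(0.976, 0.873, 0.975, 0.0918, 0.421, 0.822)` for severely warped
  NDVI orthomosaics. `tune_weights()` re-tunes them by DE on a handful
  of annotated images, seeding the defaults into the initial population
  so tuning can only improve on them (on the tuning images).
* **Gaps `g`, `g_i`** (meters in the layout, pixels after scaling):
  taken from the trial design; they define both the stage-2/3 search
  bounds and the spacing priors.
* **Bounds profile**: `"default"` searches $\pm g$ in both axes for
  every plot; `"severe-warp"` restricts $\Delta y$ to $\pm g/2$ outside
  the first row/column, which stabilizes heavily warped fields where a
  full-gap vertical search could jump to a neighbouring plot.
* **Detection threshold `T_DSC`** (default 0.5): a plot counts as
  detected when its Dice coefficient against ground truth reaches the
  threshold.

## What the synthetic generator emulates

`generate_field()` renders a vegetation-index image directly: bright
rectangles (`veg_level`, default 0.8) on dark soil (`soil_level`,
default 0.1), displaced by a smooth sinusoidal warp field evaluated at
each plot center (amplitude and wavelength in pixels, plus optional
per-row-block offsets that imitate stitching seams between flight
sections), with Gaussian intensity noise, optional Gaussian blur
standing in for canopy closure, occasional unsown plots, and a global
placement offset. Presets encode a 39×6 canola-style trial (three
two-column blocks, 5×20 ft plots, 1 ft gaps), a 47×12 wheat-style trial
(row-blocks of 15/15/17, 3.5×13.5 ft plots, 2 ft gaps) and a fast
4×3 `toy`. The inter-column gap of the canola-style preset (1 ft within
a block, 5 ft between blocks) is the package's own choice of a
realistic trial geometry.

What it does **not** emulate: real radiometry and illumination
gradients, within-plot texture and emergence variation, weeds,
senescence (plots that stop being green), non-sinusoidal warp, and
rotation of the grid. Tests passing on these fields therefore
demonstrate the optimization machinery — recovery of known offsets,
stage-wise improvement under warp, robustness to closed canopy and
missing plots — not performance on any particular real crop.

Default study conditions for the stage-progression checks were fixed
once from the layout itself: per-column vertical warp within the
within-column gap $g$ (so the column stage is needed and sufficient)
and per-plot residual warp within a third of the plot height (handled
by the per-plot stage), with 5% noise and blur $\sigma = 0.8$ px. The
`warp_phase` field gives replicate fields genuinely different warp
realizations.

## Numerical choices

* Coordinates are real-valued, 0-based, x = image column, y = image
  row; a rectangle rasterizes to the half-open pixel box
  $[\lfloor x_{min} + 0.5 \rfloor, \lfloor x_{max} + 0.5 \rfloor)$ and
  likewise in y. Half-up rounding keeps pixel membership stable under
  whole-pixel translation; optimization itself is continuous.
* Rectangular sums use a summed-area table (one subtraction per corner),
  validated against nested-loop summation to $10^{-6}$; out-of-image
  pixels contribute zero vegetation but still count in
  $\mathrm{area}(B)$, so translations that push plots off the image are
  penalized rather than rewarded.
* ExG is clipped, not min–max rescaled, into $[0,1]$: rescaling would
  let scene content (how green the greenest pixel is) change the
  meaning of soil values.
* The printed forms of the alignment and translation costs can go
  negative for negative shifts; both are implemented with absolute
  values in the numerator, as all components are costs minimized at a
  geometric optimum.
* The even-spacing and alignment terms are skipped for the top plot of
  each column (it has no already-optimized neighbour above).
* `grid_search()` breaks ties lexicographically; DE convergence stops
  when the population spread falls below `tol * |mean|`.
* The column overlap pass runs once, right-to-left, so every shifted
  column is compared against an already-final right neighbour.

## Problem sizes

The test-suite and the acceptance script run on `toy`-scale fields
(4×3 to 9×4 grids, images under 250×250 px) with 60-generation DE and
2–3 restarts; a full pipeline run at this size takes a couple of
seconds. The preset canola- and wheat-scale layouts (234 and 564 plots)
are exercised for geometry and counting; running the full optimizer on
them simply scales linearly in the number of DE calls.

## Known limitations

* The orthomosaic must be axis-aligned (plot long edges parallel to the
  image x-axis); there is no rotation or scale refinement.
* One box per known plot: spurious extra detections cannot occur, but a
  fully senesced plot will be placed by the layout priors alone.
* Plot dimensions are fixed throughout; the method localizes, it does
  not segment free-form boundaries.
* The pixel-level confusion metrics score each predicted box against
  its own plot's ground truth, so a box covering a *neighbouring* plot
  contributes false positives even though it covers vegetation.

## A short run

```{r, eval = FALSE}
library(plotgrid)

fld <- generate_field(field_preset("toy", global_offset = c(7, 5),
                                   warp_amplitude_y = 3,
                                   warp_wavelength = 150,
                                   noise_sd = 0.05, seed = 3))
res <- localize(fld$image, fld$map, fld$scale,
                config = de_config(seed = 1, max_iter = 60), restarts = 3)
match_and_score(res$plots, fld$truth,
                image_dim = c(fld$image$h, fld$image$w))
sapply(evaluate_stages(res, fld$truth), function(s) s$mean_dsc)
```
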