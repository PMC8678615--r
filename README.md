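# plotgrid

Automatic localization of breeding-trial **microplots** in UAV
orthomosaic imagery.

Field phenotyping pipelines start from one hard prerequisite: knowing
exactly where each microplot — the small rectangular plot growing one
genetic line — sits in the stitched orthomosaic of the trial. GPS-based
placement is often missing or off by meters, and orthomosaic stitching
warps the image so plot rows and columns are not straight. `plotgrid`
localizes every plot from the image alone, given only the trial's known
to-scale layout (corner coordinates in meters) and the image scale in
pixels per meter. It is aimed at plant-breeding and phenomics groups
processing drone imagery of row-and-column trials (canola, wheat, and
similar) across the whole season, including late-season images with
closed canopy.

## Method

The map is overlaid on a vegetation-index image (Excess Green for RGB
input, NDVI for red/NIR) and refined coarse-to-fine. Every stage
maximizes the normalized vegetation overlap of a rectangle set *B*
under a translation *t*:

    phi_veg(B, t) = sum_b veg(b + t) / area(B)

1. **Per block** — each block of the map is translated to maximize
   `phi_veg` of its bounding rectangle, searched over the image slack
   around the full map extent.
2. **Per column** — each cross-block column is re-translated within the
   layout gaps (`dx` in ±g_i, `dy` in ±g), then a right-to-left pass
   restores the nominal spacing wherever canopy closure let columns
   overlap.
3. **Per microplot** — each plot, visited column-major, minimizes the
   composite cost

       phi(t) = w0 (1 - phi_veg) + w1 phi_EC + w2 phi_AC + w3 phi_TC + phi_EdC

   blending vegetation overlap with even-spacing, alignment,
   translation and edge costs, with warp observed in the previous
   column propagated to the starting position and any residual vertical
   overlaps resolved.

All searches use a seeded differential-evolution optimizer; the
pipeline runs 5 restarts by default and keeps the result with the
smallest total objective. Evaluation ships with per-plot Dice
similarity (DSC), center displacement, detection at a DSC threshold
(0.5 by default), pixel-level confusion metrics, and threshold sweeps.
A synthetic orthomosaic generator with known ground truth (stitching
warp, noise, canopy blur, missing plots) makes every stage testable,
and `tune_weights()` re-tunes `w0..w5` on annotated images.

## Worked example

```r
library(plotgrid)

# a 4x3 synthetic trial, offset by (7, 5) px with mild stitching warp
fld <- generate_field(field_preset("toy", global_offset = c(7, 5),
                                   warp_amplitude_y = 3,
                                   warp_wavelength = 150,
                                   noise_sd = 0.05, seed = 3))

res <- localize(fld$image, fld$map, fld$scale,
                config = de_config(seed = 1, max_iter = 60), restarts = 3)
res
#> <localization_result: 12 plots | total objective 4.0906 | restart 3/3>

match_and_score(res$plots, fld$truth,
                image_dim = c(fld$image$h, fld$image$w))
#> <eval_report: 12 plots | mean DSC 1.0000 | undetected 0 (T_DSC=0.50) | median displacement 0.302>

sapply(evaluate_stages(res, fld$truth), function(s) s$mean_dsc)
#>  block column   plot
#> 0.8472 0.9167 1.0000
```

The localization found all 12 plots (every DSC at least the 0.5
detection threshold, here all 1.0 after rounding to the pixel grid),
with a median center displacement of 0.3 px; the stage progression
shows the coarse block placement (mean DSC 0.85) being corrected by the
column stage (0.92) and fully recovered by the per-plot refinement
(1.00).

A command-line front end wrapping the same functions (localize /
evaluate / simulate / tune) is installed at
`system.file("cli", "plotgrid.R", package = "plotgrid")`.

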