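# cyanotrace

Automated detection, tracing, reconnection and measurement of filamentous
cyanobacteria (trichomes) in bright-field micrographs of sedimented
phytoplankton samples — plus the model-II regression toolkit used to
validate automated against manual counting.

Monitoring programs quantify potentially toxic filamentous cyanobacteria by
settling Lugol-fixed water samples in Utermöhl chambers and counting
filaments per microscope field of view (FOV). `cyanotrace` automates the
image side of that workflow:

1. **Preprocess** — discrete 2D convolution with the Sobel kernel pair and
   recombination as the gradient magnitude `H = sqrt(h_v² + h_h²)`, which
   removes the background illumination gradient and the dependence on
   absolute contrast in a single operation.
2. **Segment** — threshold `H` (triangle/Otsu/fixed), seal and fill object
   outlines, label connected components, and classify objects as
   filamentous vs noise by elongation.
3. **Trace** — Zhang–Suen thinning to 1-px skeletons, decomposed into a
   node/edge graph (endpoints, junctions) with spur pruning and junction
   consolidation.
4. **Parameterize** — each path becomes a cubic least-squares B-spline under
   a chord-length parameterization; arc length by Gauss–Legendre
   quadrature, width from the distance transform.
5. **Reconnect** — fragments interrupted by debris and branches created by
   crossings are recombined by cost-ordered endpoint matching
   (gap, tangent alignment, lateral offset and width gates, plus a
   least-squares trial-fit rescue), reproducing single filaments.
6. **Measure** — per-FOV report: count and total length (µm) of filaments
   of interest, reconnection tally, filamentous object count, and the
   filamentous area fraction Afil/Aobj.

For method validation, `major_axis_fit()` implements Major Axis (model II)
regression of automated (y) on mean manual (x) estimates,

    slope = (Syy − Sxx + sqrt((Syy − Sxx)² + 4·Sxy²)) / (2·Sxy),

with `r²` the squared Pearson correlation — the symmetric fit appropriate
when both axes carry error. The package ships a 40-image validation
dataset (`validation_table()`): per-FOV manual (four operators) and
automated counts and total lengths from four stations on three Italian
volcanic lakes (Ronciglione, Caprarola, Albano, Nemi), spanning clean to
very noisy backgrounds. A seeded synthetic scene generator
(`scene_config()`, `generate_scene()`, `render_scene()`) provides ground
truth so the whole pipeline is testable end to end.

## Worked example

```r
library(cyanotrace)

# a synthetic quarter-scale FOV: 20 filaments, 10 interrupted by gaps
cfg   <- scene_config(seed = 104, n_filaments = 20, n_breaks = 10, n_blobs = 0)
truth <- generate_scene(cfg)
scene_summary(truth)
#> # A tibble: 1 × 6
#>   n_filaments total_length_um n_breaks n_crossings n_blobs filament_area_fraction
#>         <int>           <dbl>    <int>       <int>   <int>                  <dbl>
#> 1          20           2529.       10           0       0                    100

report <- process_scene(render_scene(truth), pipeline_config(), image_id = "demo")
report
#> <fov_report> demo: 20 filaments of interest, total length 2522.2 um,
#>   reconnected 10/10, 23 filamentous objects, Afil/Aobj 90.9%
```

All 20 filaments are recovered — each of the 10 gap interruptions is
re-joined, so the 30 fragment objects collapse back to 20 filaments — and
the measured total length (2522 µm) is within 0.3% of the generated truth
(2529 µm). On the packaged validation dataset:

```r
tab  <- validation_table()
fits <- station_fit_suite(tab)
dplyr::filter(fits, response == "abundance")
#> # A tibble: 4 × 7
#>   station     response  slope intercept    r2 p_value     n
#>   <chr>       <chr>     <dbl>     <dbl> <dbl>   <dbl> <int>
#> 1 Ronciglione abundance 1.09    -1.10   0.846      NA    10
#> 2 Caprarola   abundance 0.995   -0.0805 0.972      NA    10
#> 3 Albano      abundance 0.962   -2.37   0.869      NA    10
#> 4 Nemi        abundance 0.750    0.844  0.725      NA    10

pooled_summaries(tab)$overall
#> # A tibble: 1 × 1
#>   reconstruction_pct
#>                <dbl>
#> 1               83.0
```

The slope near 1 with high `r²` at Caprarola (0.99, 0.97) shows the
automated counts track the manual consensus in ordinary conditions; the
Nemi fit (0.75, 0.72) quantifies the degradation when only about a quarter
of the object area is filamentous and most objects are background debris.
The pooled reconstruction rate — 83% of interrupted/overlapping filaments
correctly recombined — summarizes the 40 per-image `rec_joined/rec_events`
tallies.

A thin command-line driver over these functions lives in
`inst/cli/cyanotrace.R` (subcommands `preprocess`, `process`, `batch`,
`simulate`, `validate-table`).

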