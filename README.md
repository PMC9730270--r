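# pixcell

Pixel-cell deconvolution for imaging-MS-based spatial single-cell
metabolomics.

In MALDI imaging mass spectrometry of single cells, the laser samples
circular **ablated regions** on a regular grid, but the biology lives in
segmented **cells** that the regions overlap only partially and often
share. `pixcell` assigns per-cell analyte intensities from per-region
intensities, corrects the analyte-specific ion suppression that distorts
them, and quantifies how well the assignment recovers a ground-truth
channel (e.g. the fluorescence of a dye detectable by both microscopy and
MS). It is aimed at developers and users of spatial single-cell
metabolomics workflows who need a testable, fully scriptable
implementation of these steps with a simulator that provides known ground
truth.

## The methods in brief

Overlap geometry per region *r* and cell *k*: sampling proportion
*sp<sub>r</sub>* (fraction of the region on any cell), sampling
specificity *spec<sub>r,k</sub>* (how the cellular part splits over
cells), and their product *S<sub>r,k</sub>*, the **specific sampling
proportion**.

* **WA (weighted average)** — region intensities are divided by their
  sampling proportion, then averaged per cell with specificities as
  weights: *S<sub>cell</sub>(k) = Σ<sub>r</sub> spec<sub>r,k</sub>
  (I<sub>r</sub>/sp<sub>r</sub>) / Σ<sub>r</sub> spec<sub>r,k</sub>*.
* **LIM (linear inverse modelling)** — solves *p = S c* for the per-cell
  intensities *c ≥ 0* by non-negative least squares, independently per
  connected component of the region-cell graph.
* **MIX** — LIM everywhere except cells in *underdetermined
  subnetworks* (components with more cells than regions), which get WA.
* **Ion suppression compensation** — the response ratio (supervised:
  intensity/fluorescence *η*; unsupervised: intensity/sampling-proportion
  *μ*) follows a negative power law in the sampling proportion; its
  log-log slope is estimated by median (quantile) regression and
  intensities are divided by the predicted ratio, anchored to 1 at full
  coverage. Analytes with fewer than 10 usable points borrow the
  best-covered analyte's fit.
* **Evaluation** — density-weighted Spearman correlation against the
  ground-truth channel (weights negatively proportional to the local
  density of the ground truth) and the mean 10-nearest-neighbour
  cell-type intermixing fraction in a 2-D embedding.

Everything operates on tibbles and composes with the pipe; fitted objects
have `tidy()`/`glance()` methods and `autoplot()`/`plot_*()` diagnostics.
A thin command-line wrapper (`exec/pixcell`) exposes the pipeline as
`simulate`, `overlaps`, `peaks`, `compensate`, `deconvolve`, `evaluate`,
`intermix`, `pipeline` and `sweep` subcommands.

## Worked example

Simulate a scene with known ground truth, measure it with noise and ion
suppression, compensate, deconvolve and evaluate:

```r
library(pixcell)

scene <- simulate_scene(n_cells = 100, seed = 1)
grid  <- scene_grid(scene)
meas  <- simulate_measurement(
  scene, grid,
  measurement_model(noise_cv = 0.2, suppression_b = -0.6, seed = 1001)
)
meas$overlaps
#> <overlap_table> 784 regions (342 cellular), 100 cells, 373 region-cell pairs

comp <- compensate_unsupervised(meas$intensities)
tidy(comp$fits)
#> # A tibble: 1 × 7
#>   analyte     mode             slope intercept n_points fallback anchored
#>   <chr>       <chr>            <dbl>     <dbl>    <int> <lgl>    <lgl>
#> 1 fluorescein unsupervised_mu -0.664      3.94      264 FALSE    TRUE

cells <- comp$table |>
  deconvolve_wa(filter_overlaps(meas$overlaps, sp_cutoff = 0.3))
cells
#> <cell_profiles> method wa: 100 cells (100 assigned, 0 zero, 0 not associated)

truth <- scene$ground_truth$fluorescein[match(cells$cell_id, scene$ground_truth$cell_id)]
density_weighted_spearman(truth, cells$fluorescein)
#> [1] 0.9608483
```

The fitted slope −0.664 recovers the simulated suppression exponent
(−0.6) from the data alone, and compensation lifts the density-weighted
correlation with the ground truth (0.961 here, versus 0.876 for the same
pipeline without compensation). One call runs the whole chain for all
three methods:

```r
run_pipeline(pipeline_config(seed = 1))$summary
#> # A tibble: 3 × 5
#>   method weighted_rho n_cells n_assigned assigned_fraction
#>   <chr>         <dbl>   <int>      <int>             <dbl>
#> 1 wa            0.876     100        100                 1
#> 2 lim           0.875     100        100                 1
#> 3 mix           0.895     100        100                 1
```

`weighted_rho` is the density-weighted Spearman correlation between each
method's assigned cell intensities and the simulated ground truth;
`assigned_fraction` is the share of cells that received a value.

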