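---
title: "Pixel-cell deconvolution and ion suppression compensation for imaging-MS single-cell metabolomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pixel-cell deconvolution and ion suppression compensation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pixcell)
```

## The problem

MALDI imaging mass spectrometry samples a specimen with a laser on a
regular raster: each shot ablates a roughly circular region and yields one
centroided mass spectrum. For single-cell metabolomics the specimen is a
field of segmented cells, and the quantity of interest is the analyte
content of each *cell* — but the measurement unit is the ablated *region*,
which rarely coincides with a cell: a region may cover one cell partially,
straddle several neighbouring cells (co-ablation), or fall mostly on
background. **Pixel-cell deconvolution** is the step that assigns per-cell
analyte intensities from the per-region intensities, given the overlap
geometry of regions and cells.

Two further effects corrupt the per-region measurements:

* **Ion suppression** — analytes in cell-dense regions compete for charge,
  so the per-unit-content response declines as the cellular coverage of a
  region grows. Empirically the intensity-to-content ratio follows a
  negative power law of the region's cellular coverage.
* **Drop-outs** — zero intensities occurring both below the limit of
  detection and completely at random, the latter largely from
  pixel-variable mass accuracy interacting with a narrow integration
  window.

`pixcell` implements the full chain: overlap geometry, peak integration,
TIC normalisation, suppression compensation, three deconvolution methods,
and ground-truth-based evaluation — plus a synthetic-scene simulator that
provides known per-cell ground truth for all of it.

## Overlap geometry

Let region $r$ consist of the image pixels whose centers lie within the
ablation radius of the region center (boundary inclusive; pixel
coordinates are 1-based `(row, col)` as in R matrices). With $n_r$ pixels
in the region, $n_r^{cell}$ of them on any cell and $n_{r,k}$ on cell $k$:

* **sampling proportion** $sp_r = n_r^{cell} / n_r \in [0, 1]$ — the
  fraction of the region that samples cellular material;
* **sampling specificity** $spec_{r,k} = n_{r,k} / n_r^{cell}$ — how the
  cellular part distributes over cells ($\sum_k spec_{r,k} = 1$);
* **specific sampling proportion** $S_{r,k} = sp_r \cdot spec_{r,k}$ —
  the fraction of the region occupied by cell $k$, and the entry of the
  design matrix $S$.

Regions clipped by the image border keep only their in-image pixels in
the denominator; out-of-image area counts as background. Every pixel in a
region contributes equally — a uniform laser energy distribution is
assumed, which is a simplification of real beam profiles.

## Deconvolution methods

**Weighted average (WA).** Each region intensity is first normalised by
its sampling proportion, then each cell receives the specificity-weighted
average over its regions:

$$S_{cell}(k) = \frac{\sum_r spec_{r,k}\, I_r / sp_r}{\sum_r spec_{r,k}}.$$

WA is robust but cannot unmix co-ablated regions exactly: a cell's value
always contains a contribution from its neighbours' content.

**Linear inverse modelling (LIM).** The region intensity vector is
modelled as $p = S\,c$ with $c \ge 0$ the unknown per-cell intensities,
and estimated by non-negative least squares (Lawson–Hanson active set,
implemented in `nnls_fit()`). Because the acquisition covers many more
regions than cells, the system is overdetermined by design. The bipartite
region–cell graph decomposes into connected components, and the NNLS
problem is solved per component — the optimum is unchanged and the
problem sizes stay small. On noiseless data with every component having
full column rank, LIM recovers the ground truth exactly; WA does not.
Rank-deficient determined components return one feasible least-squares
solution and are flagged via a message.

**MIX.** LIM fails unpredictably on *underdetermined subnetworks*:
connected components with more cells than regions, which have a solution
space rather than a unique solution. `find_components()` builds the graph
with edges wherever a region overlaps a cell (specificity > 0) and its
sampling proportion exceeds 0.3, flags cells in underdetermined
components, and `deconvolve_mix()` assigns those cells their WA value
and all others their LIM value.

**Bookkeeping.** Cells associated with no included region get `NA`
(status `not_associated`); cells whose computed value is zero get status
`zero`; everything else is `assigned`. TSV export writes `NA` literally.

**Filtering.** Before deconvolution, `filter_overlaps()` removes regions
with sampling proportion below a cutoff (default 0.3 — the value that
maximises quantitation while retaining nearly all cells) and
(region, cell) pairs with specificity below a cutoff (default 0).
Surviving specificities are *not* renormalised: they keep their raw
values so the WA weights retain their geometric meaning. Pair-level
removal is the default; `pair_level = FALSE` removes whole regions
instead. Optionally, regions with a zero intensity for a chosen analyte
can be dropped (drop-out filtering).

## Ion suppression compensation

Both modes model the log of a per-region response ratio as a linear
function of $\log sp_r$ and fit it by median (quantile) regression, which
is robust to drop-outs and heavy-tailed intensity noise:

* **Supervised** (requires a co-registered ground-truth channel such as
  fluorescence): $\eta_r = I_r / F_r$, computed on regions with
  $sp_r > 0.1$, $I_r, F_r > 0$; $\eta$ is scaled by the median $\eta$ of
  fully-covering regions ($sp \ge 1 - 10^{-6}$; the tolerance is
  configurable because rasterised grids make exact 1.0 common but not
  guaranteed), so the anchor regions have ratio 1.
* **Unsupervised** (applicable to every analyte): $\mu_r = I_r / sp_r$ on
  regions with $I_r > 0$ and $sp_r > 0.1$. The 0.1 floor mirrors the
  supervised procedure. Analytes with fewer than 10 usable points borrow
  the fit of the best-covered analyte and are flagged (`fallback`).

Corrected intensities are $I_r' = I_r / \widehat{ratio}(sp_r)$ for all
regions with $sp_r > 0$. By default the prediction is **anchored**,
$\widehat{ratio}(sp) = sp^{\hat\beta}$, so it equals exactly 1 at
$sp = 1$: fully-covering regions are untouched and per-analyte intensity
scales are preserved. Dividing by the un-anchored prediction
$e^{\hat\alpha} sp^{\hat\beta}$ differs only by a per-analyte constant
and is available with `anchor = FALSE`. The correction is a positive
scalar per region, so it preserves intensity ranking among regions with
equal sampling proportion.

### Median regression without an external solver

`fit_quantile_line()` minimises the check loss for one predictor. The
objective profiled over the intercept (a quantile of the residuals) is
convex piecewise-linear in the slope; it is minimised by golden-section
search over the range of pairwise data slopes and then polished over the
nearby two-point "breakpoint" slopes, which provably contain the exact
optimum of a least-absolute-deviations line. For more than 1200 points
the candidate set is subsampled; the profiled search is unaffected.
Exactly collinear inputs are recovered to machine precision, and the fit
is invariant to the magnitude of residuals beyond their breakpoint (the
defining robustness property of median regression).

## Evaluation

**Density-weighted Spearman correlation.** Ground-truth vectors are very
unevenly distributed (for ablated regions, most values sit in a dense
near-zero extracellular mode), so observations are weighted *negatively
proportionally* to the local density of the ground-truth vector: a 1-D
Gaussian KDE with Silverman bandwidth is evaluated at each observation
and mapped to weights. The exact published weight formula is not
reproducible from the available description, so both natural readings are
implemented and recorded in outputs: $\omega_i = 1 - \rho_i /
\max \rho + 10^{-6}$ (default, `one_minus`) and $\omega_i = 1 / \rho_i$
(`inverse`). Weights are rescaled to sum to the observation count.
Correlation is computed as the weighted Pearson correlation of average
ranks; with uniform weights this reproduces classical Spearman to
machine precision. Pairs with a missing value are dropped before
ranking; fewer than 3 complete pairs yields `NA`.

**Intermixing fraction.** For each cell in a 2-D embedding, the fraction
of its 10 nearest neighbours (Euclidean, self excluded, distance ties
broken deterministically by index order) carrying a different cell-type
label; the mean and standard deviation over cells summarise separation.
The metric consumes *any* embedding; `embed_pca()` provides a
deterministic one (first two principal components of log1p profiles) so
the pipeline needs no stochastic embedding algorithm.

## The synthetic-scene simulator

`simulate_scene()` places non-overlapping disc cells by rejection
sampling and draws per-cell ground-truth signals;
`simulate_measurement()` rasterises an ablation grid against the mask and
forms each region's base signal as $p = S c$, then applies, in order:
per-analyte suppression $sp^{b}$, multiplicative lognormal noise with
mean 1, below-LOD censoring, and MCAR zeroing. With all effects off,
$p = S c$ holds to machine precision, and the emitted `fluorescence`
column is always the suppression-free noiseless base signal — the proxy a
microscope would record.

Default study conditions, chosen once to emulate a dye-titration
validation experiment on spherical, centrifugation-deposited cells:

* 100 disc cells of radius 9–13 px on a 512×512 image; ablation grid
  with 18 px step and 9 px radius. The step is about 0.8× the mean cell
  diameter, so partial overlaps and co-ablation are frequent — in this
  geometry well over 90 % of cell-associated regions overlap cells only
  partially, as in experiments where cells are deposited by
  centrifugation and remain small and spherical.
* Per-cell signals: one of four levels (25, 50, 75, 100, emulating
  pooled populations incubated at four dye concentrations) times
  lognormal cell-to-cell variation with CV 0.2.
* Measurement: lognormal noise CV 0.2 and suppression exponent −0.6 as
  the central noisy condition; both default to off in the raw
  constructors.

For suppression-fit checks that need no geometry,
`simulate_suppression_regions()` draws regions directly on the power law:
content density lognormal (sdlog 0.5 by default), $sp$ uniform with a 5 %
share of exactly-full regions (the anchor set), $F = a\,sp$ and
$I = F\, sp^{b}\, noise$.

The two-population condition used for the intermixing analysis deserves a
note. A first design with near-disjoint type profiles was degenerate: the
types were perfectly separated with or without suppression, so the
intermixing comparison was decided by ties. The condition used instead
emulates a co-culture whose separation is *visibly* degraded by
suppression: mean profiles overlapping (a 2× difference in three of six
analytes, identical in the rest), per-cell lognormal CV 0.3, and shared,
analyte-specific suppression with exponents spanning −0.3 to −1.2 —
mirroring the observation that different analytes show clearly different
suppression slopes. Under this condition the mean 10-NN intermixing is
about 0.07 uncompensated and drops to about 0.05 after unsupervised
compensation.

What the simulator does **not** emulate: realistic spectra (isotope
patterns, adducts, matrix clusters), non-uniform laser energy within a
region, content-dependent (as opposed to coverage-dependent) suppression,
cell shapes other than discs (arbitrary masks can be supplied), and
registration error between modalities. Passing tests therefore
demonstrate correctness of the geometry, the solvers, the compensation
and the metrics under the stated generative model — not performance on
real tissue data.

## Peak integration and drop-outs

`integrate_peak()` sums all centroids within a ppm window of the target
mass (a maximum-centroid variant is available; which statistic the
original analyses used is not documented, so the sum is the default).
The per-region TIC is the sum over the full acquired mass range.
`zero_fraction_curve()` reports the drop-out fraction as a function of
the tolerance; it is non-increasing by construction, and
`simulate_spectra()` reproduces the mechanism by jittering centroid
masses with Gaussian ppm noise. The default tolerance is 3 ppm (the
common annotation default), with 4 ppm the optimum reported for a
fluorescein validation experiment; intensity-dependent mass-shift
correction is out of scope — the tolerance sweep is the supported
mitigation.

## Numerical choices

* Pixel membership: center-point-in-circle, boundary inclusive, with a
  $10^{-12}$ slack on the squared radius to absorb representation error.
* NNLS: dual-feasibility tolerance $10^{-12}$ scaled to
  $\max |A^T b|$; indices driven to relative $10^{-12}$ leave the
  passive set. Convergence failure raises an error naming the component.
* Specificity conservation ($\sum_k spec_{r,k} = 1$) and the
  factorisation $S_{r,k} = sp_r \cdot spec_{r,k}$ hold to $10^{-9}$ and
  are property-tested.
* kNN distance ties: broken by cell index (stable `order()`).
* Degenerate inputs: empty masks give all-zero sampling proportions (not
  an error); zero-pixel regions, non-positive grid steps, cutoffs
  outside $[0,1]$ and negative TICs are errors; constant ground-truth
  vectors give uniform weights with a warning.
* All simulation entry points take explicit seeds and are byte-identical
  under the same seed and parameters.

## Problem sizes

The test-suite and the acceptance script run on scenes of 25–100 cells on
images up to 512×512 (about 800 ablated regions), 500-region suppression
fits with up to 20 replicate seeds, and exhaustive oracles (per-pixel
double loops, support enumeration for NNLS, two-point line enumeration
for median regression) on instances small enough to enumerate — sizes at
which every oracle remains exact and the whole suite completes in a few
minutes on one core.

## Known limitations

* The grid is parameter-driven; there is no automatic registration of
  the grid to an ablation image (the original workflow placed it
  visually, a step that is not reproducible programmatically).
* Suppression is compensated as a function of sampling proportion only;
  molecule- and context-dependent suppression beyond the power law is
  not modelled, and fitted slopes should not be transferred across
  experiments without validation.
* The imzML reader/writer covers the centroided, external-binary subset
  of the format needed here (it is cross-checked against an independent
  Python parser in the tests); it is not a general mzML implementation.
* PNG masks written by this package use a two-channel byte encoding
  because the available PNG writer is 8-bit; true 16-bit grayscale PNGs
  from other tools are read transparently, and TIFF round-trips at
  16-bit.
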