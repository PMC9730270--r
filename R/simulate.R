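# Synthetic scenes with known per-cell ground truth: circular cells on a
# background, a regular circular ablation grid, region intensities formed
# as specific-sampling-proportion-weighted sums of cell signals, optional
# power-law ion suppression, multiplicative lognormal noise, below-LOD
# censoring and MCAR drop-outs.

#' Per-cell signal sampler emulating a pooled four-level dye titration
#'
#' Cells are assigned one of `levels` (emulating pooled populations
#' incubated at four dye concentrations), times multiplicative lognormal
#' cell-to-cell variation with coefficient of variation `cv`.
#'
#' @param levels Base signal levels (default `c(25, 50, 75, 100)`).
#' @param cv Lognormal coefficient of variation around the level
#'   (default 0.2).
#' @param analyte Analyte name for the resulting column.
#' @return A function `f(n)` returning an `n x 1` matrix with an attribute
#'   `level` (the level drawn per cell).
#' @export
signal_sampler_fda <- function(levels = c(25, 50, 75, 100), cv = 0.2,
                               analyte = "fluorescein") {
  force(levels)
  sdlog <- sqrt(log(1 + cv^2))
  function(n) {
    lv <- sample(levels, n, replace = TRUE)
    vals <- lv * stats::rlnorm(n, -sdlog^2 / 2, sdlog)
    out <- matrix(vals, ncol = 1, dimnames = list(NULL, analyte))
    attr(out, "level") <- lv
    out
  }
}

#' Two-population signal sampler
#'
#' Cells are drawn from two types with distinct mean analyte profiles and
#' shared lognormal cell-to-cell variation, emulating a co-culture of two
#' cell types with different metabolic profiles.
#'
#' @param profile_a,profile_b Named numeric vectors (same analyte names):
#'   mean signal per analyte for each type.
#' @param cv Lognormal coefficient of variation per cell and analyte
#'   (default 0.3).
#' @param prob Probability of type A (default 0.5).
#' @return A function `f(n)` returning an `n x A` matrix with attribute
#'   `cell_type` (`"A"`/`"B"`).
#' @export
signal_sampler_two_populations <- function(profile_a, profile_b, cv = 0.3,
                                           prob = 0.5) {
  stopifnot(identical(names(profile_a), names(profile_b)))
  sdlog <- sqrt(log(1 + cv^2))
  function(n) {
    type <- ifelse(stats::runif(n) < prob, "A", "B")
    base <- rbind(profile_a, profile_b)[ifelse(type == "A", 1L, 2L), ,
      drop = FALSE
    ]
    noise <- matrix(
      stats::rlnorm(n * length(profile_a), -sdlog^2 / 2, sdlog),
      nrow = n
    )
    out <- base * noise
    dimnames(out) <- list(NULL, names(profile_a))
    attr(out, "cell_type") <- type
    out
  }
}

#' Simulate a segmented scene of disc-shaped cells with known signals
#'
#' Places `n_cells` non-overlapping discs by rejection sampling, rasterises
#' them into an integer-label mask (same pixel-center-in-circle rule as the
#' overlap computation), and draws per-cell ground-truth signals from
#' `signal_sampler`. Deterministic under `seed`.
#'
#' @param n_cells Number of cells (>= 1).
#' @param image_size `(rows, cols)` of the mask (default `c(512, 512)`).
#' @param radius_range Cell radius range in pixels (default `c(9, 13)`).
#' @param signal_sampler Function `f(n)` returning an `n x A` signal matrix
#'   (see [signal_sampler_fda()]).
#' @param seed Random seed.
#' @param max_retries Placement attempts before giving up (default
#'   `200 * n_cells`).
#' @return A `synthetic_scene`: list with `mask`, `cells` (tibble
#'   `cell_id`, `row`, `col`, `radius`, and `cell_type`/`level` when the
#'   sampler provides them), `ground_truth` (tibble `cell_id` + analyte
#'   columns), `params`, `seed`.
#' @export
simulate_scene <- function(n_cells = 100, image_size = c(512, 512),
                           radius_range = c(9, 13),
                           signal_sampler = signal_sampler_fda(),
                           seed = 1, max_retries = 200 * n_cells) {
  stopifnot(n_cells >= 1, length(image_size) == 2, all(radius_range > 0))
  set.seed(seed)
  rows <- numeric(0)
  cols <- numeric(0)
  radii <- numeric(0)
  tries <- 0L
  while (length(rows) < n_cells) {
    tries <- tries + 1L
    if (tries > max_retries) {
      stop(
        "could not place ", n_cells, " non-overlapping cells in ",
        max_retries, " attempts; use fewer or smaller cells",
        call. = FALSE
      )
    }
    r <- stats::runif(1, radius_range[1], radius_range[2])
    cr <- stats::runif(1, r + 1, image_size[1] - r)
    cc <- stats::runif(1, r + 1, image_size[2] - r)
    if (length(rows) == 0L ||
      all(sqrt((rows - cr)^2 + (cols - cc)^2) > radii + r + 1)) {
      rows <- c(rows, cr)
      cols <- c(cols, cc)
      radii <- c(radii, r)
    }
  }
  mask <- matrix(0L, image_size[1], image_size[2])
  for (k in seq_len(n_cells)) {
    px <- region_pixels(c(rows[k], cols[k]), radii[k], image_size)
    mask[px] <- k
  }
  signals <- signal_sampler(n_cells)
  cells <- tibble::tibble(
    cell_id = seq_len(n_cells), row = rows, col = cols, radius = radii
  )
  if (!is.null(attr(signals, "cell_type"))) {
    cells$cell_type <- attr(signals, "cell_type")
  }
  if (!is.null(attr(signals, "level"))) {
    cells$level <- attr(signals, "level")
  }
  ground_truth <- tibble::tibble(cell_id = seq_len(n_cells)) |>
    dplyr::bind_cols(tibble::as_tibble(unclass(signals)[seq_len(n_cells), ,
      drop = FALSE
    ]))
  structure(
    list(
      mask = mask, cells = cells, ground_truth = ground_truth,
      params = list(
        n_cells = n_cells, image_size = image_size,
        radius_range = radius_range
      ),
      seed = seed
    ),
    class = "synthetic_scene"
  )
}

#' @export
print.synthetic_scene <- function(x, ...) {
  cat(sprintf(
    "<synthetic_scene> %d cells on %d x %d image, %d analyte(s), seed %d\n",
    nrow(x$cells), nrow(x$mask), ncol(x$mask),
    ncol(x$ground_truth) - 1L, x$seed
  ))
  invisible(x)
}

#' Default ablation grid covering a synthetic scene
#'
#' A regular grid with the given step and radius, starting at `origin` and
#' extending as far as fits inside the scene. The default step of 18 px
#' against the default cell diameter of 18-26 px makes partial overlaps
#' and co-ablation frequent, mirroring spherical, centrifugation-deposited
#' cells where nearly all cell-associated regions overlap cells only
#' partially.
#'
#' @param scene A `synthetic_scene`.
#' @param step Grid spacing, pixels.
#' @param radius Ablation radius, pixels.
#' @param origin Center of the first region.
#' @return An [ablation_grid()].
#' @export
scene_grid <- function(scene, step = 18, radius = 9, origin = c(10, 10)) {
  sz <- dim(scene$mask)
  ablation_grid(
    origin, step, step,
    n_rows = floor((sz[1] - origin[1]) / step) + 1L,
    n_cols = floor((sz[2] - origin[2]) / step) + 1L,
    radius = radius
  )
}

#' Measurement model for simulated imaging-MS readout
#'
#' @param noise_cv Multiplicative lognormal noise coefficient of variation
#'   (0 = noiseless).
#' @param suppression_b Ion suppression exponent(s): region intensities are
#'   multiplied by `sp^b` (0 = no suppression). Scalar or named per
#'   analyte.
#' @param mcar_rate Probability that a region measurement is zeroed
#'   (missing completely at random).
#' @param lod Limit of detection: positive intensities below it are zeroed.
#' @param seed Random seed for the measurement noise.
#' @return A `measurement_model` list.
#' @export
measurement_model <- function(noise_cv = 0, suppression_b = 0,
                              mcar_rate = 0, lod = 0, seed = 1) {
  stopifnot(
    noise_cv >= 0, mcar_rate >= 0, mcar_rate <= 1, lod >= 0
  )
  structure(
    list(
      noise_cv = noise_cv, suppression_b = suppression_b,
      mcar_rate = mcar_rate, lod = lod, seed = seed
    ),
    class = "measurement_model"
  )
}

#' Simulate the imaging-MS measurement of a scene
#'
#' Computes the region-cell overlaps of the grid against the scene mask,
#' forms each region's base signal as the specific-sampling-proportion-
#' weighted sum of the overlapped cells' ground-truth signals
#' (`p = S c`), then applies, in order: per-analyte ion suppression
#' `sp^b`, multiplicative lognormal noise (mean 1), below-LOD censoring,
#' and MCAR zeroing. With all model effects off, `p` equals `S c` to
#' machine precision. The `fluorescence` column is the suppression-free,
#' noiseless base signal of the first analyte (the ground-truth proxy a
#' microscope would record).
#'
#' @param scene A `synthetic_scene`.
#' @param grid An [ablation_grid()] covering the scene.
#' @param model A [measurement_model()].
#' @return List with `intensities` (tibble `region_id`,
#'   `sampling_proportion`, `tic`, `fluorescence`, analyte columns) and
#'   `overlaps` (the unfiltered `overlap_table`).
#' @export
simulate_measurement <- function(scene, grid, model = measurement_model()) {
  overlaps <- compute_overlaps(scene$mask, grid)
  analytes <- setdiff(names(scene$ground_truth), "cell_id")
  cmat <- as.matrix(scene$ground_truth[analytes])
  rownames(cmat) <- as.character(scene$ground_truth$cell_id)
  S <- overlap_matrix(overlaps)
  n_regions <- nrow(grid)
  base <- matrix(0, n_regions, length(analytes),
    dimnames = list(NULL, analytes)
  )
  if (nrow(S) > 0L) {
    base[match(as.integer(rownames(S)), grid$region_id), ] <-
      S %*% cmat[colnames(S), , drop = FALSE]
  }
  sp <- overlaps$regions$sampling_proportion
  b <- model$suppression_b
  if (length(b) == 1L && is.null(names(b))) {
    b <- stats::setNames(rep(b, length(analytes)), analytes)
  }
  stopifnot(all(analytes %in% names(b)))
  values <- base
  set.seed(model$seed)
  for (j in seq_along(analytes)) {
    pos <- sp > 0
    values[pos, j] <- values[pos, j] * sp[pos]^b[[analytes[j]]]
  }
  if (model$noise_cv > 0) {
    sdlog <- sqrt(log(1 + model$noise_cv^2))
    values <- values * matrix(
      stats::rlnorm(length(values), -sdlog^2 / 2, sdlog),
      nrow = n_regions
    )
  }
  if (model$lod > 0) {
    values[values > 0 & values < model$lod] <- 0
  }
  if (model$mcar_rate > 0) {
    values[matrix(stats::runif(length(values)) < model$mcar_rate,
      nrow = n_regions
    )] <- 0
  }
  intensities <- tibble::tibble(
    region_id = grid$region_id,
    sampling_proportion = sp,
    tic = rowSums(values),
    fluorescence = base[, 1]
  )
  for (j in seq_along(analytes)) intensities[[analytes[j]]] <- values[, j]
  list(intensities = intensities, overlaps = overlaps)
}

#' Simulate regions along a suppression power law (no scene geometry)
#'
#' Lightweight generator for distribution-level checks of the suppression
#' fits: per-region cell content density `a ~ lognormal`, sampling
#' proportion `sp ~ uniform` with a fixed share of fully-covering regions
#' (`sp = 1`, the anchor set), fluorescence `F = a * sp`, and measured
#' intensity `I = F * sp^b * noise`, so the true suppression ratio follows
#' `sp^b` for both the fluorescence-based and the sampling-proportion-
#' based ratio.
#'
#' @param n Number of regions.
#' @param b Suppression exponent.
#' @param noise_cv Lognormal noise coefficient of variation.
#' @param seed Random seed.
#' @param anchor_fraction Share of regions with sampling proportion exactly
#'   1 (default 0.05).
#' @param content_sdlog Lognormal sdlog of the per-region content density
#'   (default 0.5; 0 makes the content constant, the exact null case).
#' @param analyte Analyte column name.
#' @return Tibble `region_id`, `sampling_proportion`, `fluorescence`,
#'   `tic`, and the analyte column.
#' @export
simulate_suppression_regions <- function(n = 500, b = -0.6, noise_cv = 0,
                                         seed = 1, anchor_fraction = 0.05,
                                         content_sdlog = 0.5,
                                         analyte = "fluorescein") {
  set.seed(seed)
  sp <- stats::runif(n, 0.02, 1)
  n_anchor <- max(2L, round(anchor_fraction * n))
  sp[sample.int(n, n_anchor)] <- 1
  a <- stats::rlnorm(n, log(100), content_sdlog)
  fl <- a * sp
  noise <- if (noise_cv > 0) {
    sdlog <- sqrt(log(1 + noise_cv^2))
    stats::rlnorm(n, -sdlog^2 / 2, sdlog)
  } else {
    rep(1, n)
  }
  intensity <- fl * sp^b * noise
  out <- tibble::tibble(
    region_id = seq_len(n), sampling_proportion = sp,
    fluorescence = fl, tic = intensity
  )
  out[[analyte]] <- intensity
  out
}

#' Synthesise centroided spectra from a region intensity table
#'
#' Builds one centroid spectrum per region: each analyte with positive
#' intensity contributes a centroid at its nominal m/z perturbed by
#' Gaussian jitter of `jitter_ppm_sd` ppm (emulating pixel-variable mass
#' accuracy, the cause of tolerance-dependent drop-outs), plus optional
#' fixed background (matrix) peaks that only contribute to the TIC.
#'
#' @param tab Region intensity table (`region_id` + analyte columns).
#' @param analytes Named numeric vector of nominal m/z per analyte column.
#' @param jitter_ppm_sd Mass-accuracy jitter, ppm (default 2).
#' @param seed Random seed.
#' @param background Named numeric vector of background peak m/z ->
#'   intensity (default two matrix peaks).
#' @return A `pixel_spectra` tibble.
#' @export
simulate_spectra <- function(tab, analytes, jitter_ppm_sd = 2, seed = 1,
                             background = c(`340.0` = 500, `372.3` = 800)) {
  stopifnot(!is.null(names(analytes)))
  set.seed(seed)
  bg_mz <- as.numeric(names(background))
  rows <- lapply(seq_len(nrow(tab)), function(i) {
    mz <- bg_mz
    it <- as.numeric(background)
    for (a in names(analytes)) {
      v <- tab[[a]][i]
      if (v > 0) {
        mz <- c(mz, analytes[[a]] * (1 + stats::rnorm(1) * jitter_ppm_sd * 1e-6))
        it <- c(it, v)
      }
    }
    o <- order(mz)
    tibble::tibble(
      pixel_index = tab$region_id[i], x = NA_real_, y = NA_real_,
      mz = list(mz[o]), intensity = list(it[o])
    )
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("pixel_spectra", class(out))
  out
}
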