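# End-to-end orchestration: simulate -> overlaps -> (peaks) ->
# normalise/compensate -> filter -> deconvolve -> evaluate, plus the
# cutoff / m/z-tolerance parameter sweeps.

#' Default pipeline configuration
#'
#' Returns the resolved configuration list for [run_pipeline()] /
#' [sweep_parameter()], with any supplied values overriding the defaults.
#' Defaults describe the synthetic study conditions: 100 spherical cells
#' of radius 9-13 px on a 512 x 512 image, an 18 px grid of 9 px-radius
#' ablated regions (step about 0.8 x cell diameter, so co-ablation is
#' frequent), four-level dye ground truth, lognormal measurement noise
#' (CV 0.2), suppression exponent -0.6, and the deconvolution cutoffs
#' found optimal (sampling proportion 0.3, specificity 0).
#'
#' @param ... Named overrides of any default.
#' @return Named list of settings.
#' @export
pipeline_config <- function(...) {
  defaults <- list(
    seed = 1L,
    n_cells = 100L,
    image_size = c(512L, 512L),
    radius_range = c(9, 13),
    grid_step = 18,
    grid_radius = 9,
    grid_origin = c(10, 10),
    signal_levels = c(25, 50, 75, 100),
    signal_cv = 0.2,
    noise_cv = 0.2,
    suppression_b = -0.6,
    mcar_rate = 0,
    lod = 0,
    tic_normalise = FALSE,
    compensation = "none", # none | supervised | unsupervised
    min_points = 10,
    min_sp = 0.1,
    methods = c("wa", "lim", "mix"),
    sp_cutoff = 0.3,
    spec_cutoff = 0,
    drop_zero_analyte = NULL,
    analyte = "fluorescein",
    analyte_mz = c(fluorescein = 331.0612),
    tol_ppm = 3,
    jitter_ppm_sd = 2,
    weight_scheme = "one_minus"
  )
  overrides <- list(...)
  if (length(overrides) == 1L && is.list(overrides[[1]]) &&
    is.null(names(overrides))) {
    overrides <- overrides[[1]]
  }
  unknown <- setdiff(names(overrides), names(defaults))
  if (length(unknown) > 0L) {
    stop("unknown config keys: ", paste(unknown, collapse = ", "),
      call. = FALSE
    )
  }
  utils::modifyList(defaults, overrides)
}

# simulate inputs and apply normalisation/compensation once
pipeline_inputs <- function(config) {
  scene <- simulate_scene(
    n_cells = config$n_cells, image_size = config$image_size,
    radius_range = config$radius_range,
    signal_sampler = signal_sampler_fda(
      levels = config$signal_levels, cv = config$signal_cv,
      analyte = config$analyte
    ),
    seed = config$seed
  )
  grid <- scene_grid(scene,
    step = config$grid_step, radius = config$grid_radius,
    origin = config$grid_origin
  )
  meas <- simulate_measurement(
    scene, grid,
    measurement_model(
      noise_cv = config$noise_cv, suppression_b = config$suppression_b,
      mcar_rate = config$mcar_rate, lod = config$lod,
      seed = config$seed + 1000L
    )
  )
  list(scene = scene, grid = grid, measurement = meas)
}

apply_normalisation <- function(tab, config) {
  fits <- NULL
  if (isTRUE(config$tic_normalise)) tab <- tic_normalize(tab)
  if (config$compensation == "supervised") {
    res <- compensate_supervised(tab, config$analyte,
      min_sp = config$min_sp
    )
    tab <- res$table
    fits <- structure(
      stats::setNames(list(res$fit), config$analyte),
      class = "suppression_fits"
    )
  } else if (config$compensation == "unsupervised") {
    res <- compensate_unsupervised(tab,
      min_points = config$min_points, min_sp = config$min_sp
    )
    tab <- res$table
    fits <- res$fits
  }
  list(table = tab, fits = fits)
}

deconvolve_by <- function(method, tab, filtered) {
  switch(method,
    wa = deconvolve_wa(tab, filtered),
    lim = deconvolve_lim(tab, filtered),
    mix = deconvolve_mix(tab, filtered),
    stop("unknown method: ", method, call. = FALSE)
  )
}

evaluate_profiles <- function(profiles, scene, analyte, scheme) {
  truth <- scene$ground_truth[[analyte]][
    match(profiles$cell_id, scene$ground_truth$cell_id)
  ]
  est <- profiles[[analyte]]
  tibble::tibble(
    method = attr(profiles, "method"),
    weighted_rho = density_weighted_spearman(truth, est, scheme = scheme),
    n_cells = nrow(profiles),
    n_assigned = sum(profiles$status != "not_associated"),
    assigned_fraction = mean(profiles$status != "not_associated")
  )
}

#' Run the synthetic end-to-end pipeline
#'
#' Simulates a scene and its measurement, applies the configured
#' normalisation/compensation, filters overlaps, deconvolves with each
#' configured method, and evaluates the per-cell estimates against the
#' simulated ground truth with the density-weighted Spearman correlation.
#' Deterministic given `config$seed`. When `out_dir` is given, the mask,
#' tables, per-method profiles, suppression fits, summary JSON and the
#' exact resolved configuration are written there.
#'
#' @param config A [pipeline_config()] (or named list of overrides).
#' @param out_dir Optional output directory.
#' @return A `pipeline_result`: list with `summary` (tibble: `method`,
#'   `weighted_rho`, `n_cells`, `n_assigned`, `assigned_fraction`),
#'   `profiles` (named list of `cell_profiles`), `scene`, `grid`,
#'   `intensities`, `overlaps`, `filtered`, `fits`, `config`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  config <- pipeline_config(config)
  inputs <- pipeline_inputs(config)
  norm <- apply_normalisation(inputs$measurement$intensities, config)
  filtered <- filter_overlaps(
    inputs$measurement$overlaps,
    sp_cutoff = config$sp_cutoff, spec_cutoff = config$spec_cutoff,
    intensities = norm$table, drop_zero_analyte = config$drop_zero_analyte
  )
  profiles <- lapply(config$methods, deconvolve_by,
    tab = norm$table, filtered = filtered
  )
  names(profiles) <- config$methods
  summary <- dplyr::bind_rows(lapply(
    profiles, evaluate_profiles,
    scene = inputs$scene, analyte = config$analyte,
    scheme = config$weight_scheme
  ))
  result <- structure(
    list(
      summary = summary, profiles = profiles, scene = inputs$scene,
      grid = inputs$grid, intensities = norm$table,
      overlaps = inputs$measurement$overlaps, filtered = filtered,
      fits = norm$fits, config = config
    ),
    class = "pipeline_result"
  )
  if (!is.null(out_dir)) {
    write_pipeline_result(result, out_dir)
  }
  result
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  print(x$summary)
  invisible(x)
}

write_pipeline_result <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_mask(result$scene$mask, file.path(out_dir, "mask.tif"))
  write_overlap_table(result$overlaps, file.path(out_dir, "overlaps.tsv"))
  write_region_table(
    dplyr::select(
      result$intensities, -dplyr::any_of("sampling_proportion")
    ),
    file.path(out_dir, "regions.tsv")
  )
  readr::write_tsv(
    result$scene$ground_truth,
    file.path(out_dir, "ground_truth.tsv")
  )
  for (m in names(result$profiles)) {
    write_cell_profiles(
      result$profiles[[m]],
      file.path(out_dir, paste0("cells_", m, ".tsv"))
    )
  }
  if (!is.null(result$fits)) {
    write_suppression_fits(
      result$fits, file.path(out_dir, "suppression_fits.tsv")
    )
  }
  jsonlite::write_json(
    result$summary, file.path(out_dir, "summary.json"),
    dataframe = "rows", digits = NA
  )
  cfg <- result$config
  cfg$drop_zero_analyte <- cfg$drop_zero_analyte %||% "none"
  cfg$analyte_mz <- unname(cfg$analyte_mz)
  write_config(cfg, file.path(out_dir, "config.toml"))
  invisible(out_dir)
}

#' Sweep a filtering or integration parameter
#'
#' Re-evaluates the pipeline over a grid of values for one parameter,
#' sharing the simulated inputs across values. For `sp_cutoff` and
#' `spec_cutoff` the same measured table is re-filtered per value; for
#' `tol_ppm`, centroided spectra with mass-accuracy jitter are synthesised
#' once and re-integrated per tolerance (the `zero_fraction` column then
#' reports the drop-out fraction). The first configured method is used.
#'
#' @param config A [pipeline_config()] (or overrides list).
#' @param parameter One of `"sp_cutoff"`, `"spec_cutoff"`, `"tol_ppm"`.
#' @param values Ascending numeric vector of parameter values.
#' @return A tibble with `parameter`, `value`, `weighted_rho`,
#'   `assigned_fraction`, and `zero_fraction` for tolerance sweeps.
#' @export
sweep_parameter <- function(config, parameter, values) {
  parameter <- match.arg(parameter, c("sp_cutoff", "spec_cutoff", "tol_ppm"))
  stopifnot(!is.unsorted(values))
  config <- pipeline_config(config)
  method <- config$methods[1]
  inputs <- pipeline_inputs(config)
  scene <- inputs$scene
  meas <- inputs$measurement

  eval_one <- function(tab, sp_cutoff, spec_cutoff) {
    norm <- apply_normalisation(tab, config)
    filtered <- filter_overlaps(
      meas$overlaps,
      sp_cutoff = sp_cutoff, spec_cutoff = spec_cutoff,
      intensities = norm$table,
      drop_zero_analyte = config$drop_zero_analyte
    )
    profiles <- deconvolve_by(method, norm$table, filtered)
    evaluate_profiles(
      profiles, scene, config$analyte, config$weight_scheme
    )
  }

  if (parameter %in% c("sp_cutoff", "spec_cutoff")) {
    rows <- lapply(values, function(v) {
      res <- eval_one(
        meas$intensities,
        sp_cutoff = if (parameter == "sp_cutoff") v else config$sp_cutoff,
        spec_cutoff = if (parameter == "spec_cutoff") v else config$spec_cutoff
      )
      tibble::tibble(
        parameter = parameter, value = v,
        weighted_rho = res$weighted_rho,
        assigned_fraction = res$assigned_fraction
      )
    })
    return(dplyr::bind_rows(rows))
  }

  # tol_ppm sweep: synthesise jittered centroids once, re-integrate per tol
  spectra <- simulate_spectra(
    meas$intensities, config$analyte_mz,
    jitter_ppm_sd = config$jitter_ppm_sd, seed = config$seed + 2000L
  )
  zf <- zero_fraction_curve(
    spectra, config$analyte_mz[[config$analyte]], values
  )
  rows <- lapply(seq_along(values), function(i) {
    tab <- build_region_table(spectra, config$analyte_mz,
      tol_ppm = values[i]
    )
    tab$sampling_proportion <- meas$intensities$sampling_proportion
    tab$fluorescence <- meas$intensities$fluorescence
    res <- eval_one(tab, config$sp_cutoff, config$spec_cutoff)
    tibble::tibble(
      parameter = parameter, value = values[i],
      weighted_rho = res$weighted_rho,
      assigned_fraction = res$assigned_fraction,
      zero_fraction = zf$zero_fraction[i]
    )
  })
  dplyr::bind_rows(rows)
}
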