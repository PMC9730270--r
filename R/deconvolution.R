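# Pixel-cell deconvolution: filtering, weighted average (WA), linear
# inverse modelling (LIM, non-negative least squares on the specific
# sampling proportion matrix), and the MIX strategy that falls back to WA
# for cells in underdetermined subnetworks.

#' Filter an overlap table before deconvolution
#'
#' Removes ablated regions whose sampling proportion is below `sp_cutoff`
#' (and regions with no cellular overlap at all), removes (region, cell)
#' pairs whose sampling specificity is below `spec_cutoff`, and optionally
#' removes regions with a zero measured intensity for one analyte
#' (drop-out filtering). Surviving specificities are NOT renormalised: they
#' keep their original values, preserving the weighted-average semantics.
#'
#' Defaults are a sampling-proportion cutoff of 0.3 and a specificity
#' cutoff of 0, the combination found to maximise quantitation while
#' retaining most cells.
#'
#' @param overlaps An `overlap_table` from [compute_overlaps()].
#' @param sp_cutoff,spec_cutoff Cutoffs in `[0, 1]`; regions/pairs strictly
#'   below the cutoff are removed.
#' @param intensities Region intensity table (needed for
#'   `drop_zero_analyte`).
#' @param drop_zero_analyte Analyte column name; regions whose intensity
#'   for it is 0 are removed.
#' @param pair_level If `FALSE`, the specificity cutoff removes whole
#'   regions containing any low-specificity pair instead of just the pairs.
#' @return A filtered `overlap_table` carrying its filter settings.
#' @export
filter_overlaps <- function(overlaps, sp_cutoff = 0.3, spec_cutoff = 0,
                            intensities = NULL, drop_zero_analyte = NULL,
                            pair_level = TRUE) {
  if (sp_cutoff < 0 || sp_cutoff > 1 || spec_cutoff < 0 || spec_cutoff > 1) {
    stop("cutoffs must lie in [0, 1]", call. = FALSE)
  }
  regions <- overlaps$regions |>
    dplyr::filter(
      .data$sampling_proportion >= sp_cutoff,
      .data$sampling_proportion > 0
    )
  pairs <- overlaps$pairs |>
    dplyr::semi_join(regions, by = "region_id")
  if (!is.null(drop_zero_analyte)) {
    if (is.null(intensities)) {
      stop("drop_zero_analyte requires `intensities`", call. = FALSE)
    }
    nonzero <- intensities$region_id[intensities[[drop_zero_analyte]] != 0]
    regions <- dplyr::filter(regions, .data$region_id %in% nonzero)
    pairs <- dplyr::filter(pairs, .data$region_id %in% nonzero)
  }
  if (spec_cutoff > 0) {
    if (pair_level) {
      pairs <- dplyr::filter(pairs, .data$specificity >= spec_cutoff)
    } else {
      bad <- unique(pairs$region_id[pairs$specificity < spec_cutoff])
      pairs <- dplyr::filter(pairs, !.data$region_id %in% bad)
      regions <- dplyr::filter(regions, !.data$region_id %in% bad)
    }
  }
  new_overlap_table(regions, pairs,
    cell_ids = overlaps$cell_ids,
    filter_settings = list(
      sp_cutoff = sp_cutoff, spec_cutoff = spec_cutoff,
      drop_zero_analyte = drop_zero_analyte %||% NA,
      pair_level = pair_level
    )
  )
}

new_cell_profiles <- function(values, cell_ids, method, filter_settings) {
  out <- tibble::tibble(cell_id = cell_ids) |>
    dplyr::left_join(values, by = "cell_id")
  analytes <- setdiff(names(out), "cell_id")
  vals <- as.matrix(out[analytes])
  status <- dplyr::case_when(
    apply(vals, 1, function(v) all(is.na(v))) ~ "not_associated",
    apply(vals, 1, function(v) all(v == 0)) ~ "zero",
    TRUE ~ "assigned"
  )
  out <- tibble::add_column(out, status = status, .after = "cell_id")
  structure(out,
    method = method, filter_settings = filter_settings,
    class = c("cell_profiles", class(out))
  )
}

#' @export
print.cell_profiles <- function(x, ...) {
  cat(sprintf(
    "<cell_profiles> method %s: %d cells (%d assigned, %d zero, %d not associated)\n",
    attr(x, "method"), nrow(x), sum(x$status == "assigned"),
    sum(x$status == "zero"), sum(x$status == "not_associated")
  ))
  NextMethod()
}

check_deconv_inputs <- function(intensities, overlaps) {
  missing <- setdiff(overlaps$pairs$region_id, intensities$region_id)
  if (length(missing) > 0L) {
    stop(
      "intensity table lacks ", length(missing),
      " regions present in the overlap table", call. = FALSE
    )
  }
}

#' Weighted-average pixel-cell deconvolution
#'
#' Region intensities are first divided by their sampling proportion, then
#' each cell is assigned the specificity-weighted average of its regions'
#' normalised intensities:
#' `S_cell(k) = sum_r spec[r,k] * (I_r / sp_r) / sum_r spec[r,k]`.
#' Cells overlapped by no included region get `NA` (status
#' `not_associated`); all-zero results get status `zero`.
#'
#' @param intensities Region intensity table (`region_id` + analyte
#'   columns).
#' @param overlaps A filtered `overlap_table`; all its regions must have
#'   `sampling_proportion > 0`.
#' @param analytes Analyte columns to deconvolve (default: all).
#' @return A `cell_profiles` tibble (`cell_id`, `status`, analyte columns).
#' @export
deconvolve_wa <- function(intensities, overlaps, analytes = NULL) {
  analytes <- analytes %||% analyte_columns(intensities)
  check_deconv_inputs(intensities, overlaps)
  stopifnot(all(overlaps$regions$sampling_proportion > 0))
  joined <- overlaps$pairs |>
    dplyr::inner_join(
      intensities[c("region_id", analytes)],
      by = "region_id"
    )
  values <- joined |>
    dplyr::group_by(.data$cell_id) |>
    dplyr::summarise(dplyr::across(
      dplyr::all_of(analytes),
      ~ sum(.data$specificity * .x / .data$sampling_proportion) /
        sum(.data$specificity)
    ), .groups = "drop")
  new_cell_profiles(values, overlaps$cell_ids, "wa", overlaps$filter_settings)
}

#' Linear-inverse-modelling pixel-cell deconvolution
#'
#' Models the region intensity vector p as `S c` where S is the region x
#' cell matrix of specific sampling proportions and c the unknown
#' non-negative cell intensities, and estimates c by non-negative least
#' squares. The problem decomposes over connected components of the
#' region-cell graph and is solved per component (identical optimum,
#' bounded problem size). Each analyte column is solved independently
#' against the same S. Cells with an all-zero S column (no included
#' overlap) get `NA`.
#'
#' @inheritParams deconvolve_wa
#' @return A `cell_profiles` tibble.
#' @export
deconvolve_lim <- function(intensities, overlaps, analytes = NULL) {
  analytes <- analytes %||% analyte_columns(intensities)
  check_deconv_inputs(intensities, overlaps)
  S <- overlap_matrix(overlaps)
  if (nrow(S) == 0L) {
    values <- tibble::tibble(cell_id = integer(0))
    for (a in analytes) values[[a]] <- numeric(0)
    return(new_cell_profiles(
      values, overlaps$cell_ids, "lim", overlaps$filter_settings
    ))
  }
  p <- as.matrix(
    intensities[match(as.integer(rownames(S)), intensities$region_id),
      analytes,
      drop = FALSE
    ]
  )
  comp <- matrix_components(S)
  cell_ids <- as.integer(colnames(S))
  est <- matrix(NA_real_, ncol(S), length(analytes),
    dimnames = list(colnames(S), analytes)
  )
  for (cc in unique(comp$cell_component)) {
    cols <- which(comp$cell_component == cc)
    rows <- which(rowSums(S[, cols, drop = FALSE] != 0) > 0)
    Sc <- S[rows, cols, drop = FALSE]
    for (j in seq_along(analytes)) {
      fit <- tryCatch(
        nnls_fit(Sc, p[rows, j]),
        error = function(e) {
          stop("NNLS failed in component ", cc, ": ", conditionMessage(e),
            call. = FALSE
          )
        }
      )
      if (fit$rank_deficient) {
        message(
          "component ", cc, ": rank-deficient design; ",
          "returning one feasible least-squares solution"
        )
      }
      est[cols, j] <- fit$x
    }
  }
  values <- tibble::tibble(cell_id = cell_ids)
  for (j in seq_along(analytes)) values[[analytes[j]]] <- unname(est[, j])
  new_cell_profiles(values, overlaps$cell_ids, "lim", overlaps$filter_settings)
}

# connected components of the bipartite graph implied by the nonzero
# pattern of S (used only to decompose the NNLS problem)
matrix_components <- function(S) {
  nz <- which(S != 0, arr.ind = TRUE)
  g <- igraph::graph_from_edgelist(
    cbind(
      paste0("r", rownames(S)[nz[, 1]]),
      paste0("c", colnames(S)[nz[, 2]])
    ),
    directed = FALSE
  )
  memb <- igraph::components(g)$membership
  cell_component <- memb[paste0("c", colnames(S))]
  cell_component[is.na(cell_component)] <- -seq_len(sum(is.na(cell_component)))
  list(cell_component = unname(cell_component))
}

#' Connected components of the region-cell overlap graph
#'
#' Cells and ablated regions form a bipartite graph with an edge wherever
#' a region overlaps a cell (specificity > 0) and the region's sampling
#' proportion exceeds `edge_sp_threshold`. A cell is underdetermined when
#' its connected component contains more cells than regions; such cells
#' have no unique linear-inverse solution.
#'
#' @param overlaps An `overlap_table`.
#' @param edge_sp_threshold Sampling-proportion threshold for an edge
#'   (strict `>`; default 0.3).
#' @return A `component_assignment`: list with tibbles `cells` (`cell_id`,
#'   `component`, `underdetermined`), `regions` (`region_id`, `component`)
#'   and `summary` (`component`, `n_cells`, `n_regions`,
#'   `underdetermined`). Cells with no qualifying edge form singleton
#'   components with zero regions (hence underdetermined).
#' @export
find_components <- function(overlaps, edge_sp_threshold = 0.3) {
  edges <- overlaps$pairs |>
    dplyr::filter(
      .data$specificity > 0,
      .data$sampling_proportion > edge_sp_threshold
    )
  g <- igraph::make_empty_graph(directed = FALSE)
  cell_v <- paste0("c", overlaps$cell_ids)
  region_v <- paste0("r", sort(unique(edges$region_id)))
  g <- igraph::add_vertices(g, length(cell_v) + length(region_v),
    name = c(cell_v, region_v)
  )
  if (nrow(edges) > 0L) {
    g <- igraph::add_edges(g, rbind(
      paste0("r", edges$region_id),
      paste0("c", edges$cell_id)
    ))
  }
  memb <- igraph::components(g)$membership
  cells <- tibble::tibble(
    cell_id = overlaps$cell_ids,
    component = unname(memb[cell_v])
  )
  regions <- tibble::tibble(
    region_id = sort(unique(edges$region_id)),
    component = unname(memb[region_v])
  )
  summary <- dplyr::full_join(
    dplyr::count(cells, .data$component, name = "n_cells"),
    dplyr::count(regions, .data$component, name = "n_regions"),
    by = "component"
  ) |>
    tidyr::replace_na(list(n_cells = 0L, n_regions = 0L)) |>
    dplyr::mutate(underdetermined = .data$n_cells > .data$n_regions) |>
    dplyr::arrange(.data$component)
  cells <- cells |>
    dplyr::left_join(
      summary[c("component", "underdetermined")],
      by = "component"
    )
  structure(
    list(cells = cells, regions = regions, summary = summary),
    class = "component_assignment"
  )
}

#' @export
print.component_assignment <- function(x, ...) {
  cat(sprintf(
    "<component_assignment> %d components; %d/%d cells underdetermined\n",
    nrow(x$summary), sum(x$cells$underdetermined), nrow(x$cells)
  ))
  invisible(x)
}

#' Mixed pixel-cell deconvolution
#'
#' Runs both WA and LIM, then assigns each cell the WA value if it belongs
#' to an underdetermined subnetwork (more cells than regions, see
#' [find_components()]) and the LIM value otherwise.
#'
#' @inheritParams deconvolve_wa
#' @param edge_sp_threshold Sampling-proportion threshold defining graph
#'   edges for the underdetermined classification (default 0.3).
#' @return A `cell_profiles` tibble; the attribute `underdetermined` holds
#'   the per-cell flag used for the splice.
#' @export
deconvolve_mix <- function(intensities, overlaps, analytes = NULL,
                           edge_sp_threshold = 0.3) {
  analytes <- analytes %||% analyte_columns(intensities)
  wa <- deconvolve_wa(intensities, overlaps, analytes)
  lim <- deconvolve_lim(intensities, overlaps, analytes)
  comp <- find_components(overlaps, edge_sp_threshold)
  under <- comp$cells$underdetermined[match(wa$cell_id, comp$cells$cell_id)]
  values <- tibble::tibble(cell_id = wa$cell_id)
  for (a in analytes) {
    values[[a]] <- ifelse(under, wa[[a]], lim[[a]])
  }
  out <- new_cell_profiles(
    values, overlaps$cell_ids, "mix", overlaps$filter_settings
  )
  attr(out, "underdetermined") <- under
  out
}

#' Write cell profiles to TSV (N/A encoded as literal "NA")
#'
#' @param profiles A `cell_profiles` tibble.
#' @param path Output path.
#' @export
write_cell_profiles <- function(profiles, path) {
  readr::write_tsv(tibble::as_tibble(profiles), path, na = "NA")
  invisible(path)
}
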