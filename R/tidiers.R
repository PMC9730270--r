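# broom-style tidiers for fitted objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a suppression fit
#'
#' @param x A `suppression_fit` or `suppression_fits` object.
#' @param ... Unused.
#' @return One row per analyte: `analyte`, `mode`, `slope`, `intercept`,
#'   `n_points`, `fallback`, `anchored`.
#' @method tidy suppression_fit
#' @export
tidy.suppression_fit <- function(x, ...) {
  tibble::tibble(
    analyte = x$analyte, mode = x$mode, slope = x$slope,
    intercept = x$intercept, n_points = x$n_points,
    fallback = x$fallback, anchored = x$anchored
  )
}

#' @rdname tidy.suppression_fit
#' @method tidy suppression_fits
#' @export
tidy.suppression_fits <- function(x, ...) {
  dplyr::bind_rows(lapply(x, tidy.suppression_fit))
}

#' @rdname tidy.suppression_fit
#' @method glance suppression_fits
#' @export
glance.suppression_fits <- function(x, ...) {
  td <- tidy.suppression_fits(x)
  tibble::tibble(
    n_analytes = nrow(td),
    n_fallback = sum(td$fallback),
    median_slope = stats::median(td$slope[!td$fallback])
  )
}

#' Tidy a component assignment
#'
#' @param x A `component_assignment` from [find_components()].
#' @param ... Unused.
#' @return The per-cell tibble (`cell_id`, `component`, `underdetermined`).
#' @method tidy component_assignment
#' @export
tidy.component_assignment <- function(x, ...) x$cells

#' @rdname tidy.component_assignment
#' @method glance component_assignment
#' @export
glance.component_assignment <- function(x, ...) {
  tibble::tibble(
    n_components = nrow(x$summary),
    n_cells = nrow(x$cells),
    n_underdetermined = sum(x$cells$underdetermined),
    underdetermined_fraction = mean(x$cells$underdetermined)
  )
}

#' Tidy an intermixing result
#'
#' @param x An `intermixing` object.
#' @param ... Unused.
#' @return Per-cell fractions; `glance()` returns `mean`, `sd`, `k`.
#' @method tidy intermixing
#' @export
tidy.intermixing <- function(x, ...) x$per_cell

#' @rdname tidy.intermixing
#' @method glance intermixing
#' @export
glance.intermixing <- function(x, ...) {
  tibble::tibble(mean = x$mean, sd = x$sd, k = x$k)
}

#' Tidy cell profiles into long form
#'
#' @param x A `cell_profiles` tibble.
#' @param ... Unused.
#' @return Long tibble `cell_id`, `status`, `analyte`, `value`.
#' @method tidy cell_profiles
#' @export
tidy.cell_profiles <- function(x, ...) {
  tibble::as_tibble(x) |>
    tidyr::pivot_longer(
      cols = -c("cell_id", "status"),
      names_to = "analyte", values_to = "value"
    )
}

#' @rdname tidy.cell_profiles
#' @method glance cell_profiles
#' @export
glance.cell_profiles <- function(x, ...) {
  tibble::tibble(
    method = attr(x, "method"),
    n_cells = nrow(x),
    n_assigned = sum(x$status == "assigned"),
    n_zero = sum(x$status == "zero"),
    n_not_associated = sum(x$status == "not_associated"),
    assigned_fraction = mean(x$status != "not_associated")
  )
}
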