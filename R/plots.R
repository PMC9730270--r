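# ggplot2 diagnostics for the main result types.

#' Plot a suppression fit (log-log ratio vs sampling proportion)
#'
#' @param object A `suppression_fit` with fit data attached.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot suppression_fit
#' @export
autoplot.suppression_fit <- function(object, ...) {
  if (is.null(object$data)) {
    stop("fit carries no data (fallback fit); nothing to plot",
      call. = FALSE
    )
  }
  ggplot2::ggplot(
    object$data,
    ggplot2::aes(x = .data$sampling_proportion, y = .data$ratio)
  ) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::geom_function(
      fun = function(sp) predict(object, sp),
      colour = "red"
    ) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(
      x = "sampling proportion",
      y = if (object$mode == "supervised_eta") {
        "scaled ratio (MS / fluorescence)"
      } else {
        "ratio (MS / sampling proportion)"
      },
      title = sprintf(
        "%s: slope %.3f (%s)", object$analyte, object$slope, object$mode
      )
    )
}

#' Plot the sampling-proportion distribution of an overlap table
#'
#' @param object An `overlap_table`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot overlap_table
#' @export
autoplot.overlap_table <- function(object, ...) {
  ggplot2::ggplot(
    object$regions,
    ggplot2::aes(x = .data$sampling_proportion)
  ) +
    ggplot2::geom_histogram(bins = 30, boundary = 0) +
    ggplot2::labs(
      x = "sampling proportion", y = "ablated regions"
    )
}

#' Scatter of assigned cell values against ground truth
#'
#' @param profiles A `cell_profiles` tibble.
#' @param truth Tibble with `cell_id` and the ground-truth analyte column.
#' @param analyte Analyte column name.
#' @return A ggplot; the subtitle reports the density-weighted Spearman
#'   correlation.
#' @export
plot_quantitation <- function(profiles, truth, analyte) {
  df <- tibble::as_tibble(profiles) |>
    dplyr::inner_join(
      dplyr::select(
        truth, "cell_id",
        truth_value = dplyr::all_of(analyte)
      ),
      by = "cell_id"
    )
  rho <- density_weighted_spearman(df$truth_value, df[[analyte]])
  ggplot2::ggplot(
    df, ggplot2::aes(x = .data$truth_value, y = .data[[analyte]])
  ) +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::labs(
      x = "ground truth", y = paste("assigned", analyte),
      title = paste("method:", attr(profiles, "method")),
      subtitle = sprintf("density-weighted Spearman rho = %.3f", rho)
    )
}

#' Plot a parameter sweep
#'
#' Correlation, assigned-cell fraction (and drop-out fraction for
#' tolerance sweeps) against the swept parameter value.
#'
#' @param sweep Output of [sweep_parameter()].
#' @return A ggplot.
#' @export
plot_sweep <- function(sweep) {
  long <- sweep |>
    tidyr::pivot_longer(
      cols = -c("parameter", "value"),
      names_to = "metric", values_to = "y"
    )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$value, y = .data$y)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = unique(sweep$parameter), y = NULL)
}
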