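# Ion suppression estimation and compensation. The intensity-to-content
# ratio of an analyte declines with the sampling proportion of the ablated
# region, approximately as a power law (linear in log-log). The decline is
# estimated by median (quantile) regression, robust to drop-outs and
# heavy-tailed intensity noise, and compensated by dividing intensities by
# the predicted ratio, anchored so regions fully covering cells
# (sampling proportion 1) are left unchanged.

#' Quantile (median) regression line for one predictor
#'
#' Finds `(slope, intercept)` minimising the check loss
#' `sum_i rho_tau(y_i - slope * x_i - intercept)`; at `tau = 0.5` this is
#' least-absolute-deviations (median) regression. The objective, profiled
#' over the intercept (a quantile of the residuals), is convex piecewise
#' linear in the slope; it is minimised by golden-section search and then
#' polished over nearby two-point breakpoint slopes, which contain the
#' exact optimum.
#'
#' @param x,y Finite numeric vectors; at least 2 distinct `x` values.
#' @param quantile Quantile level in (0, 1); default 0.5 (median).
#' @return Named numeric vector `c(slope, intercept)`.
#' @export
fit_quantile_line <- function(x, y, quantile = 0.5) {
  stopifnot(length(x) == length(y), quantile > 0, quantile < 1)
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]
  y <- y[ok]
  if (length(unique(x)) < 2L) {
    stop("need at least 2 distinct x values for a line fit", call. = FALSE)
  }
  tau <- quantile
  intercept_for <- function(r) {
    if (tau == 0.5) {
      stats::median(r)
    } else {
      stats::quantile(r, tau, type = 1, names = FALSE)
    }
  }
  check_loss <- function(r) sum(pmax(tau * r, (tau - 1) * r))
  profile_loss <- function(a) {
    r <- y - a * x
    check_loss(r - intercept_for(r))
  }
  # candidate breakpoint slopes: lines through two data points
  idx <- if (length(x) > 1200L) sample.int(length(x), 1200L) else seq_along(x)
  dx <- outer(x[idx], x[idx], "-")
  dy <- outer(y[idx], y[idx], "-")
  slopes <- dy[lower.tri(dx)] / dx[lower.tri(dx)]
  slopes <- sort(unique(slopes[is.finite(slopes)]))
  lo <- min(slopes)
  hi <- max(slopes)
  a_opt <- if (lo == hi) {
    lo
  } else {
    stats::optimize(profile_loss, c(lo, hi), tol = 1e-10)$minimum
  }
  near <- slopes[order(abs(slopes - a_opt))]
  near <- near[seq_len(min(length(near), 200L))]
  cand <- c(a_opt, near)
  losses <- vapply(cand, profile_loss, numeric(1))
  a_best <- cand[which.min(losses)]
  r <- y - a_best * x
  c(slope = a_best, intercept = intercept_for(r))
}

new_suppression_fit <- function(analyte, mode, slope, intercept, n_points,
                                fallback = FALSE, anchored = TRUE,
                                anchor_median = NA_real_, data = NULL) {
  structure(
    list(
      analyte = analyte, mode = mode, slope = unname(slope),
      intercept = unname(intercept), n_points = n_points,
      fallback = fallback, anchored = anchored,
      anchor_median = anchor_median, data = data
    ),
    class = "suppression_fit"
  )
}

#' Predicted suppression ratio at given sampling proportions
#'
#' Anchored fits predict `sp^slope` (exactly 1 at `sp = 1`); un-anchored
#' fits keep the fitted intercept: `exp(intercept) * sp^slope`.
#'
#' @param object A `suppression_fit`.
#' @param sp Sampling proportions (> 0).
#' @param ... Unused.
#' @return Predicted ratio per element of `sp`.
#' @export
predict.suppression_fit <- function(object, sp, ...) {
  if (object$anchored) {
    sp^object$slope
  } else {
    exp(object$intercept) * sp^object$slope
  }
}

#' @export
print.suppression_fit <- function(x, ...) {
  cat(sprintf(
    "<suppression_fit> %s (%s): slope %.4f, intercept %.4f, n = %d%s%s\n",
    x$analyte, x$mode, x$slope, x$intercept, x$n_points,
    if (x$fallback) ", fallback" else "",
    if (x$anchored) ", anchored" else ""
  ))
  invisible(x)
}

apply_correction <- function(intensity, sp, fit) {
  pos <- sp > 0
  out <- intensity
  out[pos] <- intensity[pos] / predict(fit, sp[pos])
  out
}

#' Supervised ion suppression compensation (fluorescence-anchored)
#'
#' For each region, the ratio eta = MS intensity / fluorescence measures
#' the per-region MS response. Ratios from regions with sampling proportion
#' above `min_sp` (and positive intensity and fluorescence) are scaled by
#' the median eta of fully-covering regions (sampling proportion 1 within
#' `sp_one_tol`), then a median regression of log eta on log sampling
#' proportion estimates the suppression power law. Intensities of all
#' regions with positive sampling proportion are divided by the predicted
#' ratio; with `anchor = TRUE` (default) the prediction is pinned to 1 at
#' sampling proportion 1, so fully-covering regions are (asymptotically)
#' unchanged.
#'
#' @param tab Region table with columns `sampling_proportion`,
#'   `fluorescence`, and the analyte column.
#' @param analyte Analyte column name to correct.
#' @param min_sp Minimum sampling proportion for a region to enter the fit
#'   (default 0.1).
#' @param sp_one_tol Regions with `sampling_proportion >= 1 - sp_one_tol`
#'   form the anchor set (default 1e-6).
#' @param anchor Pin the predicted ratio to 1 at sampling proportion 1
#'   (default TRUE).
#' @return List with `table` (the input with the analyte column corrected)
#'   and `fit` (a `suppression_fit`; its `data` holds the scaled ratios
#'   used).
#' @export
compensate_supervised <- function(tab, analyte, min_sp = 0.1,
                                  sp_one_tol = 1e-6, anchor = TRUE) {
  stopifnot(all(c("sampling_proportion", "fluorescence", analyte) %in%
    names(tab)))
  intensity <- tab[[analyte]]
  fl <- tab$fluorescence
  sp <- tab$sampling_proportion
  if (all(intensity == 0)) {
    stop("all intensities are zero for analyte ", analyte, call. = FALSE)
  }
  sel <- sp > min_sp & fl > 0 & intensity > 0
  eta <- intensity[sel] / fl[sel]
  sp_sel <- sp[sel]
  anchor_set <- sp_sel >= 1 - sp_one_tol
  if (!any(anchor_set)) {
    stop(
      "no regions with sampling proportion of 1 to anchor the ratio; ",
      "consider relaxing sp_one_tol", call. = FALSE
    )
  }
  anchor_median <- stats::median(eta[anchor_set])
  eta_scaled <- eta / anchor_median
  coefs <- fit_quantile_line(log(sp_sel), log(eta_scaled))
  fit <- new_suppression_fit(
    analyte, "supervised_eta", coefs["slope"], coefs["intercept"],
    n_points = sum(sel), anchored = anchor, anchor_median = anchor_median,
    data = tibble::tibble(sampling_proportion = sp_sel, ratio = eta_scaled)
  )
  tab[[analyte]] <- apply_correction(intensity, sp, fit)
  list(table = tab, fit = fit)
}

#' Unsupervised, analyte-specific ion suppression compensation
#'
#' For each analyte, the ratio mu = MS intensity / sampling proportion is
#' regressed (median regression, log-log) on the sampling proportion using
#' regions with positive intensity and sampling proportion above `min_sp`.
#' Analytes with fewer than `min_points` usable points borrow the fit of
#' the analyte with the most points (fallback). Intensities are divided by
#' the predicted ratio, anchored at sampling proportion 1 by default so
#' per-analyte scales are preserved.
#'
#' @param tab Region table with `sampling_proportion` and analyte columns.
#' @param analytes Analyte columns (default: all analyte columns).
#' @param min_points Minimum usable points to fit an analyte's own line
#'   (default 10).
#' @param min_sp Minimum sampling proportion for fit points (default 0.1,
#'   mirroring the supervised procedure).
#' @param anchor Pin predictions to 1 at sampling proportion 1 (default
#'   TRUE).
#' @return List with `table` (analyte columns corrected) and `fits` (a
#'   `suppression_fits` list, one `suppression_fit` per analyte).
#' @export
compensate_unsupervised <- function(tab, analytes = NULL, min_points = 10,
                                    min_sp = 0.1, anchor = TRUE) {
  stopifnot("sampling_proportion" %in% names(tab))
  analytes <- analytes %||% analyte_columns(tab)
  sp <- tab$sampling_proportion
  info <- lapply(analytes, function(a) {
    intensity <- tab[[a]]
    sel <- intensity > 0 & sp > min_sp
    list(analyte = a, sel = sel, n = sum(sel))
  })
  ns <- vapply(info, function(z) as.numeric(z$n), numeric(1))
  if (max(ns) < min_points) {
    stop(
      "no analyte has at least ", min_points,
      " non-zero data points for the suppression fit", call. = FALSE
    )
  }
  donor_idx <- which.max(ns)
  fit_one <- function(i) {
    a <- info[[i]]$analyte
    sel <- info[[i]]$sel
    mu <- tab[[a]][sel] / sp[sel]
    coefs <- fit_quantile_line(log(sp[sel]), log(mu))
    new_suppression_fit(
      a, "unsupervised_mu", coefs["slope"], coefs["intercept"],
      n_points = info[[i]]$n, anchored = anchor,
      data = tibble::tibble(sampling_proportion = sp[sel], ratio = mu)
    )
  }
  donor_fit <- fit_one(donor_idx)
  fits <- lapply(seq_along(info), function(i) {
    if (info[[i]]$n >= min_points) {
      fit_one(i)
    } else {
      f <- donor_fit
      f$analyte <- info[[i]]$analyte
      f$n_points <- info[[i]]$n
      f$fallback <- TRUE
      f$data <- NULL
      f
    }
  })
  names(fits) <- analytes
  for (i in seq_along(analytes)) {
    tab[[analytes[i]]] <- apply_correction(tab[[analytes[i]]], sp, fits[[i]])
  }
  list(table = tab, fits = structure(fits, class = "suppression_fits"))
}

#' @export
print.suppression_fits <- function(x, ...) {
  cat(sprintf(
    "<suppression_fits> %d analytes (%d fallback)\n",
    length(x), sum(vapply(x, `[[`, logical(1), "fallback"))
  ))
  for (f in x) print(f)
  invisible(x)
}

#' Attach per-region sampling proportions to an intensity table
#'
#' @param tab Region intensity table.
#' @param overlaps An (unfiltered) `overlap_table`.
#' @return `tab` with a `sampling_proportion` column.
#' @export
add_sampling_proportion <- function(tab, overlaps) {
  dplyr::left_join(
    dplyr::select(tab, -dplyr::any_of("sampling_proportion")),
    overlaps$regions[c("region_id", "sampling_proportion")],
    by = "region_id"
  )
}

#' Export suppression fits as a tidy TSV
#'
#' @param fits A `suppression_fits` object (or single `suppression_fit`).
#' @param path Output path.
#' @export
write_suppression_fits <- function(fits, path) {
  readr::write_tsv(generics::tidy(fits), path)
  invisible(path)
}
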