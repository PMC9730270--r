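# Quantitation quality metrics: density-weighted Spearman correlation
# against a ground-truth channel, and the k-nearest-neighbour cell-type
# intermixing fraction in a 2-D embedding.

#' Density-based observation weights for correlation
#'
#' Ground-truth (fluorescence) values are very unevenly distributed:
#' for ablated regions most values sit in a dense extracellular mode near
#' zero. To stop that mode from dominating a correlation, each observation
#' is weighted negatively proportionally to the local density of the
#' ground-truth vector: a 1-D Gaussian kernel density estimate (Silverman
#' bandwidth) is evaluated at each observation and mapped to a weight by
#' either `1 - density/max(density) + 1e-6` (scheme `"one_minus"`, the
#' default) or `1/density` (scheme `"inverse"`). Weights are rescaled to
#' sum to the number of observations.
#'
#' @param values Finite numeric vector, length >= 3.
#' @param scheme `"one_minus"` or `"inverse"`.
#' @param bandwidth Kernel bandwidth; default Silverman's rule
#'   ([stats::bw.nrd0()]).
#' @return A `density_weights` tibble with columns `value`, `density`,
#'   `weight`; attributes `bandwidth` and `scheme`.
#' @export
density_weights <- function(values, scheme = c("one_minus", "inverse"),
                            bandwidth = NULL) {
  scheme <- match.arg(scheme)
  stopifnot(length(values) >= 3, all(is.finite(values)))
  n <- length(values)
  if (stats::sd(values) == 0) {
    warning("constant ground-truth vector; using uniform weights",
      call. = FALSE
    )
    out <- tibble::tibble(
      value = values, density = rep(1, n), weight = rep(1, n)
    )
    return(structure(out,
      bandwidth = NA_real_, scheme = scheme,
      class = c("density_weights", class(out))
    ))
  }
  bw <- bandwidth %||% stats::bw.nrd0(values)
  rho <- gaussian_kde_at(values, bw)
  w <- switch(scheme,
    one_minus = 1 - rho / max(rho) + 1e-6,
    inverse = 1 / rho
  )
  w <- w * n / sum(w)
  out <- tibble::tibble(value = values, density = rho, weight = w)
  structure(out,
    bandwidth = bw, scheme = scheme,
    class = c("density_weights", class(out))
  )
}

# Gaussian KDE evaluated at the sample points themselves; exact pairwise
# sum up to n = 2000, grid + linear interpolation beyond (the exact sum is
# quadratic in n).
gaussian_kde_at <- function(values, bw) {
  n <- length(values)
  if (n <= 2000L) {
    vapply(
      values,
      function(v) mean(stats::dnorm((v - values) / bw)) / bw,
      numeric(1)
    )
  } else {
    d <- stats::density(values, bw = bw, n = 2048)
    stats::approx(d$x, d$y, xout = values, rule = 2)$y
  }
}

#' Weighted Spearman correlation
#'
#' Both vectors are transformed to average ranks (ties get the mean rank),
#' then the weighted Pearson correlation of the ranks is returned. Pairs
#' with a missing value in either vector are dropped before ranking; with
#' fewer than 3 complete pairs the result is `NA`.
#'
#' @param x,y Numeric vectors of equal length.
#' @param w Positive weights (default: uniform, giving the classical
#'   Spearman coefficient).
#' @return Correlation in `[-1, 1]`, or `NA`.
#' @export
weighted_spearman <- function(x, y, w = NULL) {
  stopifnot(length(x) == length(y))
  w <- w %||% rep(1, length(x))
  stopifnot(length(w) == length(x))
  ok <- !is.na(x) & !is.na(y) & !is.na(w)
  if (sum(ok) < 3L) {
    return(NA_real_)
  }
  x <- rank(x[ok], ties.method = "average")
  y <- rank(y[ok], ties.method = "average")
  w <- w[ok]
  stopifnot(all(w > 0))
  mx <- sum(w * x) / sum(w)
  my <- sum(w * y) / sum(w)
  sxy <- sum(w * (x - mx) * (y - my))
  sxx <- sum(w * (x - mx)^2)
  syy <- sum(w * (y - my)^2)
  if (sxx == 0 || syy == 0) {
    return(NA_real_)
  }
  sxy / sqrt(sxx * syy)
}

#' Density-weighted Spearman correlation against a ground truth
#'
#' Convenience wrapper: weights from [density_weights()] on the
#' ground-truth vector, correlation by [weighted_spearman()]. Pairs with
#' `NA` in the estimate (e.g. cells without assigned signal) are dropped
#' by the correlation; the weights are computed on the complete
#' ground-truth pairs.
#'
#' @param truth Ground-truth vector (fluorescence or simulated signal).
#' @param estimate Estimated vector, same length.
#' @param scheme Weight scheme, see [density_weights()].
#' @return A single correlation.
#' @export
density_weighted_spearman <- function(truth, estimate,
                                      scheme = c("one_minus", "inverse")) {
  scheme <- match.arg(scheme)
  ok <- !is.na(truth) & !is.na(estimate)
  if (sum(ok) < 3L) {
    return(NA_real_)
  }
  w <- density_weights(truth[ok], scheme = scheme)$weight
  weighted_spearman(truth[ok], estimate[ok], w)
}

#' Cell-type intermixing in a 2-D embedding
#'
#' For each cell, its `k` nearest neighbours (Euclidean distance in the
#' embedding, self excluded, distance ties broken by index order) are
#' inspected and the fraction belonging to another cell type is recorded.
#' Well-separated cell types give fractions near 0; fully mixed types
#' approach the opposite-type frequency.
#'
#' @param embedding Numeric matrix or data frame with one row per cell and
#'   2 (or more) coordinate columns.
#' @param labels Cell-type label per cell.
#' @param k Number of neighbours (default 10); requires `n > k`.
#' @return An `intermixing` object: list with `per_cell` (tibble `cell`,
#'   `fraction`), `mean`, `sd`, `k`.
#' @export
intermixing_fraction <- function(embedding, labels, k = 10) {
  emb <- as.matrix(embedding)
  n <- nrow(emb)
  if (n <= k) {
    stop("need more cells than neighbours (n > k)", call. = FALSE)
  }
  stopifnot(length(labels) == n)
  d <- as.matrix(stats::dist(emb))
  frac <- vapply(seq_len(n), function(i) {
    di <- d[i, ]
    di[i] <- Inf
    nn <- order(di)[seq_len(k)] # order() breaks ties by index
    mean(labels[nn] != labels[i])
  }, numeric(1))
  structure(
    list(
      per_cell = tibble::tibble(cell = seq_len(n), fraction = frac),
      mean = mean(frac), sd = stats::sd(frac), k = k
    ),
    class = "intermixing"
  )
}

#' @export
print.intermixing <- function(x, ...) {
  cat(sprintf(
    "<intermixing> k = %d: mean fraction %.4f (sd %.4f) over %d cells\n",
    x$k, x$mean, x$sd, nrow(x$per_cell)
  ))
  invisible(x)
}

#' Simple 2-D embedding by principal components
#'
#' A deterministic stand-in for a nonlinear embedding: the first two
#' principal components of log1p-transformed profiles. The intermixing
#' metric consumes any 2-D embedding; this one keeps the pipeline free of
#' stochastic embedding algorithms.
#'
#' @param profiles A `cell_profiles` tibble (rows with `NA` are dropped).
#' @return List with `embedding` (n x 2 matrix) and `cell_id`.
#' @export
embed_pca <- function(profiles) {
  analytes <- setdiff(names(profiles), c("cell_id", "status"))
  vals <- as.matrix(tibble::as_tibble(profiles)[analytes])
  keep <- stats::complete.cases(vals)
  pc <- stats::prcomp(log1p(vals[keep, , drop = FALSE]),
    center = TRUE, scale. = FALSE
  )
  k <- min(2L, ncol(pc$x))
  emb <- pc$x[, seq_len(k), drop = FALSE]
  if (k == 1L) emb <- cbind(emb, 0)
  list(embedding = emb, cell_id = profiles$cell_id[keep])
}
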