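#' Build a regular ablation grid
#'
#' Models the regions sampled by the imaging-MS laser as a regular grid of
#' circles of shared radius. Centers are ordered row-major (all columns of
#' grid row 1, then grid row 2, ...), matching the acquisition order of the
#' MALDI stage and the spectrum order of an imzML file.
#'
#' @param origin Numeric length-2, `(row, col)` of the first grid center, in
#'   mask pixel units (1-based, pixel `(i, j)` has its center at `(i, j)`).
#' @param row_step,col_step Spacing between grid rows / columns, pixels (> 0).
#' @param n_rows,n_cols Grid dimensions (>= 1).
#' @param radius Radius of each circular ablated region, pixels (> 0). The
#'   default 15 corresponds to a 30-pixel ablation diameter.
#' @return An `ablation_grid`: a tibble with columns `region_id`, `row`,
#'   `col`, plus attributes `radius`, `n_rows`, `n_cols`.
#' @examples
#' g <- ablation_grid(c(15, 15), 30, 30, n_rows = 3, n_cols = 3)
#' g[5, ]
#' @export
ablation_grid <- function(origin, row_step, col_step, n_rows, n_cols,
                          radius = 15) {
  stopifnot(length(origin) == 2, is.finite(origin))
  if (row_step <= 0 || col_step <= 0) {
    stop("grid steps must be positive", call. = FALSE)
  }
  if (n_rows < 1 || n_cols < 1) {
    stop("grid dimensions must be >= 1", call. = FALSE)
  }
  if (radius <= 0) stop("ablation radius must be positive", call. = FALSE)
  ij <- expand.grid(j = seq_len(n_cols) - 1L, i = seq_len(n_rows) - 1L)
  out <- tibble::tibble(
    region_id = seq_len(n_rows * n_cols),
    row = origin[1] + ij$i * row_step,
    col = origin[2] + ij$j * col_step
  )
  structure(out,
    radius = radius, n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
    class = c("ablation_grid", class(out))
  )
}

#' @export
print.ablation_grid <- function(x, ...) {
  cat(sprintf(
    "<ablation_grid> %d x %d regions, radius %.6g px\n",
    attr(x, "n_rows"), attr(x, "n_cols"), attr(x, "radius")
  ))
  NextMethod()
}

grid_radius <- function(grid) attr(grid, "radius")

#' Pixels covered by one circular ablated region
#'
#' A pixel belongs to the region iff the Euclidean distance from its center
#' point to the region center is at most `radius` (boundary inclusive).
#' Pixels outside the image are clipped (they count as background and do not
#' enter any denominator).
#'
#' @return Integer matrix with columns `row`, `col` (possibly 0 rows).
#' @keywords internal
region_pixels <- function(center, radius, dim_mask) {
  r0 <- max(1L, ceiling(center[1] - radius))
  r1 <- min(dim_mask[1], floor(center[1] + radius))
  c0 <- max(1L, ceiling(center[2] - radius))
  c1 <- min(dim_mask[2], floor(center[2] + radius))
  if (r0 > r1 || c0 > c1) {
    return(cbind(row = integer(0), col = integer(0)))
  }
  rows <- r0:r1
  cols <- c0:c1
  dr2 <- (rows - center[1])^2
  dc2 <- (cols - center[2])^2
  inside <- outer(dr2, dc2, "+") <= radius^2 + 1e-12
  idx <- which(inside, arr.ind = TRUE)
  cbind(row = rows[idx[, 1]], col = cols[idx[, 2]])
}

#' Region-cell overlap geometry
#'
#' Rasterises every circular ablated region against an integer-label cell
#' mask and computes, per region, the sampling proportion (fraction of the
#' region's pixels overlapping any cell) and, per (region, cell) pair, the
#' sampling specificity (fraction of the region's cellular pixels belonging
#' to that cell). Their product is the specific sampling proportion, the
#' entry of the design matrix used by linear inverse modelling.
#'
#' Regions clipped by the image border only count their in-image pixels;
#' out-of-image area is treated as background. A region must cover at least
#' one in-image pixel.
#'
#' @param mask Integer matrix; 0 = background, positive labels = cells.
#' @param grid An [ablation_grid()].
#' @return An `overlap_table`: list with tibbles `regions` (`region_id`,
#'   `n_pixels`, `n_cell_pixels`, `sampling_proportion`) and `pairs`
#'   (`region_id`, `cell_id`, `sampling_proportion`, `specificity`,
#'   `specific_sampling_proportion`), plus `cell_ids` (every label present
#'   in the mask).
#' @export
compute_overlaps <- function(mask, grid) {
  stopifnot(is.matrix(mask))
  if (any(mask < 0)) stop("mask labels must be non-negative", call. = FALSE)
  radius <- grid_radius(grid)
  dm <- dim(mask)
  centers <- cbind(grid$row, grid$col)

  reg_list <- vector("list", nrow(centers))
  n_pix <- integer(nrow(centers))
  n_cell <- integer(nrow(centers))
  for (r in seq_len(nrow(centers))) {
    px <- region_pixels(centers[r, ], radius, dm)
    if (nrow(px) == 0L) {
      stop(sprintf(
        "region %d covers no image pixels (radius too small or grid off-image)",
        grid$region_id[r]
      ), call. = FALSE)
    }
    labs <- mask[px]
    n_pix[r] <- nrow(px)
    cellular <- labs > 0L
    n_cell[r] <- sum(cellular)
    if (n_cell[r] > 0L) {
      tab <- table(labs[cellular])
      reg_list[[r]] <- tibble::tibble(
        region_id = grid$region_id[r],
        cell_id = as.integer(names(tab)),
        n_overlap = as.integer(tab)
      )
    }
  }
  regions <- tibble::tibble(
    region_id = grid$region_id,
    n_pixels = n_pix,
    n_cell_pixels = n_cell,
    sampling_proportion = n_cell / n_pix
  )
  pairs <- dplyr::bind_rows(reg_list)
  if (nrow(pairs) == 0L) {
    pairs <- tibble::tibble(
      region_id = integer(0), cell_id = integer(0), n_overlap = integer(0)
    )
  }
  pairs <- pairs |>
    dplyr::left_join(regions, by = "region_id") |>
    dplyr::mutate(
      specificity = .data$n_overlap / .data$n_cell_pixels,
      specific_sampling_proportion =
        .data$sampling_proportion * .data$specificity
    ) |>
    dplyr::select(
      "region_id", "cell_id", "sampling_proportion", "specificity",
      "specific_sampling_proportion"
    )
  new_overlap_table(regions, pairs,
    cell_ids = sort(unique(as.integer(mask[mask > 0L])))
  )
}

new_overlap_table <- function(regions, pairs, cell_ids,
                              filter_settings = NULL) {
  structure(
    list(
      regions = regions, pairs = pairs, cell_ids = cell_ids,
      filter_settings = filter_settings
    ),
    class = "overlap_table"
  )
}

#' @export
print.overlap_table <- function(x, ...) {
  cat(sprintf(
    "<overlap_table> %d regions (%d cellular), %d cells, %d region-cell pairs\n",
    nrow(x$regions), sum(x$regions$sampling_proportion > 0),
    length(x$cell_ids), nrow(x$pairs)
  ))
  if (!is.null(x$filter_settings)) {
    cat(
      "  filtered:",
      paste(names(x$filter_settings), unlist(x$filter_settings),
        sep = "=", collapse = ", "
      ), "\n"
    )
  }
  invisible(x)
}

#' Specific sampling proportion matrix
#'
#' Assembles the sparse region x cell design matrix S whose entry `S[r, k]`
#' is the specific sampling proportion of region r for cell k.
#'
#' @param overlaps An `overlap_table` (typically after [filter_overlaps()]).
#' @return A dense numeric matrix with rownames = region ids and colnames =
#'   cell ids; rows are the regions present in `overlaps$pairs`.
#' @export
overlap_matrix <- function(overlaps) {
  p <- overlaps$pairs
  rid <- sort(unique(p$region_id))
  cid <- sort(unique(p$cell_id))
  S <- matrix(0, length(rid), length(cid),
    dimnames = list(as.character(rid), as.character(cid))
  )
  S[cbind(match(p$region_id, rid), match(p$cell_id, cid))] <-
    p$specific_sampling_proportion
  S
}

#' Summarise an image over regions or cells
#'
#' Computes a per-shape statistic of image pixel values, using the same
#' rasterisation rule as [compute_overlaps()] for grids (center-point test,
#' boundary inclusive) and the label mask itself for cells. Used e.g. for
#' the per-region sum fluorescence and the per-cell median fluorescence.
#'
#' @param image Numeric matrix, same dimensions as the mask / grid frame.
#' @param shapes An [ablation_grid()] or an integer label mask matrix.
#' @param statistic One of `"sum"`, `"mean"`, `"median"`.
#' @param mask_dim Image dimensions the grid was defined over (defaults to
#'   `dim(image)`); must equal `dim(image)`.
#' @return A tibble with `region_id` (or `cell_id`) and `value`.
#' @export
aggregate_image <- function(image, shapes, statistic = c("sum", "mean", "median"),
                            mask_dim = dim(image)) {
  statistic <- match.arg(statistic)
  stopifnot(is.matrix(image))
  if (!identical(as.integer(mask_dim), as.integer(dim(image)))) {
    stop("image dimensions do not match the mask/grid frame", call. = FALSE)
  }
  fun <- switch(statistic, sum = sum, mean = mean, median = stats::median)
  if (inherits(shapes, "ablation_grid")) {
    radius <- grid_radius(shapes)
    vals <- vapply(seq_len(nrow(shapes)), function(r) {
      px <- region_pixels(c(shapes$row[r], shapes$col[r]), radius, dim(image))
      if (nrow(px) == 0L) NA_real_ else fun(image[px])
    }, numeric(1))
    tibble::tibble(region_id = shapes$region_id, value = vals)
  } else if (is.matrix(shapes)) {
    if (!identical(dim(shapes), dim(image))) {
      stop("image and mask dimensions differ", call. = FALSE)
    }
    ids <- sort(unique(as.integer(shapes[shapes > 0L])))
    vals <- vapply(
      ids, function(k) fun(image[shapes == k]),
      numeric(1)
    )
    tibble::tibble(cell_id = ids, value = vals)
  } else {
    stop("`shapes` must be an ablation_grid or a label matrix", call. = FALSE)
  }
}
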