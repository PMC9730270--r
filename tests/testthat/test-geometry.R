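test_that("grid arithmetic places centers row-major at the right spots", {
  g <- ablation_grid(c(15, 15), 30, 30, n_rows = 3, n_cols = 3, radius = 15)
  expect_equal(nrow(g), 9L)
  # grid row 2, col 3 (row-major position 6)
  expect_equal(unlist(g[6, c("row", "col")]), c(row = 45, col = 75))
  big <- ablation_grid(c(1, 1), 25, 25, n_rows = 100, n_cols = 100)
  expect_equal(nrow(big), 10000L)
  expect_equal(attr(big, "radius"), 15)
  expect_error(ablation_grid(c(1, 1), 0, 10, 2, 2), "positive")
  expect_error(ablation_grid(c(1, 1), 10, 10, 2, 2, radius = -1), "positive")
})

test_that("full containment, background-only and edge-straddling regions", {
  mask <- matrix(0L, 60, 60)
  mask[, 1:30] <- 1L # one cell occupying the left half
  g <- ablation_grid(c(15, 15), 1, 15, n_rows = 1, n_cols = 4, radius = 7)
  # centers at cols 15 (inside), 30 (on the edge), 45, 60 (background)
  ov <- compute_overlaps(mask, g)
  expect_equal(ov$regions$sampling_proportion[1], 1)
  expect_equal(
    ov$pairs$specificity[ov$pairs$region_id == 1], 1
  )
  expect_equal(ov$regions$sampling_proportion[3], 0)
  expect_false(3 %in% ov$pairs$region_id)
  # straddling region: boundary column included on the cell side
  sp_edge <- ov$regions$sampling_proportion[2]
  orc <- oracle_overlaps(mask, cbind(15, 30), 7)[[1]]
  expect_equal(sp_edge, orc$counts[["1"]] / orc$n_pixels)
  expect_gt(sp_edge, 0.4)
  expect_lt(sp_edge, 0.65)
  expect_equal(ov$pairs$specificity[ov$pairs$region_id == 2], 1)
})

test_that("overlap table matches the exhaustive per-pixel oracle", {
  set.seed(42)
  mask <- matrix(0L, 64, 64)
  # three blobby cells: discs of different radii, possibly clipped
  centers <- list(c(12, 12), c(30, 40), c(55, 20))
  radii <- c(8, 11, 7)
  for (k in seq_along(centers)) {
    for (i in 1:64) {
      for (j in 1:64) {
        if ((i - centers[[k]][1])^2 + (j - centers[[k]][2])^2 <= radii[k]^2) {
          mask[i, j] <- k
        }
      }
    }
  }
  g <- ablation_grid(c(6, 6), 13, 13, n_rows = 5, n_cols = 5, radius = 7)
  ov <- compute_overlaps(mask, g)
  orc <- oracle_overlaps(mask, cbind(g$row, g$col), 7)
  for (r in seq_len(nrow(g))) {
    expect_equal(ov$regions$n_pixels[r], orc[[r]]$n_pixels)
    expect_equal(
      ov$regions$sampling_proportion[r],
      sum(orc[[r]]$counts) / orc[[r]]$n_pixels
    )
    prs <- ov$pairs[ov$pairs$region_id == r, ]
    expect_setequal(
      as.character(prs$cell_id), as.character(names(orc[[r]]$counts))
    )
    for (k in seq_len(nrow(prs))) {
      expect_equal(
        prs$specificity[k],
        orc[[r]]$counts[[as.character(prs$cell_id[k])]] /
          sum(orc[[r]]$counts)
      )
    }
  }
})

test_that("overlap invariants: conservation, ranges, S factorisation", {
  set.seed(7)
  mask <- matrix(sample(0:4, 48 * 48, replace = TRUE, prob = c(.7, rep(.075, 4))),
    48, 48
  )
  g <- ablation_grid(c(8, 8), 11, 11, n_rows = 4, n_cols = 4, radius = 6)
  ov <- compute_overlaps(mask, g)
  expect_true(all(ov$regions$sampling_proportion >= 0 &
    ov$regions$sampling_proportion <= 1))
  expect_true(all(ov$pairs$specificity > 0 & ov$pairs$specificity <= 1))
  by_region <- split(ov$pairs, ov$pairs$region_id)
  for (prs in by_region) {
    expect_equal(sum(prs$specificity), 1, tolerance = 1e-9)
    expect_equal(
      sum(prs$specific_sampling_proportion),
      prs$sampling_proportion[1],
      tolerance = 1e-9
    )
    expect_equal(
      prs$specific_sampling_proportion,
      prs$sampling_proportion * prs$specificity
    )
  }
})

test_that("enlarging a cell never decreases sampling proportions", {
  set.seed(11)
  mask <- matrix(0L, 40, 40)
  mask[10:20, 10:20] <- 1L
  g <- ablation_grid(c(10, 10), 12, 12, n_rows = 3, n_cols = 3, radius = 6)
  sp1 <- compute_overlaps(mask, g)$regions$sampling_proportion
  grown <- mask
  grown[10:26, 10:26] <- 1L
  sp2 <- compute_overlaps(grown, g)$regions$sampling_proportion
  expect_true(all(sp2 >= sp1))
})

test_that("overlaps are equivariant under joint integer translation", {
  set.seed(3)
  mask <- matrix(0L, 50, 50)
  mask[5:18, 6:20] <- 1L
  mask[25:36, 28:41] <- 2L
  g <- ablation_grid(c(8, 8), 14, 14, n_rows = 2, n_cols = 2, radius = 6)
  ov <- compute_overlaps(mask, g)
  shift <- c(4L, 6L)
  shifted <- matrix(0L, 50 + shift[1], 50 + shift[2])
  shifted[(1 + shift[1]):(50 + shift[1]), (1 + shift[2]):(50 + shift[2])] <- mask
  g2 <- ablation_grid(c(8 + shift[1], 8 + shift[2]), 14, 14,
    n_rows = 2, n_cols = 2, radius = 6
  )
  ov2 <- compute_overlaps(shifted, g2)
  expect_equal(ov$regions$sampling_proportion, ov2$regions$sampling_proportion)
  expect_equal(
    ov$pairs[c("cell_id", "sampling_proportion", "specificity")],
    ov2$pairs[c("cell_id", "sampling_proportion", "specificity")]
  )
})

test_that("border-clipped regions use only in-image pixels", {
  mask <- matrix(1L, 30, 30)
  g <- ablation_grid(c(1, 1), 10, 10, n_rows = 1, n_cols = 1, radius = 5)
  ov <- compute_overlaps(mask, g)
  orc <- oracle_overlaps(mask, cbind(1, 1), 5)[[1]]
  # roughly a quarter disc survives; denominator is in-image pixels only
  expect_equal(ov$regions$n_pixels, orc$n_pixels)
  expect_equal(ov$regions$sampling_proportion, 1)
  g_off <- ablation_grid(c(-20, -20), 5, 5, n_rows = 1, n_cols = 1, radius = 3)
  expect_error(compute_overlaps(mask, g_off), "no image pixels")
})

test_that("empty mask yields all-zero sampling proportions, not an error", {
  mask <- matrix(0L, 40, 40)
  g <- ablation_grid(c(10, 10), 10, 10, n_rows = 2, n_cols = 2, radius = 5)
  ov <- compute_overlaps(mask, g)
  expect_equal(ov$regions$sampling_proportion, rep(0, 4))
  expect_equal(nrow(ov$pairs), 0L)
})

test_that("aggregate_image matches hand values and the pixel oracle", {
  img <- matrix(0, 30, 30)
  mask <- matrix(0L, 30, 30)
  mask[5:9, 5] <- 1L
  img[5:9, 5] <- c(1, 2, 3, 4, 100)
  expect_equal(aggregate_image(img, mask, "median")$value, 3)
  expect_equal(aggregate_image(img, mask, "sum")$value, 110)
  g <- ablation_grid(c(15, 15), 5, 5, n_rows = 1, n_cols = 1, radius = 6)
  img5 <- matrix(5, 30, 30)
  p_oracle <- oracle_overlaps(mask, cbind(15, 15), 6)[[1]]$n_pixels
  expect_equal(aggregate_image(img5, g, "sum")$value, 5 * p_oracle)
  expect_equal(aggregate_image(img5, g, "mean")$value, 5)
  expect_error(aggregate_image(matrix(0, 10, 10), mask), "dimensions")
})

test_that("masks round-trip through 16-bit TIFF and PNG", {
  mask <- matrix(sample(0:500, 32 * 32, replace = TRUE), 32, 32)
  for (ext in c("tif", "png")) {
    f <- withr::local_tempfile(fileext = paste0(".", ext))
    write_mask(mask, f)
    expect_identical(read_mask(f), matrix(as.integer(mask), 32, 32))
  }
})

test_that("config files round-trip scalars, strings and arrays", {
  cfg <- list(
    origin = c(10, 10), step = 18.5, n_rows = 28, label = "grid-a",
    normalise = TRUE
  )
  f <- withr::local_tempfile(fileext = ".toml")
  write_config(cfg, f)
  back <- read_config(f)
  expect_equal(back$origin, c(10, 10))
  expect_equal(back$step, 18.5)
  expect_equal(back$label, "grid-a")
  expect_true(back$normalise)
})
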