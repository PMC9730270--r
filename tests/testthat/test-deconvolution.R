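test_that("filtering removes low-overlap regions and low-specificity pairs", {
  ov <- micro_overlap_table(
    region_id = c(1L, 2L, 3L, 4L, 5L),
    cell_id = c(1L, 1L, 2L, 2L, 1L),
    sp = c(0.1, 0.2, 0.4, 0.6, 1.0),
    spec = c(1, 1, 1, 1, 1)
  )
  f <- filter_overlaps(ov, sp_cutoff = 0.3)
  expect_equal(nrow(f$regions), 3L)
  expect_setequal(f$pairs$region_id, 3:5)
  # boundary behaviour around the 0.3 cutoff
  ov2 <- micro_overlap_table(1:2, c(1L, 1L), c(0.25, 0.35), c(1, 1))
  f2 <- filter_overlaps(ov2, sp_cutoff = 0.3)
  expect_equal(f2$pairs$region_id, 2L)
  expect_error(filter_overlaps(ov, sp_cutoff = 1.2), "\\[0, 1\\]")
})

test_that("specificity filtering keeps raw specificities and supports both scopes", {
  ov <- micro_overlap_table(
    region_id = c(1L, 1L, 2L),
    cell_id = c(1L, 2L, 2L),
    sp = c(0.8, 0.8, 0.5),
    spec = c(0.9, 0.1, 1)
  )
  all_kept <- filter_overlaps(ov, sp_cutoff = 0, spec_cutoff = 0)
  expect_equal(nrow(all_kept$pairs), 3L)
  pair_level <- filter_overlaps(ov, sp_cutoff = 0, spec_cutoff = 0.5)
  expect_equal(nrow(pair_level$pairs), 2L)
  # surviving pair keeps its raw specificity (no renormalisation)
  expect_equal(
    pair_level$pairs$specificity[pair_level$pairs$region_id == 1], 0.9
  )
  region_level <- filter_overlaps(ov,
    sp_cutoff = 0, spec_cutoff = 0.5,
    pair_level = FALSE
  )
  expect_equal(region_level$pairs$region_id, 2L)
})

test_that("drop-out filtering removes regions with zero analyte intensity", {
  ov <- micro_overlap_table(1:3, c(1L, 1L, 1L), c(0.5, 0.6, 0.7), c(1, 1, 1))
  tab <- tibble::tibble(region_id = 1:3, fluorescein = c(4, 0, 2))
  f <- filter_overlaps(ov,
    sp_cutoff = 0, intensities = tab,
    drop_zero_analyte = "fluorescein"
  )
  expect_setequal(f$pairs$region_id, c(1L, 3L))
  expect_error(
    filter_overlaps(ov, drop_zero_analyte = "fluorescein"),
    "intensities"
  )
})

test_that("weighted average reproduces hand-computed values and N/A rules", {
  # identity case: one fully-specific, fully-sampling region
  ov1 <- micro_overlap_table(1L, 1L, 1, 1)
  tab1 <- tibble::tibble(region_id = 1L, fluorescein = 7)
  expect_equal(deconvolve_wa(tab1, ov1)$fluorescein, 7)
  # hand-computed weighted average: (1*10 + 0.5*(4/0.5)) / 1.5
  ov2 <- micro_overlap_table(1:2, c(1L, 1L), c(1, 0.5), c(1, 0.5))
  tab2 <- tibble::tibble(region_id = 1:2, fluorescein = c(10, 4))
  expect_equal(deconvolve_wa(tab2, ov2)$fluorescein, 28 / 3)
  # a cell overlapped by no included region gets NA / not_associated
  ov3 <- micro_overlap_table(1L, 1L, 1, 1)
  ov3$cell_ids <- c(1L, 2L)
  wa <- deconvolve_wa(tab1, ov3)
  expect_equal(wa$status, c("assigned", "not_associated"))
  expect_true(is.na(wa$fluorescein[2]))
  # zero result carries status zero
  tab0 <- tibble::tibble(region_id = 1L, fluorescein = 0)
  expect_equal(deconvolve_wa(tab0, ov1)$status, "zero")
})

test_that("LIM solves the 3x2 noiseless system exactly", {
  ov <- micro_overlap_table(
    region_id = c(1L, 2L, 2L, 3L),
    cell_id = c(1L, 1L, 2L, 2L),
    sp = c(1, 0.5, 0.5, 0.8),
    spec = c(1, 0.6, 0.4, 1)
  )
  S <- overlap_matrix(ov)
  expect_equal(unname(S), rbind(c(1, 0), c(0.3, 0.2), c(0, 0.8)))
  truth <- c(5, 10)
  p <- as.numeric(S %*% truth)
  tab <- tibble::tibble(region_id = 1:3, fluorescein = p)
  lim <- deconvolve_lim(tab, ov)
  expect_equal(lim$fluorescein, truth, tolerance = 1e-8)
  # p = 0 gives c = 0 with status zero
  tab0 <- tibble::tibble(region_id = 1:3, fluorescein = 0)
  lim0 <- deconvolve_lim(tab0, ov)
  expect_equal(lim0$fluorescein, c(0, 0))
  expect_equal(lim0$status, c("zero", "zero"))
})

test_that("non-negativity constraint activates on negative targets", {
  fit <- nnls_fit(matrix(c(1, 1), 2, 1), c(-1, -1))
  expect_equal(fit$x, 0)
  ov <- micro_overlap_table(1:2, c(1L, 1L), c(1, 1), c(1, 1))
  tab <- tibble::tibble(region_id = 1:2, fluorescein = c(-1, -1))
  expect_equal(deconvolve_lim(tab, ov)$fluorescein, 0)
})

test_that("NNLS matches brute-force enumeration and an independent solver", {
  skip_if_not_installed("pracma")
  set.seed(123)
  for (rep in 1:50) {
    # overdetermined instances (regions >= cells), as in the deconvolution
    # setting, where the NNLS optimum is generically unique
    m <- sample(2:6, 1)
    n <- m + sample.int(7 - m, 1) - 1L
    A <- matrix(runif(n * m), n, m)
    A[runif(n * m) < 0.3] <- 0
    x_true <- ifelse(runif(m) < 0.5, 0, runif(m, 0, 10))
    b <- as.numeric(A %*% x_true + rnorm(n, 0, 0.3))
    fit <- nnls_fit(A, b)
    expect_true(all(fit$x >= 0))
    brute <- oracle_nnls(A, b)
    expect_equal(fit$x, brute, tolerance = 1e-8)
    ref <- pracma::lsqnonneg(A, b)$x
    expect_equal(fit$x, ref, tolerance = 1e-6)
  }
})

test_that("LIM solves each analyte independently against the same S", {
  ov <- micro_overlap_table(
    region_id = c(1L, 2L, 2L, 3L),
    cell_id = c(1L, 1L, 2L, 2L),
    sp = c(1, 0.5, 0.5, 0.8),
    spec = c(1, 0.6, 0.4, 1)
  )
  S <- overlap_matrix(ov)
  c1 <- c(5, 10)
  c2 <- c(2, 0.5)
  tab <- tibble::tibble(
    region_id = 1:3,
    a = as.numeric(S %*% c1),
    b = as.numeric(S %*% c2)
  )
  lim <- deconvolve_lim(tab, ov)
  expect_equal(lim$a, c1, tolerance = 1e-8)
  expect_equal(lim$b, c2, tolerance = 1e-8)
})

test_that("deconvolution is scale-equivariant and non-negative", {
  set.seed(21)
  scene <- simulate_scene(n_cells = 25, image_size = c(220, 220), seed = 21)
  meas <- simulate_measurement(
    scene, scene_grid(scene),
    measurement_model(noise_cv = 0.3, suppression_b = -0.5, seed = 22)
  )
  filt <- filter_overlaps(meas$overlaps, sp_cutoff = 0.3)
  tab <- meas$intensities
  tab5 <- tab
  tab5$fluorescein <- 5 * tab5$fluorescein
  for (fun in list(deconvolve_wa, deconvolve_lim)) {
    v1 <- fun(tab, filt)$fluorescein
    v5 <- fun(tab5, filt)$fluorescein
    expect_equal(v5, 5 * v1, tolerance = 1e-9)
    expect_true(all(v1 >= 0, na.rm = TRUE))
  }
})

test_that("WA on an isolated cell equals the mean of sp-normalised regions", {
  # two regions exclusive to one cell, specificity 1 each
  ov <- micro_overlap_table(1:2, c(1L, 1L), c(0.6, 0.9), c(1, 1))
  tab <- tibble::tibble(region_id = 1:2, fluorescein = c(3, 6))
  expect_equal(
    deconvolve_wa(tab, ov)$fluorescein,
    mean(c(3 / 0.6, 6 / 0.9))
  )
})

test_that("component detection flags underdetermined subnetworks", {
  # 2 cells sharing their single region -> underdetermined
  ov <- micro_overlap_table(
    region_id = c(1L, 1L),
    cell_id = c(1L, 2L),
    sp = c(0.9, 0.9),
    spec = c(0.5, 0.5)
  )
  comp <- find_components(ov)
  expect_equal(nrow(comp$summary), 1L)
  expect_true(all(comp$cells$underdetermined))
  # 1 cell covered by 2 regions -> determined
  ov2 <- micro_overlap_table(1:2, c(1L, 1L), c(0.9, 0.8), c(1, 1))
  expect_false(any(find_components(ov2)$cells$underdetermined))
  # low-sp overlaps do not create edges (threshold is strict > 0.3)
  ov3 <- micro_overlap_table(1L, 1L, 0.3, 1)
  comp3 <- find_components(ov3)
  expect_true(comp3$cells$underdetermined) # isolated cell, 0 regions
})

test_that("component ids match a flood-fill oracle on a disjoint network", {
  set.seed(31)
  scene <- simulate_scene(n_cells = 30, image_size = c(260, 260), seed = 31)
  meas <- simulate_measurement(scene, scene_grid(scene))
  comp <- find_components(meas$overlaps, edge_sp_threshold = 0.3)
  edges <- dplyr::filter(
    meas$overlaps$pairs, specificity > 0, sampling_proportion > 0.3
  )
  orc <- oracle_components(
    meas$overlaps$cell_ids, unique(edges$region_id), edges
  )
  # same partition: cells share a component iff the oracle agrees
  key_pkg <- comp$cells$component
  key_orc <- unname(orc[paste0("c", comp$cells$cell_id)])
  expect_equal(
    outer(key_pkg, key_pkg, "=="),
    outer(key_orc, key_orc, "==")
  )
  expect_equal(
    length(unique(key_pkg)), length(unique(key_orc))
  )
})

test_that("MIX splices WA and LIM by the underdetermined flag", {
  # component A (regions 1-2, cell 1) is determined;
  # component B (region 3, cells 2-3) is underdetermined
  ov <- micro_overlap_table(
    region_id = c(1L, 2L, 3L, 3L),
    cell_id = c(1L, 1L, 2L, 3L),
    sp = c(1, 0.8, 0.9, 0.9),
    spec = c(1, 1, 0.5, 0.5)
  )
  tab <- tibble::tibble(region_id = 1:3, fluorescein = c(4, 3.5, 6))
  wa <- deconvolve_wa(tab, ov)
  lim <- deconvolve_lim(tab, ov)
  mix <- deconvolve_mix(tab, ov)
  expect_equal(mix$fluorescein[1], lim$fluorescein[1])
  expect_equal(mix$fluorescein[2:3], wa$fluorescein[2:3])
  # fully determined network: MIX == LIM elementwise
  ov_det <- micro_overlap_table(1:2, c(1L, 1L), c(1, 0.8), c(1, 1))
  tab2 <- tibble::tibble(region_id = 1:2, fluorescein = c(4, 3))
  expect_equal(
    deconvolve_mix(tab2, ov_det)$fluorescein,
    deconvolve_lim(tab2, ov_det)$fluorescein
  )
  # fully underdetermined network: MIX == WA elementwise
  ov_und <- micro_overlap_table(
    c(1L, 1L), c(1L, 2L), c(0.9, 0.9), c(0.6, 0.4)
  )
  tab3 <- tibble::tibble(region_id = 1L, fluorescein = 5)
  expect_equal(
    deconvolve_mix(tab3, ov_und)$fluorescein,
    deconvolve_wa(tab3, ov_und)$fluorescein
  )
})

test_that("cell profile TSV export encodes N/A as literal NA", {
  ov <- micro_overlap_table(1L, 1L, 1, 1)
  ov$cell_ids <- c(1L, 2L)
  tab <- tibble::tibble(region_id = 1L, fluorescein = 7)
  prof <- deconvolve_wa(tab, ov)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_cell_profiles(prof, f)
  lines <- readLines(f)
  expect_match(lines[3], "\tNA$")
})
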