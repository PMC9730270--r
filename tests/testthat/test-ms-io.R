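make_toy_spectra <- function() {
  tibble::tibble(
    pixel_index = 1:3, x = c(1, 2, 3), y = c(1, 1, 1),
    mz = list(
      c(331.0612, 331.0640, 350.1),
      c(305.5, 331.06121),
      numeric(0)
    ),
    intensity = list(c(100, 50, 7), c(3, 40), numeric(0))
  )
}

test_that("toy imzML round-trips spectra at float64 precision", {
  sp <- make_toy_spectra()
  f <- withr::local_tempfile(fileext = ".imzML")
  write_pixel_spectra(sp, f)
  back <- read_pixel_spectra(f)
  expect_equal(nrow(back), 3L)
  expect_identical(back$pixel_index, 1:3)
  for (i in 1:3) {
    expect_identical(back$mz[[i]], sp$mz[[i]])
    expect_identical(back$intensity[[i]], sp$intensity[[i]])
  }
})

test_that("written imzML is readable by an external imzML parser", {
  has_pyimzml <- nzchar(Sys.which("python")) &&
    system2("python", c("-c", shQuote("import pyimzml")),
      stdout = FALSE, stderr = FALSE
    ) == 0
  skip_if_not(has_pyimzml, "python pyimzml not available")
  sp <- make_toy_spectra()[1:2, ]
  f <- withr::local_tempfile(fileext = ".imzML")
  write_pixel_spectra(sp, f)
  out <- system2("python",
    c("-c", shQuote(paste0(
      "from pyimzml.ImzMLParser import ImzMLParser;",
      "p = ImzMLParser('", f, "');",
      "mz, it = p.getspectrum(0);",
      "print(len(p.coordinates), repr(list(mz)), repr(list(it)))"
    ))),
    stdout = TRUE, stderr = FALSE
  )
  expect_match(out[1], "^2 ")
  expect_match(out[1], "331\\.0612")
  expect_match(out[1], "100\\.0")
})

test_that("missing ibd errors and profile-mode data is refused", {
  sp <- make_toy_spectra()
  f <- withr::local_tempfile(fileext = ".imzML")
  write_pixel_spectra(sp, f)
  ibd <- paste0(tools::file_path_sans_ext(f), ".ibd")
  xml <- readLines(f)
  profile_xml <- gsub("MS:1000127", "MS:1000128", xml)
  profile_xml <- gsub("centroid spectrum", "profile spectrum", profile_xml)
  f2 <- withr::local_tempfile(fileext = ".imzML")
  writeLines(profile_xml, f2)
  file.copy(ibd, paste0(tools::file_path_sans_ext(f2), ".ibd"))
  expect_warning(
    expect_error(read_pixel_spectra(f2), "profile-mode"),
    "profile-mode"
  )
  expect_silent(invisible(read_pixel_spectra(f2, force = TRUE)))
  file.remove(ibd)
  expect_error(read_pixel_spectra(f), "ibd")
})

test_that("peak integration respects the ppm window", {
  mz <- c(331.0612, 331.0640)
  it <- c(100, 50)
  # second centroid is ~8.46 ppm away from the target
  expect_equal(integrate_peak(mz, it, 331.0612, 4), 100)
  expect_equal(integrate_peak(mz, it, 331.0612, 10), 150)
  expect_equal(integrate_peak(mz, it, 331.0612, 10, statistic = "max"), 100)
  expect_equal(integrate_peak(c(400.2), c(5), 331.0612, 4), 0)
  expect_equal(integrate_peak(numeric(0), numeric(0), 331.0612, 4), 0)
})

test_that("peak integration is additive over disjoint windows and monotone", {
  set.seed(5)
  mz <- sort(331.0612 * (1 + runif(40, -30, 30) * 1e-6))
  it <- runif(40, 1, 10)
  target <- 331.0612
  for (tol in c(2, 5, 12, 25)) {
    lo <- integrate_peak(mz, it, target, tol)
    hi <- integrate_peak(mz, it, target, tol * 1.5)
    expect_gte(hi, lo)
  }
  # window [0, 30] = [0, 10] plus the 10-30 ppm shell (disjoint sets)
  full <- integrate_peak(mz, it, target, 30)
  inner <- integrate_peak(mz, it, target, 10)
  d_ppm <- abs(mz - target) / target * 1e6
  shell <- sum(it[d_ppm > 10 & d_ppm <= 30])
  expect_equal(inner + shell, full)
})

test_that("TIC normalisation scales rows and flags zero-TIC regions", {
  tab <- tibble::tibble(
    region_id = 1:3, tic = c(10, 0, 4),
    a = c(2, 5, 2), b = c(3, 1, 1), c = c(5, 2, 1)
  )
  out <- tic_normalize(tab)
  expect_equal(unlist(out[1, c("a", "b", "c")]),
    c(a = 0.2, b = 0.3, c = 0.5)
  )
  expect_equal(unlist(out[2, c("a", "b", "c")]), c(a = 0, b = 0, c = 0))
  expect_identical(out$tic_zero, c(FALSE, TRUE, FALSE))
  # within-row ratios preserved
  expect_equal(out$a[3] / out$b[3], tab$a[3] / tab$b[3])
  expect_error(
    tic_normalize(tibble::tibble(region_id = 1, tic = -1, a = 1)),
    "negative"
  )
})

test_that("zero-fraction curve is monotone and matches a brute-force recount", {
  tab <- tibble::tibble(region_id = 1:200, fluorescein = runif(200, 0, 50))
  set.seed(99)
  tab$fluorescein[sample(200, 30)] <- 0
  spectra <- simulate_spectra(
    tab, c(fluorescein = 331.0612),
    jitter_ppm_sd = 2, seed = 17
  )
  tols <- c(0.5, 1, 2, 3, 4, 6, 10)
  curve <- zero_fraction_curve(spectra, 331.0612, tols)
  expect_true(all(diff(curve$zero_fraction) <= 0))
  expect_equal(
    curve$zero_fraction,
    oracle_zero_fraction(spectra, 331.0612, tols)
  )
  # at huge tolerance only true drop-outs remain
  wide <- zero_fraction_curve(spectra, 331.0612, 1000)
  expect_equal(wide$zero_fraction, 30 / 200)
})

test_that("region table assembly integrates peaks and computes TIC", {
  sp <- make_toy_spectra()
  tab <- build_region_table(sp, c(fluorescein = 331.0612), tol_ppm = 4)
  expect_equal(tab$fluorescein, c(100, 40, 0))
  expect_equal(tab$tic, c(157, 43, 0))
  tab10 <- build_region_table(sp, c(fluorescein = 331.0612), tol_ppm = 10)
  expect_equal(tab10$fluorescein, c(150, 40, 0))
})

test_that("region intensity tables round-trip through long TSV", {
  tab <- tibble::tibble(
    region_id = 1:4, tic = c(10, 20, 30, 40),
    fluorescence = c(1.5, 0, 2.25, 3),
    fluorescein = c(5, 0, 7, 1), lipid = c(0.5, 1, 0, 2)
  )
  f <- withr::local_tempfile(fileext = ".tsv")
  write_region_table(tab, f)
  back <- read_region_table(f)
  expect_equal(
    as.data.frame(back[names(tab)]),
    as.data.frame(tab)
  )
})

test_that("overlap tables round-trip through TSV", {
  mask <- matrix(0L, 40, 40)
  mask[8:20, 8:20] <- 1L
  mask[25:35, 22:33] <- 2L
  g <- ablation_grid(c(10, 10), 12, 12, n_rows = 3, n_cols = 3, radius = 6)
  ov <- compute_overlaps(mask, g)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_overlap_table(ov, f)
  back <- read_overlap_table(f)
  expect_equal(
    back$regions$sampling_proportion,
    ov$regions$sampling_proportion
  )
  expect_equal(
    as.data.frame(back$pairs),
    as.data.frame(ov$pairs)
  )
})
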