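# Centroided imzML I/O and region x analyte table assembly.
#
# Only the subset of imzML needed for centroided spectra with external
# binary arrays is handled: processed-mode files, 32/64-bit float arrays,
# scan x/y positions. Spectrum order follows the file, which for a regular
# raster matches the row-major ordering of ablation_grid().

CV_MZ_ARRAY <- "MS:1000514"
CV_INT_ARRAY <- "MS:1000515"
CV_FLOAT64 <- "MS:1000523"
CV_FLOAT32 <- "MS:1000521"
CV_CENTROID <- "MS:1000127"
CV_PROFILE <- "MS:1000128"
CV_EXT_OFFSET <- "IMS:1000102"
CV_EXT_LENGTH <- "IMS:1000103"
CV_POS_X <- "IMS:1000050"
CV_POS_Y <- "IMS:1000051"

#' Read centroided imaging-MS spectra from an imzML file
#'
#' Reads the XML index and the companion `.ibd` binary file and returns one
#' centroid spectrum per MALDI pixel, in acquisition order.
#'
#' @param path Path to the `.imzML` file; the `.ibd` file must sit next to
#'   it (same stem).
#' @param force Read profile-mode data anyway (default `FALSE`: profile
#'   spectra trigger a warning and a refusal, since peak picking is out of
#'   scope).
#' @return A `pixel_spectra` tibble with columns `pixel_index`, `x`, `y`,
#'   and list-columns `mz` (strictly increasing doubles) and `intensity`.
#' @export
read_pixel_spectra <- function(path, force = FALSE) {
  ibd <- paste0(tools::file_path_sans_ext(path), ".ibd")
  if (!file.exists(ibd)) {
    stop("companion .ibd file not found: ", ibd, call. = FALSE)
  }
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  accessions <- function(node) {
    xml2::xml_attr(xml2::xml_find_all(node, ".//cvParam"), "accession")
  }
  file_acc <- accessions(xml2::xml_find_first(doc, ".//fileDescription"))
  group_nodes <- xml2::xml_find_all(doc, ".//referenceableParamGroup")
  param_groups <- stats::setNames(
    lapply(group_nodes, accessions),
    xml2::xml_attr(group_nodes, "id")
  )
  spectra <- xml2::xml_find_all(doc, ".//spectrum")
  if (length(spectra) == 0L) stop("no spectra in imzML file", call. = FALSE)
  is_profile <- CV_PROFILE %in% file_acc ||
    any(vapply(spectra, function(s) {
      CV_PROFILE %in% xml2::xml_attr(
        xml2::xml_find_all(s, "./cvParam"), "accession"
      )
    }, logical(1)))
  if (is_profile && !force) {
    warning("imzML file contains profile-mode spectra", call. = FALSE)
    stop("refusing profile-mode data; use force = TRUE to override",
      call. = FALSE
    )
  }
  con <- file(ibd, "rb")
  on.exit(close(con))
  read_array <- function(offset, length, bytes) {
    seek(con, where = offset, origin = "start")
    readBin(con,
      what = "double", n = length, size = bytes, endian = "little"
    )
  }
  rows <- lapply(seq_along(spectra), function(i) {
    s <- spectra[[i]]
    pos <- xml2::xml_find_all(s, ".//scan/cvParam")
    pacc <- xml2::xml_attr(pos, "accession")
    pval <- as.numeric(xml2::xml_attr(pos, "value"))
    x <- pval[match(CV_POS_X, pacc)]
    y <- pval[match(CV_POS_Y, pacc)]
    arrays <- xml2::xml_find_all(s, ".//binaryDataArray")
    mz <- NULL
    intensity <- NULL
    for (a in arrays) {
      cv <- xml2::xml_find_all(a, ".//cvParam")
      acc <- xml2::xml_attr(cv, "accession")
      val <- xml2::xml_attr(cv, "value")
      ref <- xml2::xml_attr(
        xml2::xml_find_first(a, "./referenceableParamGroupRef"), "ref"
      )
      if (!is.na(ref) && ref %in% names(param_groups)) {
        acc <- c(acc, param_groups[[ref]])
      }
      offset <- as.numeric(val[match(CV_EXT_OFFSET, acc)])
      len <- as.integer(val[match(CV_EXT_LENGTH, acc)])
      bytes <- if (CV_FLOAT32 %in% acc) 4L else 8L
      v <- read_array(offset, len, bytes)
      if (CV_MZ_ARRAY %in% acc) mz <- v
      if (CV_INT_ARRAY %in% acc) intensity <- v
    }
    if (is.null(mz) || is.null(intensity)) {
      stop("spectrum ", i, " lacks m/z or intensity array", call. = FALSE)
    }
    tibble::tibble(
      pixel_index = i, x = x, y = y,
      mz = list(mz), intensity = list(intensity)
    )
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("pixel_spectra", class(out))
  out
}

#' Write centroided spectra to a minimal imzML/ibd pair
#'
#' Writes processed-mode centroided imzML with 64-bit float external binary
#' arrays; intended for small fixtures and diagnostics, not for archival
#' use.
#'
#' @param spectra A `pixel_spectra` tibble (see [read_pixel_spectra()]).
#' @param path Output `.imzML` path; the `.ibd` is written next to it.
#' @return `path`, invisibly.
#' @export
write_pixel_spectra <- function(spectra, path) {
  ibd <- paste0(tools::file_path_sans_ext(path), ".ibd")
  con <- file(ibd, "wb")
  uuid <- as.raw(seq_len(16))
  writeBin(uuid, con)
  offsets <- vector("list", nrow(spectra))
  pos <- 16
  for (i in seq_len(nrow(spectra))) {
    mz <- as.double(spectra$mz[[i]])
    it <- as.double(spectra$intensity[[i]])
    writeBin(mz, con, size = 8L, endian = "little")
    writeBin(it, con, size = 8L, endian = "little")
    offsets[[i]] <- list(
      mz_off = pos, mz_n = length(mz),
      int_off = pos + 8 * length(mz), int_n = length(it)
    )
    pos <- pos + 8 * (length(mz) + length(it))
  }
  close(con)

  array_xml <- function(off, n, group) {
    sprintf(paste0(
      '<binaryDataArray encodedLength="0">',
      '<referenceableParamGroupRef ref="%s"/>',
      '<cvParam cvRef="IMS" accession="IMS:1000102" name="external offset" value="%.0f"/>',
      '<cvParam cvRef="IMS" accession="IMS:1000103" name="external array length" value="%d"/>',
      '<cvParam cvRef="IMS" accession="IMS:1000104" name="external encoded length" value="%.0f"/>',
      "<binary/></binaryDataArray>"
    ), group, off, n, 8 * n)
  }
  spec_xml <- vapply(seq_len(nrow(spectra)), function(i) {
    o <- offsets[[i]]
    x <- if (is.na(spectra$x[i])) i else spectra$x[i]
    y <- if (is.na(spectra$y[i])) 1 else spectra$y[i]
    sprintf(paste0(
      '<spectrum index="%d" id="spectrum=%d" defaultArrayLength="%d">',
      '<cvParam cvRef="MS" accession="MS:1000127" name="centroid spectrum"/>',
      "<scanList count=\"1\"><scan>",
      '<cvParam cvRef="IMS" accession="IMS:1000050" name="position x" value="%g"/>',
      '<cvParam cvRef="IMS" accession="IMS:1000051" name="position y" value="%g"/>',
      "</scan></scanList>",
      '<binaryDataArrayList count="2">%s%s</binaryDataArrayList>',
      "</spectrum>"
    ), i - 1L, i, o$mz_n, x, y,
    array_xml(o$mz_off, o$mz_n, "mzArray"),
    array_xml(o$int_off, o$int_n, "intensityArray")
    )
  }, character(1))
  xml <- paste0(
    '<?xml version="1.0" encoding="ISO-8859-1"?>',
    '<mzML xmlns="http://psi.hupo.org/ms/mzml" version="1.1">',
    "<fileDescription><fileContent>",
    '<cvParam cvRef="MS" accession="MS:1000127" name="centroid spectrum"/>',
    '<cvParam cvRef="IMS" accession="IMS:1000031" name="processed"/>',
    "</fileContent></fileDescription>",
    '<referenceableParamGroupList count="2">',
    '<referenceableParamGroup id="mzArray">',
    '<cvParam cvRef="MS" accession="MS:1000514" name="m/z array"/>',
    '<cvParam cvRef="MS" accession="MS:1000523" name="64-bit float"/>',
    '<cvParam cvRef="MS" accession="MS:1000576" name="no compression"/>',
    "</referenceableParamGroup>",
    '<referenceableParamGroup id="intensityArray">',
    '<cvParam cvRef="MS" accession="MS:1000515" name="intensity array"/>',
    '<cvParam cvRef="MS" accession="MS:1000523" name="64-bit float"/>',
    '<cvParam cvRef="MS" accession="MS:1000576" name="no compression"/>',
    "</referenceableParamGroup>",
    "</referenceableParamGroupList>",
    '<softwareList count="1"><software id="pixcell" version="0.1"/></softwareList>',
    sprintf(paste0(
      '<scanSettingsList count="1"><scanSettings id="scansettings1">',
      '<cvParam cvRef="IMS" accession="IMS:1000042" name="max count of pixels x" value="%d"/>',
      '<cvParam cvRef="IMS" accession="IMS:1000043" name="max count of pixels y" value="%d"/>',
      "</scanSettings></scanSettingsList>"
    ),
    max(c(1, spectra$x), na.rm = TRUE), max(c(1, spectra$y), na.rm = TRUE)
    ),
    '<instrumentConfigurationList count="1">',
    '<instrumentConfiguration id="instrument1"/>',
    "</instrumentConfigurationList>",
    '<dataProcessingList count="1"><dataProcessing id="export">',
    '<processingMethod order="1" softwareRef="pixcell"/>',
    "</dataProcessing></dataProcessingList>",
    sprintf(
      '<run id="run1"><spectrumList count="%d">%s</spectrumList></run>',
      nrow(spectra), paste(spec_xml, collapse = "")
    ),
    "</mzML>"
  )
  writeLines(xml, path)
  invisible(path)
}

#' Integrate a centroid peak within a ppm tolerance window
#'
#' Sums the intensities of all centroids whose m/z lies within
#' `tol_ppm` parts-per-million of `target_mz`. Returns 0 when no centroid
#' falls in the window (a drop-out). With `statistic = "max"` the largest
#' centroid in the window is taken instead of the sum.
#'
#' @param mz,intensity Centroid m/z values (sorted) and intensities.
#' @param target_mz Target m/z (> 0).
#' @param tol_ppm Tolerance in ppm (>= 0).
#' @param statistic `"sum"` (default) or `"max"`.
#' @return A single intensity.
#' @export
integrate_peak <- function(mz, intensity, target_mz, tol_ppm,
                           statistic = c("sum", "max")) {
  statistic <- match.arg(statistic)
  stopifnot(target_mz > 0, tol_ppm >= 0)
  if (length(mz) == 0L) {
    return(0)
  }
  sel <- abs(mz - target_mz) / target_mz * 1e6 <= tol_ppm
  if (!any(sel)) {
    return(0)
  }
  if (statistic == "sum") sum(intensity[sel]) else max(intensity[sel])
}

#' Assemble a region x analyte intensity table from pixel spectra
#'
#' Integrates each target analyte in every spectrum and computes the
#' per-region total ion current (TIC) over the full acquired m/z range.
#' Spectrum order is taken as region order (row-major acquisition).
#'
#' @param spectra A `pixel_spectra` tibble.
#' @param analytes Named numeric vector of target m/z values; names become
#'   column names.
#' @param tol_ppm Integration tolerance in ppm (default 3, the usual
#'   annotation-engine default; 4 was found optimal for fluorescein).
#' @param statistic Passed to [integrate_peak()].
#' @return A tibble with `region_id`, `tic` and one column per analyte.
#' @export
build_region_table <- function(spectra, analytes, tol_ppm = 3,
                               statistic = "sum") {
  stopifnot(!is.null(names(analytes)), all(nzchar(names(analytes))))
  out <- tibble::tibble(
    region_id = spectra$pixel_index,
    tic = vapply(spectra$intensity, sum, numeric(1))
  )
  for (a in names(analytes)) {
    out[[a]] <- purrr::map2_dbl(
      spectra$mz, spectra$intensity,
      ~ integrate_peak(.x, .y, analytes[[a]], tol_ppm, statistic)
    )
  }
  attr(out, "tol_ppm") <- tol_ppm
  out
}

#' TIC-normalise a region intensity table
#'
#' Divides each region's analyte intensities by its total ion current.
#' Regions with zero TIC become all-zero and are flagged in the logical
#' column `tic_zero`.
#'
#' @param tab Tibble with a `tic` column and analyte columns.
#' @param analytes Character vector of analyte column names; defaults to
#'   every numeric column other than `region_id`, `tic`, `fluorescence`.
#' @return The table with analyte columns normalised, a `tic_zero` column,
#'   and attribute `tic_normalised = TRUE`.
#' @export
tic_normalize <- function(tab, analytes = NULL) {
  if (any(tab$tic < 0)) stop("negative TIC", call. = FALSE)
  analytes <- analytes %||% analyte_columns(tab)
  zero <- tab$tic == 0
  scale <- ifelse(zero, 0, 1 / tab$tic)
  for (a in analytes) tab[[a]] <- tab[[a]] * scale
  tab$tic_zero <- zero
  attr(tab, "tic_normalised") <- TRUE
  tab
}

analyte_columns <- function(tab) {
  setdiff(
    names(tab)[vapply(tab, is.numeric, logical(1))],
    c("region_id", "tic", "fluorescence", "sampling_proportion")
  )
}

#' Fraction of drop-out regions as a function of m/z tolerance
#'
#' For each tolerance, the fraction of spectra whose integrated intensity
#' at `target_mz` is exactly zero. Widening the window can only gain
#' centroids, so the curve is non-increasing.
#'
#' @param spectra A `pixel_spectra` tibble.
#' @param target_mz Target m/z.
#' @param tolerances Ascending numeric vector of ppm tolerances.
#' @return A tibble with `tol_ppm` and `zero_fraction`.
#' @export
zero_fraction_curve <- function(spectra, target_mz, tolerances) {
  stopifnot(!is.unsorted(tolerances))
  frac <- vapply(tolerances, function(tol) {
    z <- purrr::map2_dbl(
      spectra$mz, spectra$intensity,
      ~ integrate_peak(.x, .y, target_mz, tol)
    )
    mean(z == 0)
  }, numeric(1))
  tibble::tibble(tol_ppm = tolerances, zero_fraction = frac)
}

#' Read / write a region intensity table as long TSV
#'
#' The plain-text exchange format has columns `region_id`, `analyte`,
#' `intensity` and optionally per-region `tic` and `fluorescence`; it is
#' pivoted to the wide form used throughout the package (one column per
#' analyte).
#'
#' @param path TSV path.
#' @param tab Wide region intensity table.
#' @return `read_region_table()` returns the wide tibble.
#' @export
read_region_table <- function(path) {
  long <- readr::read_tsv(path, show_col_types = FALSE)
  stopifnot(all(c("region_id", "analyte", "intensity") %in% names(long)))
  extra <- intersect(c("tic", "fluorescence"), names(long))
  wide <- long |>
    tidyr::pivot_wider(
      id_cols = dplyr::all_of(c("region_id", extra)),
      names_from = "analyte", values_from = "intensity"
    ) |>
    dplyr::arrange(.data$region_id)
  wide
}

#' @rdname read_region_table
#' @export
write_region_table <- function(tab, path) {
  extra <- intersect(c("tic", "fluorescence"), names(tab))
  long <- tab |>
    dplyr::select(-dplyr::any_of("tic_zero")) |>
    tidyr::pivot_longer(
      cols = -dplyr::all_of(c("region_id", extra)),
      names_to = "analyte", values_to = "intensity"
    )
  readr::write_tsv(long, path)
  invisible(path)
}

#' Export / import an overlap table as TSV
#'
#' @param overlaps An `overlap_table`.
#' @param path TSV path.
#' @return `read_overlap_table()` rebuilds the `overlap_table`; regions
#'   without cellular overlap are preserved through a `cell_id` of `NA`.
#' @export
write_overlap_table <- function(overlaps, path) {
  full <- overlaps$regions |>
    dplyr::select("region_id", "sampling_proportion") |>
    dplyr::left_join(
      overlaps$pairs |>
        dplyr::select(
          "region_id", "cell_id", "specificity",
          "specific_sampling_proportion"
        ),
      by = "region_id"
    ) |>
    dplyr::select(
      "region_id", "cell_id", "sampling_proportion", "specificity",
      "specific_sampling_proportion"
    )
  readr::write_tsv(full, path)
  invisible(path)
}

#' @rdname write_overlap_table
#' @export
read_overlap_table <- function(path) {
  full <- readr::read_tsv(path, show_col_types = FALSE)
  regions <- full |>
    dplyr::distinct(.data$region_id, .data$sampling_proportion)
  pairs <- full |>
    dplyr::filter(!is.na(.data$cell_id)) |>
    dplyr::select(
      "region_id", "cell_id", "sampling_proportion", "specificity",
      "specific_sampling_proportion"
    )
  new_overlap_table(regions, pairs,
    cell_ids = sort(unique(pairs$cell_id))
  )
}
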