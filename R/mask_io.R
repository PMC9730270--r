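#' Read and write integer-label segmentation masks
#'
#' Masks are integer-label images (0 = background, positive labels =
#' cells). TIFF masks are written and read as single-channel 16-bit
#' (`value / 65535`), so labels up to 65535 round-trip exactly. PNG masks
#' are read either as true 16-bit grayscale (as produced by segmentation
#' tools) or as the two-channel byte encoding this package writes (red =
#' high byte, green = low byte; the png writer available here is limited
#' to 8 bits per channel).
#'
#' @param mask Integer matrix of labels in `[0, 65535]`.
#' @param path File path ending in `.tif`, `.tiff` or `.png`.
#' @return `read_mask()` returns an integer matrix; `write_mask()` returns
#'   `path` invisibly.
#' @export
write_mask <- function(mask, path) {
  stopifnot(is.matrix(mask), all(mask >= 0), all(mask <= 65535))
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(mask / 65535, path, bits.per.sample = 16L)
  } else if (ext == "png") {
    arr <- array(0, c(nrow(mask), ncol(mask), 3L))
    arr[, , 1L] <- (mask %/% 256L) / 255
    arr[, , 2L] <- (mask %% 256L) / 255
    png::writePNG(arr, path)
  } else {
    stop("unsupported mask format: ", ext, call. = FALSE)
  }
  invisible(path)
}

#' @rdname write_mask
#' @export
read_mask <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    img <- tiff::readTIFF(path)
    if (length(dim(img)) == 3L) img <- img[, , 1L]
    m <- round(img * 65535)
  } else if (ext == "png") {
    img <- png::readPNG(path)
    if (length(dim(img)) == 3L) {
      m <- round(img[, , 1L] * 255) * 256 + round(img[, , 2L] * 255)
    } else {
      m <- round(img * 65535)
    }
  } else {
    stop("unsupported mask format: ", ext, call. = FALSE)
  }
  storage.mode(m) <- "integer"
  m
}

#' Read and write simple key = value configuration files
#'
#' A minimal TOML-like dialect: one `key = value` per line, `#` comments,
#' bare numbers, `true`/`false`, quoted strings, and flat `[a, b, c]`
#' arrays. Sufficient for grid parameters and pipeline settings; nested
#' tables are not supported.
#'
#' @param path File path.
#' @param config Named list of scalars / flat vectors.
#' @return `read_config()` returns a named list.
#' @export
read_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^([A-Za-z0-9_.-]+)\\s*=\\s*(.*)$", ln))[[1]]
    if (length(m) != 3L) stop("cannot parse config line: ", ln, call. = FALSE)
    out[[m[2]]] <- parse_config_value(trimws(m[3]))
  }
  out
}

parse_config_value <- function(v) {
  if (grepl("^\\[.*\\]$", v)) {
    parts <- strsplit(gsub("^\\[|\\]$", "", v), ",")[[1]]
    return(unlist(lapply(trimws(parts), parse_config_value), use.names = FALSE))
  }
  if (grepl('^".*"$', v)) {
    return(gsub('^"|"$', "", v))
  }
  if (v %in% c("true", "false")) {
    return(v == "true")
  }
  num <- suppressWarnings(as.numeric(v))
  if (!is.na(num)) {
    return(num)
  }
  v
}

#' @rdname read_config
#' @export
write_config <- function(config, path) {
  fmt <- function(x) {
    if (is.character(x)) {
      paste0('"', x, '"')
    } else if (is.logical(x)) {
      ifelse(x, "true", "false")
    } else {
      format(x, digits = 15)
    }
  }
  lines <- vapply(names(config), function(k) {
    v <- config[[k]]
    body <- if (length(v) > 1L) {
      paste0("[", paste(fmt(v), collapse = ", "), "]")
    } else {
      fmt(v)
    }
    paste(k, "=", body)
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
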