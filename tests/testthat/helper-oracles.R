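# Independent brute-force oracles. These deliberately re-derive results by
# exhaustive enumeration / double loops, sharing no code with the package
# internals they check.

# exhaustive per-pixel overlap computation: loops over every image pixel
# for every region
oracle_overlaps <- function(mask, centers, radius) {
  lapply(seq_len(nrow(centers)), function(r) {
    cr <- centers[r, 1]
    cc <- centers[r, 2]
    n_pix <- 0L
    counts <- integer(0)
    for (i in seq_len(nrow(mask))) {
      for (j in seq_len(ncol(mask))) {
        if ((i - cr)^2 + (j - cc)^2 <= radius^2 + 1e-12) {
          n_pix <- n_pix + 1L
          lab <- mask[i, j]
          if (lab > 0L) {
            key <- as.character(lab)
            counts[key] <- if (key %in% names(counts)) counts[key] + 1L else 1L
          }
        }
      }
    }
    list(n_pixels = n_pix, counts = counts)
  })
}

# brute-force NNLS: enumerate every support set, solve unconstrained LS on
# it, keep feasible candidates, return the best
oracle_nnls <- function(A, b) {
  m <- ncol(A)
  best <- list(x = numeric(m), rss = sum(b^2))
  for (mask_bits in seq_len(2^m - 1)) {
    sel <- as.logical(bitwAnd(mask_bits, 2^(seq_len(m) - 1)))
    As <- A[, sel, drop = FALSE]
    coef <- tryCatch(qr.coef(qr(As), b), error = function(e) NULL)
    if (is.null(coef) || any(is.na(coef))) next
    if (any(coef < -1e-9)) next
    x <- numeric(m)
    x[sel] <- pmax(coef, 0)
    rss <- sum((b - A %*% x)^2)
    if (rss < best$rss - 1e-12) best <- list(x = x, rss = rss)
  }
  best$x
}

# exhaustive least-absolute-deviations line: the optimum passes through
# two data points, so enumerate all point pairs
oracle_lad_line <- function(x, y) {
  best <- NULL
  for (i in seq_along(x)) {
    for (j in seq_along(x)) {
      if (j <= i || x[i] == x[j]) next
      a <- (y[j] - y[i]) / (x[j] - x[i])
      b <- y[i] - a * x[i]
      loss <- sum(abs(y - a * x - b))
      if (is.null(best) || loss < best$loss) {
        best <- list(slope = a, intercept = b, loss = loss)
      }
    }
  }
  best
}

# Gaussian KDE evaluated at sample points by an explicit double loop
oracle_kde <- function(values, bw) {
  n <- length(values)
  out <- numeric(n)
  for (i in seq_len(n)) {
    s <- 0
    for (j in seq_len(n)) {
      s <- s + exp(-((values[i] - values[j]) / bw)^2 / 2) / sqrt(2 * pi)
    }
    out[i] <- s / (n * bw)
  }
  out
}

# brute-force k-nearest-neighbour intermixing with explicit (distance,
# index) ordering
oracle_intermixing <- function(emb, labels, k) {
  n <- nrow(emb)
  vapply(seq_len(n), function(i) {
    d <- sqrt(rowSums((emb - matrix(emb[i, ], n, ncol(emb), byrow = TRUE))^2))
    ord <- order(d, seq_len(n))
    ord <- ord[ord != i]
    mean(labels[ord[seq_len(k)]] != labels[i])
  }, numeric(1))
}

# flood-fill connected components over the region-cell bipartite edge list
oracle_components <- function(cells, regions, edges) {
  nodes <- c(paste0("c", cells), paste0("r", regions))
  comp <- stats::setNames(seq_along(nodes), nodes)
  repeat {
    changed <- FALSE
    for (e in seq_len(nrow(edges))) {
      a <- paste0("r", edges$region_id[e])
      b <- paste0("c", edges$cell_id[e])
      m <- min(comp[a], comp[b])
      if (comp[a] != m || comp[b] != m) {
        comp[a] <- m
        comp[b] <- m
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  comp
}

# direct recount of zero fractions at each tolerance
oracle_zero_fraction <- function(spectra, target_mz, tolerances) {
  vapply(tolerances, function(tol) {
    zeros <- 0L
    for (i in seq_len(nrow(spectra))) {
      mz <- spectra$mz[[i]]
      it <- spectra$intensity[[i]]
      s <- 0
      for (j in seq_along(mz)) {
        if (abs(mz[j] - target_mz) / target_mz * 1e6 <= tol) s <- s + it[j]
      }
      if (s == 0) zeros <- zeros + 1L
    }
    zeros / nrow(spectra)
  }, numeric(1))
}

# micro overlap table constructed directly from given geometry numbers
micro_overlap_table <- function(region_id, cell_id, sp, spec) {
  regions <- tibble::tibble(
    region_id = unique(region_id),
    n_pixels = 100L,
    n_cell_pixels = as.integer(round(100 * sp[match(
      unique(region_id), region_id
    )])),
    sampling_proportion = sp[match(unique(region_id), region_id)]
  )
  pairs <- tibble::tibble(
    region_id = region_id, cell_id = cell_id,
    sampling_proportion = sp, specificity = spec,
    specific_sampling_proportion = sp * spec
  )
  pixcell:::new_overlap_table(regions, pairs,
    cell_ids = sort(unique(cell_id))
  )
}
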