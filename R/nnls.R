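#' Non-negative least squares (Lawson-Hanson active set)
#'
#' Solves `min ||A x - b||_2` subject to `x >= 0`. This is the solver
#' behind linear-inverse-modelling deconvolution; components are small
#' (connected subnetworks of the region-cell graph), so a dense active-set
#' method is appropriate.
#'
#' @param A Numeric matrix (n x m).
#' @param b Numeric vector (length n).
#' @param maxit Outer iteration cap (default `10 * m + 50`).
#' @return List with `x` (solution, length m), `residual_norm`,
#'   `rank_deficient` (TRUE when the passive-set design dropped rank at any
#'   point; the solution returned is then one feasible minimiser).
#' @export
nnls_fit <- function(A, b, maxit = 10 * ncol(A) + 50) {
  A <- as.matrix(A)
  b <- as.numeric(b)
  stopifnot(nrow(A) == length(b))
  m <- ncol(A)
  x <- numeric(m)
  passive <- rep(FALSE, m)
  w <- as.numeric(crossprod(A, b))
  scale <- max(abs(w), 1)
  tol <- 1e-12 * scale
  rank_deficient <- FALSE
  outer <- 0L
  while (any(!passive) && any(w[!passive] > tol)) {
    outer <- outer + 1L
    if (outer > maxit) {
      stop("NNLS failed to converge within ", maxit, " iterations",
        call. = FALSE
      )
    }
    cand <- which(!passive)
    passive[cand[which.max(w[cand])]] <- TRUE
    repeat {
      Ap <- A[, passive, drop = FALSE]
      qr_ap <- qr(Ap)
      if (qr_ap$rank < ncol(Ap)) rank_deficient <- TRUE
      s <- qr.coef(qr_ap, b)
      s[is.na(s)] <- 0
      if (all(s > 0)) {
        x[] <- 0
        x[passive] <- s
        break
      }
      xp <- x[passive]
      neg <- which(s <= 0)
      alpha <- min(xp[neg] / (xp[neg] - s[neg]))
      xp <- xp + alpha * (s - xp)
      # indices driven to (numerical) zero leave the passive set
      drop_zero <- xp <= 1e-12 * max(xp, 1)
      x[] <- 0
      x[passive] <- ifelse(drop_zero, 0, xp)
      passive[which(passive)[drop_zero]] <- FALSE
      if (!any(passive)) break
    }
    w <- as.numeric(crossprod(A, b - A %*% x))
  }
  list(
    x = x,
    residual_norm = sqrt(sum((b - A %*% x)^2)),
    rank_deficient = rank_deficient
  )
}
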