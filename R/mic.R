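## Maximal information coefficient via grid search over equal-frequency
## partitions: MIC = max over grids (kx x ky, kx*ky <= n^alpha, each axis
## capped at c bins) of I(binned x; binned y) / log2(min(kx, ky)).

# Equal-frequency binning into k bins (ties broken by first-rank).
.ef_bins <- function(x, k) {
  n <- length(x)
  ceiling(rank(x, ties.method = "first") * k / n)
}

#' Maximal information coefficient of two numeric vectors
#'
#' Dependence measure in \[0, 1\]: 0 for independent pairs, 1 for
#' noiseless functional relationships. Computed by maximizing the
#' normalized mutual information of equal-frequency grid partitions under
#' the standard resolution bound `kx * ky <= n^alpha`.
#'
#' @param x,y numeric vectors of equal length (>= 8).
#' @param alpha grid resolution exponent (default 0.6).
#' @param c_cap maximum bins per axis (default 15).
#' @return list with `mic` and `grid` (the maximizing kx, ky).
#' @export
mic <- function(x, y, alpha = 0.6, c_cap = 15) {
  stopifnot(length(x) == length(y))
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 8) stop("need at least 8 paired observations")
  if (stats::sd(x) < 1e-12 || stats::sd(y) < 1e-12)
    stop("MIC undefined for constant input")
  B <- max(4, n^alpha)
  best <- 0; best_grid <- c(2, 2)
  kx_max <- min(c_cap, floor(B / 2))
  for (kx in 2:kx_max) {
    bx <- .ef_bins(x, kx)
    ky_max <- min(c_cap, floor(B / kx))
    if (ky_max < 2) break
    for (ky in 2:ky_max) {
      by <- .ef_bins(y, ky)
      tab <- tabulate(bx + (by - 1L) * kx, kx * ky) / n
      px <- tabulate(bx, kx) / n
      py <- tabulate(by, ky) / n
      pj <- matrix(tab, kx, ky)
      nz <- pj > 0
      i_xy <- sum(pj[nz] * log2(pj[nz] / outer(px, py)[nz]))
      val <- i_xy / log2(min(kx, ky))
      if (val > best) { best <- val; best_grid <- c(kx, ky) }
    }
  }
  list(mic = min(best, 1), grid = best_grid)
}
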