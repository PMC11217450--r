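#' @keywords internal
"_PACKAGE"

## Internal helpers shared across modules.

# Run code under a fixed RNG seed, restoring the caller's RNG state on exit.
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Z-score a vector; constant input is an error for embedding (caller decides),
# here we return zeros to keep batch paths total.
zscore <- function(x, strict = FALSE) {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) {
    if (strict) stop("cannot z-score a constant trace")
    return(rep(0, length(x)))
  }
  (x - mean(x)) / s
}

# Row-wise z-score of a matrix [n x T]; constant rows become zero rows.
zscore_rows <- function(m) {
  mu <- rowMeans(m)
  s <- sqrt(rowMeans(m * m) - mu^2) * sqrt(ncol(m) / (ncol(m) - 1))
  s[!is.finite(s) | s < .Machine$double.eps] <- Inf
  (m - mu) / s
}

# Histogram-based mutual information (bits) between two numeric vectors,
# equal-width bins.
hist_mi <- function(x, y, bins = 16L) {
  bx <- cut(x, breaks = bins, labels = FALSE, include.lowest = TRUE)
  by <- cut(y, breaks = bins, labels = FALSE, include.lowest = TRUE)
  joint <- table(bx, by) / length(x)
  px <- rowSums(joint); py <- colSums(joint)
  nz <- joint > 0
  sum(joint[nz] * log2(joint[nz] / outer(px, py)[nz]))
}

# Stable softmax over rows of a matrix of logits.
softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
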