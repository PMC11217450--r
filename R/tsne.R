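## Exact (O(n^2)) t-SNE for the small embedding tasks in this package
## (hundreds of cohorts or neurons). Standard formulation: per-point
## bandwidths calibrated to a target perplexity by bisection, symmetrized
## affinities with early exaggeration, momentum gradient descent on the
## Student-t low-dimensional similarities.

# Conditional affinities for one row given squared distances and beta.
.tsne_row_p <- function(d2, beta) {
  p <- exp(-d2 * beta)
  s <- sum(p)
  if (s < 1e-300) return(list(H = 0, p = p * 0))
  p <- p / s
  H <- -sum(p[p > 0] * log(p[p > 0]))
  list(H = H, p = p)
}

#' 2-D t-SNE embedding
#'
#' @param X numeric matrix \[n x d\] of features.
#' @param perplexity target perplexity (effective neighbor count).
#' @param max_iter gradient-descent iterations.
#' @param seed RNG seed for the initial layout.
#' @return matrix \[n x 2\] of embedding coordinates.
#' @export
tsne_embed <- function(X, perplexity = 30, max_iter = 400, seed = 0) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 4) stop("need at least 4 points for t-SNE")
  perplexity <- min(perplexity, (n - 1) / 3)
  D2 <- as.matrix(stats::dist(X))^2
  target <- log(perplexity)
  P <- matrix(0, n, n)
  for (i in seq_len(n)) {
    d2 <- D2[i, -i]
    beta <- 1; lo <- -Inf; hi <- Inf
    for (it in 1:50) {
      r <- .tsne_row_p(d2, beta)
      diff <- r$H - target
      if (abs(diff) < 1e-5) break
      if (diff > 0) { lo <- beta; beta <- if (is.finite(hi)) (beta + hi) / 2 else beta * 2 }
      else { hi <- beta; beta <- if (is.finite(lo)) (beta + lo) / 2 else beta / 2 }
    }
    P[i, -i] <- r$p
  }
  P <- (P + t(P)) / (2 * n)
  P <- pmax(P, 1e-12)
  with_seed(seed, {
    Y <- matrix(stats::rnorm(n * 2, sd = 1e-4), n, 2)
    inc <- matrix(0, n, 2)
    momentum <- 0.5; eta <- 100
    exaggeration <- 12
    for (iter in seq_len(max_iter)) {
      Pe <- if (iter <= 100) P * exaggeration else P
      sumY <- rowSums(Y^2)
      num <- 1 / (1 + outer(sumY, sumY, `+`) - 2 * tcrossprod(Y))
      diag(num) <- 0
      Q <- pmax(num / sum(num), 1e-12)
      L <- (Pe - Q) * num
      grad <- 4 * (diag(rowSums(L)) - L) %*% Y
      if (iter == 101) momentum <- 0.8
      inc <- momentum * inc - eta * grad
      Y <- Y + inc
      Y <- sweep(Y, 2, colMeans(Y))
    }
    Y
  })
}
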