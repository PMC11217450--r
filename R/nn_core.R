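## Minimal neural-network primitives on base matrix algebra: batched 1-D
## (dilated) convolutions over [batch x time x channel] arrays, dense
## layers, activations, softmax cross-entropy, and an Adam optimizer.
## All networks in the package (graph state classifier, cohort time
## predictor, attribution network, contrastive encoder) run on these.

# Shift a [B x T x C] array along time: out[, t, ] = X[, t + s, ],
# zero-padded outside.
shift_time <- function(X, s) {
  if (s == 0) return(X)
  d <- dim(X)
  out <- array(0, d)
  if (s > 0) {
    if (s < d[2]) out[, 1:(d[2] - s), ] <- X[, (1 + s):d[2], , drop = FALSE]
  } else {
    s <- -s
    if (s < d[2]) out[, (1 + s):d[2], ] <- X[, 1:(d[2] - s), , drop = FALSE]
  }
  out
}

# [B x T x Ci] times [Ci x Co] -> [B x T x Co]
tensor_mat <- function(X, W) {
  d <- dim(X)
  array(matrix(X, d[1] * d[2], d[3]) %*% W, c(d[1], d[2], ncol(W)))
}

# Tap j of a conv kernel as a [c_in x c_out] matrix.
tap_matrix <- function(W, j) {
  dw <- dim(W)
  matrix(W[j, , ], dw[2], dw[3])
}

conv1d_init <- function(k, c_in, c_out, gain = 1) {
  sd <- gain * sqrt(2 / (k * c_in))
  list(W = array(stats::rnorm(k * c_in * c_out, sd = sd), c(k, c_in, c_out)),
       b = numeric(c_out), k = k)
}

# Same-padded (dilated) 1-D convolution. Returns output and keeps the
# input in the cache for the backward pass.
conv1d_forward <- function(layer, X, dilation = 1) {
  d <- dim(X); k <- layer$k
  c_out <- dim(layer$W)[3]
  Y <- array(rep(layer$b, each = d[1] * d[2]), c(d[1], d[2], c_out))
  off <- (seq_len(k) - (k %/% 2 + 1L)) * dilation
  for (j in seq_len(k))
    Y <- Y + tensor_mat(shift_time(X, off[j]), tap_matrix(layer$W, j))
  list(Y = Y, X = X, dilation = dilation)
}

conv1d_backward <- function(layer, cache, dY) {
  X <- cache$X; d <- dim(X); k <- layer$k
  off <- (seq_len(k) - (k %/% 2 + 1L)) * cache$dilation
  dW <- array(0, dim(layer$W))
  dX <- array(0, d)
  dYm <- matrix(dY, d[1] * d[2], dim(dY)[3])
  for (j in seq_len(k)) {
    Xs <- shift_time(X, off[j])
    Wj <- tap_matrix(layer$W, j)
    dW[j, , ] <- crossprod(matrix(Xs, d[1] * d[2], d[3]), dYm)
    dX <- dX + shift_time(tensor_mat(dY, t(Wj)), -off[j])
  }
  list(dX = dX, dW = dW, db = colSums(dYm))
}

dense_init <- function(n_in, n_out, gain = 1) {
  list(W = matrix(stats::rnorm(n_in * n_out, sd = gain * sqrt(2 / n_in)),
                  n_in, n_out),
       b = numeric(n_out))
}

dense_forward <- function(layer, X) {
  list(Y = sweep(X %*% layer$W, 2, layer$b, `+`), X = X)
}

dense_backward <- function(layer, cache, dY) {
  list(dX = dY %*% t(layer$W), dW = crossprod(cache$X, dY),
       db = colSums(dY))
}

leaky_relu <- function(x, slope = 0.2) {
  x * ifelse(x > 0, 1, slope)
}

leaky_relu_grad <- function(x, slope = 0.2) {
  ifelse(x > 0, 1, slope)
}

# Softmax cross-entropy over rows; labels are 1-based class indices.
# Returns mean loss and the gradient w.r.t. the logits.
softmax_xent <- function(logits, labels) {
  p <- softmax_rows(logits)
  n <- nrow(logits)
  idx <- cbind(seq_len(n), labels)
  loss <- -mean(log(pmax(p[idx], 1e-12)))
  g <- p
  g[idx] <- g[idx] - 1
  list(loss = loss, grad = g / n, probs = p)
}

# Adam optimizer over a named flat list of numeric arrays.
adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0)
}

adam_step <- function(params, grads, state, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8, weight_decay = 0) {
  state$t <- state$t + 1
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
    if (weight_decay > 0)
      params[[nm]] <- params[[nm]] * (1 - lr * weight_decay)
  }
  list(params = params, state = state)
}

# Linear resampling of a [n x d] node/coordinate matrix to m rows.
resample_rows <- function(x, m) {
  n <- nrow(x)
  if (n == m) return(x)
  pos <- seq(1, n, length.out = m)
  lo <- floor(pos); hi <- pmin(lo + 1, n); w <- pos - lo
  x[lo, , drop = FALSE] * (1 - w) + x[hi, , drop = FALSE] * w
}
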