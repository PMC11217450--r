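## Dynamical-state analysis: time-delay embedding of z-scored traces into
## directed phase-space graphs, training-set augmentation, a graph
## convolutional state classifier, population state maps, and 12-h
## high/low activity mode assignment.

#' Delay-embed a trace into a directed phase-space graph
#'
#' Z-scores the trace, picks the embedding delay tau as the first local
#' minimum of the histogram mutual information over delays 1..T/4 (falling
#' back to the delay where MI first drops below half its lag-1 value, then
#' to the global minimum), and builds the 3-D delay embedding whose
#' consecutive points are linked by directed edges.
#'
#' @param trace numeric vector (raw or dF/F; z-scored internally).
#' @param m embedding dimension (default 3).
#' @param tau optional fixed delay (frames); skips the MI search.
#' @param bins histogram bins for the MI estimate.
#' @param recurrence if `TRUE` also return the binary recurrence matrix at
#'   distance threshold `theta` * max pairwise distance.
#' @param theta recurrence distance threshold (fraction of max distance).
#' @return `scn_manifold` object: `nodes` (\[T-(m-1)tau x m\]), `edges`
#'   (two-column matrix i -> i+1), `tau`, `m`, `mi_curve`, optionally
#'   `recurrence`.
#' @export
embed_manifold <- function(trace, m = 3, tau = NULL, bins = 16,
                           recurrence = FALSE, theta = 0.1) {
  if (stats::sd(trace) < 1e-12 || !is.finite(stats::sd(trace)))
    stop("constant trace: z-score undefined, cannot embed")
  x <- zscore(trace, strict = TRUE)
  n <- length(x)
  if (n < 3 * m) stop("trace too short to embed")
  mi_curve <- NULL
  if (is.null(tau)) {
    dmax <- max(2L, floor(n / 4))
    mi <- vapply(seq_len(dmax), function(d)
      hist_mi(x[1:(n - d)], x[(1 + d):n], bins), numeric(1))
    mi_curve <- mi
    loc_min <- which(diff(sign(diff(mi))) > 0) + 1L
    tau <- if (length(loc_min) > 0) loc_min[1]
           else {
             below <- which(mi <= mi[1] / 2)
             if (length(below) > 0) below[1] else which.min(mi)
           }
  }
  tau <- max(1L, as.integer(tau))
  n_nodes <- n - (m - 1) * tau
  if (n_nodes < 2) stop("delay too large for trace length")
  nodes <- vapply(0:(m - 1), function(j) x[(1 + j * tau):(n_nodes + j * tau)],
                  numeric(n_nodes))
  edges <- cbind(seq_len(n_nodes - 1), 2:n_nodes)
  out <- list(nodes = nodes, edges = edges, tau = tau, m = m,
              mi_curve = mi_curve)
  if (recurrence) {
    dm <- as.matrix(stats::dist(nodes))
    out$recurrence <- dm <= theta * max(dm)
  }
  class(out) <- "scn_manifold"
  out
}

# Magnitude-perturbation factors used by the augmentation (mean 1,
# variance 0.5).
aug_magnitude_factor <- function(n) {
  stats::rnorm(n, mean = 1, sd = sqrt(0.5))
}

# Swap the first floor(n/2) rows with the rest (involution for even n).
half_swap <- function(nodes) {
  n <- nrow(nodes)
  k <- n %/% 2
  nodes[c((k + 1):n, seq_len(k)), , drop = FALSE]
}

#' Expand a labeled manifold set four-fold by augmentation
#'
#' Output = originals, magnitude-perturbed copies (node coordinates
#' multiplied by a random factor with mean 1 and variance 0.5),
#' half-swapped copies (first and second node halves exchanged, split at
#' floor(n/2)), and perturbed half-swapped copies. Labels are preserved,
#' so 25% of the expanded set is original data.
#'
#' @param manifolds list of `scn_manifold` objects or node matrices.
#' @param labels integer class labels, one per manifold.
#' @return list with `manifolds` (length 4x input), `labels`, `origin`
#'   (`"original"`, `"perturbed"`, `"swapped"`, `"perturbed_swapped"`).
#' @export
augment_labeled_manifolds <- function(manifolds, labels) {
  stopifnot(length(manifolds) == length(labels), length(manifolds) > 0)
  get_nodes <- function(m) if (inherits(m, "scn_manifold")) m$nodes else m
  nodes <- lapply(manifolds, get_nodes)
  n <- length(nodes)
  fac1 <- aug_magnitude_factor(n)
  fac2 <- aug_magnitude_factor(n)
  out <- c(nodes,
           mapply(function(x, f) x * f, nodes, fac1, SIMPLIFY = FALSE),
           lapply(nodes, half_swap),
           mapply(function(x, f) half_swap(x) * f, nodes, fac2,
                  SIMPLIFY = FALSE))
  list(manifolds = out, labels = rep(labels, 4),
       origin = rep(c("original", "perturbed", "swapped",
                      "perturbed_swapped"), each = n))
}

## --- Graph convolutional state classifier -------------------------------

# Global max pooling over the time/node axis of a [B x T x C] array,
# tracking argmax indices for backprop.
max_pool_time <- function(H) {
  d <- dim(H)
  pool <- matrix(H[, 1, ], d[1], d[3])
  arg <- matrix(1L, d[1], d[3])
  if (d[2] > 1) for (t in 2:d[2]) {
    ht <- matrix(H[, t, ], d[1], d[3])
    upd <- ht > pool
    pool[upd] <- ht[upd]
    arg[upd] <- t
  }
  list(pool = pool, arg = arg)
}

# Directed path-graph propagation with self-loops, in-degree normalized:
# node 1 keeps itself; node t>1 averages itself and its predecessor.
gcn_prop <- function(X) {
  Y <- 0.5 * (X + shift_time(X, -1))
  Y[, 1, ] <- X[, 1, ]
  Y
}

# Transpose operator of gcn_prop for backprop.
gcn_prop_back <- function(dY) {
  dX <- 0.5 * dY + 0.5 * shift_time(dY, 1)
  dX[, 1, ] <- dX[, 1, ] + 0.5 * dY[, 1, ]
  dX
}

gcn_init <- function(n_feat = 3, width = 32, n_class = 6) {
  list(g1 = dense_init(n_feat, width), g2 = dense_init(width, width),
       g3 = dense_init(width, width),
       f1 = dense_init(3 * width, width), f2 = dense_init(width, n_class))
}

# Forward pass over a batch X [B x n x 3]; returns logits and caches.
gcn_forward <- function(p, X, slope = 0.2) {
  d <- dim(X)
  a1 <- tensor_mat(gcn_prop(X), p$g1$W)
  a1 <- sweep(a1, 3, p$g1$b, `+`)
  h1 <- leaky_relu(a1, slope)
  a2 <- tensor_mat(gcn_prop(h1), p$g2$W)
  a2 <- sweep(a2, 3, p$g2$b, `+`)
  h2 <- leaky_relu(a2, slope)
  a3 <- tensor_mat(gcn_prop(h2), p$g3$W)
  a3 <- sweep(a3, 3, p$g3$b, `+`)
  h3 <- leaky_relu(a3, slope)
  # concatenate the three layer outputs along channels, then global max
  # pooling over nodes
  H <- array(c(h1, h2, h3), c(d[1], d[2], 3 * dim(h1)[3]))
  mp <- max_pool_time(H)
  pool <- mp$pool
  arg <- mp$arg
  z1 <- sweep(pool %*% p$f1$W, 2, p$f1$b, `+`)
  r1 <- leaky_relu(z1, slope)
  logits <- sweep(r1 %*% p$f2$W, 2, p$f2$b, `+`)
  list(logits = logits,
       cache = list(X = X, a1 = a1, h1 = h1, a2 = a2, h2 = h2, a3 = a3,
                    h3 = h3, pool = pool, arg = arg, z1 = z1, r1 = r1,
                    slope = slope))
}

gcn_backward <- function(p, cache, dlogits) {
  s <- cache$slope
  g <- list()
  g$f2.W <- crossprod(cache$r1, dlogits); g$f2.b <- colSums(dlogits)
  dr1 <- dlogits %*% t(p$f2$W)
  dz1 <- dr1 * leaky_relu_grad(cache$z1, s)
  g$f1.W <- crossprod(cache$pool, dz1); g$f1.b <- colSums(dz1)
  dpool <- dz1 %*% t(p$f1$W)
  d <- dim(cache$h1)
  width <- d[3]
  dH <- array(0, c(d[1], d[2], 3 * width))
  # route pooled gradients to the argmax node of each (sample, channel)
  B <- d[1]
  for (ch in seq_len(3 * width)) {
    idx <- cbind(seq_len(B), cache$arg[, ch], ch)
    dH[idx] <- dpool[, ch]
  }
  dh1 <- dH[, , seq_len(width), drop = FALSE]
  dh2 <- dH[, , width + seq_len(width), drop = FALSE]
  dh3 <- dH[, , 2 * width + seq_len(width), drop = FALSE]
  da3 <- dh3 * leaky_relu_grad(cache$a3, s)
  ph2 <- gcn_prop(cache$h2)
  g$g3.W <- crossprod(matrix(ph2, B * d[2], width),
                      matrix(da3, B * d[2], width))
  g$g3.b <- colSums(matrix(da3, B * d[2], width))
  dh2 <- dh2 + gcn_prop_back(tensor_mat(da3, t(p$g3$W)))
  da2 <- dh2 * leaky_relu_grad(cache$a2, s)
  ph1 <- gcn_prop(cache$h1)
  g$g2.W <- crossprod(matrix(ph1, B * d[2], width),
                      matrix(da2, B * d[2], width))
  g$g2.b <- colSums(matrix(da2, B * d[2], width))
  dh1 <- dh1 + gcn_prop_back(tensor_mat(da2, t(p$g2$W)))
  da1 <- dh1 * leaky_relu_grad(cache$a1, s)
  pX <- gcn_prop(cache$X)
  g$g1.W <- crossprod(matrix(pX, B * d[2], dim(cache$X)[3]),
                      matrix(da1, B * d[2], width))
  g$g1.b <- colSums(matrix(da1, B * d[2], width))
  g
}

# Flatten/unflatten GCN params for the Adam optimizer.
gcn_flatten <- function(p) {
  list(g1.W = p$g1$W, g1.b = p$g1$b, g2.W = p$g2$W, g2.b = p$g2$b,
       g3.W = p$g3$W, g3.b = p$g3$b, f1.W = p$f1$W, f1.b = p$f1$b,
       f2.W = p$f2$W, f2.b = p$f2$b)
}

gcn_unflatten <- function(fl) {
  list(g1 = list(W = fl$g1.W, b = fl$g1.b),
       g2 = list(W = fl$g2.W, b = fl$g2.b),
       g3 = list(W = fl$g3.W, b = fl$g3.b),
       f1 = list(W = fl$f1.W, b = fl$f1.b),
       f2 = list(W = fl$f2.W, b = fl$f2.b))
}

# Stack a list of manifolds into a [B x n_nodes x 3] array by linear node
# resampling to a common node count.
stack_manifolds <- function(manifolds, n_nodes) {
  get_nodes <- function(m) if (inherits(m, "scn_manifold")) m$nodes else m
  B <- length(manifolds)
  X <- array(0, c(B, n_nodes, 3))
  for (i in seq_len(B))
    X[i, , ] <- resample_rows(get_nodes(manifolds[[i]]), n_nodes)
  X
}

#' Train the graph-convolutional state classifier
#'
#' Three graph-convolution layers of width 32 with leaky-rectifier
#' activations (negative slope 0.2) on the directed temporal-successor
#' graph, concatenation of the three layer outputs, global max pooling
#' over nodes, and a two-layer classifier head, optimized with Adam
#' (learning rate 0.001) under cross-entropy for 160 epochs. Node
#' sequences are linearly resampled to a common length for batching.
#'
#' @param manifolds list of `scn_manifold` objects or node matrices.
#' @param labels integer state labels (1..6); at least 2 classes required.
#' @param epochs,lr,batch_size,width,slope training hyperparameters.
#' @param n_nodes common node count after resampling.
#' @param seed RNG seed for initialization and batching.
#' @return `scn_state_classifier` with trained `params`, `loss_curve`,
#'   `n_nodes`, `classes`.
#' @export
train_state_classifier <- function(manifolds, labels, epochs = 160,
                                   lr = 1e-3, batch_size = 64, width = 32,
                                   slope = 0.2, n_nodes = 100, seed = 0) {
  classes <- sort(unique(labels))
  if (length(classes) < 2) stop("need at least 2 classes to train")
  y <- match(labels, classes)
  X <- stack_manifolds(manifolds, n_nodes)
  B <- dim(X)[1]
  with_seed(seed, {
    p <- gcn_init(3, width, length(classes))
    fl <- gcn_flatten(p)
    st <- adam_init(fl)
    loss_curve <- numeric(epochs)
    for (ep in seq_len(epochs)) {
      ord <- sample.int(B)
      tot <- 0
      for (start in seq(1, B, by = batch_size)) {
        idx <- ord[start:min(B, start + batch_size - 1)]
        p <- gcn_unflatten(fl)
        fw <- gcn_forward(p, X[idx, , , drop = FALSE], slope)
        ce <- softmax_xent(fw$logits, y[idx])
        g <- gcn_backward(p, fw$cache, ce$grad)
        upd <- adam_step(fl, g, st, lr)
        fl <- upd$params; st <- upd$state
        tot <- tot + ce$loss * length(idx)
      }
      loss_curve[ep] <- tot / B
    }
    res <- list(params = gcn_unflatten(fl), loss_curve = loss_curve,
                n_nodes = n_nodes, classes = classes, width = width,
                slope = slope)
    class(res) <- "scn_state_classifier"
    res
  })
}

#' Predict state labels for manifolds
#'
#' @param classifier a trained `scn_state_classifier`.
#' @param manifolds list of manifolds or node matrices.
#' @return data.frame with `state` and per-class probability columns.
#' @export
predict_states <- function(classifier, manifolds) {
  X <- stack_manifolds(manifolds, classifier$n_nodes)
  fw <- gcn_forward(classifier$params, X, classifier$slope)
  probs <- softmax_rows(fw$logits)
  state <- classifier$classes[max.col(probs)]
  out <- data.frame(state = state)
  colnames(probs) <- paste0("p", classifier$classes)
  cbind(out, as.data.frame(probs))
}

#' Classify dynamical states for every neuron and session of a dataset
#'
#' Embeds each z-scored session trace, applies the classifier, and
#' summarizes state fractions per hour plus a raster matrix.
#'
#' @param dataset an `scn_dataset`.
#' @param classifier a trained `scn_state_classifier`.
#' @return list with `states` (\[N x S\] matrix), `confidence`,
#'   `fractions` (\[S x K\] state fraction per hour, rows sum to 1),
#'   `raster` (alias of `states`).
#' @export
classify_states <- function(dataset, classifier) {
  stopifnot(inherits(dataset, "scn_dataset"))
  d <- dim(dataset$fluorescence)
  states <- matrix(NA_integer_, d[1], d[2])
  conf <- matrix(NA_real_, d[1], d[2])
  for (s in seq_len(d[2])) {
    mans <- lapply(seq_len(d[1]), function(i) {
      tr <- dataset$fluorescence[i, s, ]
      if (stats::sd(tr) < 1e-12) return(NULL)
      embed_manifold(tr)
    })
    ok <- !vapply(mans, is.null, logical(1))
    if (any(ok)) {
      pr <- predict_states(classifier, mans[ok])
      states[which(ok), s] <- pr$state
      conf[which(ok), s] <- apply(as.matrix(pr[, -1, drop = FALSE]), 1, max)
    }
  }
  k <- classifier$classes
  fractions <- t(apply(states, 2, function(col)
    tabulate(match(col, k), length(k)) / sum(!is.na(col))))
  colnames(fractions) <- paste0("state", k)
  list(states = states, confidence = conf, fractions = fractions,
       raster = states)
}

#' Assign 12-h high/low activity modes per neuron
#'
#' For each neuron the contiguous 12-session circular window with maximal
#' mean session dF/F is the high-activity (H) mode; the complement is the
#' L mode. A two-sided Wilcoxon rank-sum test compares H vs L session
#' means per neuron (`wilcox_p`); because the window is itself chosen to
#' maximize the H mean, the primary `p_value` is a selection-aware
#' permutation test (session means permuted, the max-window statistic
#' recomputed) that keeps the type-I rate nominal.
#'
#' @param dataset an `scn_dataset` with an even number (>= 4) of sessions;
#'   the canonical design is 24 hourly sessions.
#' @param n_perm permutations for the selection-aware p-value.
#' @return data.frame per neuron: `h_start` (0-based session index of the
#'   H window), `mean_H`, `mean_L`, `p_value` (permutation),
#'   `wilcox_p`; plus attribute `mode_matrix` (\[N x S\] of "H"/"L").
#' @export
assign_modes <- function(dataset, n_perm = 200) {
  stopifnot(inherits(dataset, "scn_dataset"))
  d <- dim(dataset$fluorescence)
  S <- d[2]
  if (S < 4 || S %% 2 != 0)
    stop("mode assignment needs an even number (>= 4) of hourly sessions")
  half <- S %/% 2
  amp <- sapply(seq_len(S), function(s) rowMeans(session_dff(dataset, s)))
  # circular rolling sum over each 12-session window
  idx <- outer(seq_len(S) - 1, 0:(half - 1), function(a, b) (a + b) %% S + 1)
  h_start <- integer(d[1]); pv <- numeric(d[1]); wp <- numeric(d[1])
  mh <- numeric(d[1]); ml <- numeric(d[1])
  modes <- matrix("L", d[1], S)
  max_win_stat <- function(v) {
    win <- vapply(seq_len(S), function(s0) sum(v[idx[s0, ]]), numeric(1))
    s0 <- which.max(win)
    list(s0 = s0, stat = win[s0] / half - (sum(v) - win[s0]) / (S - half))
  }
  for (i in seq_len(d[1])) {
    obs <- max_win_stat(amp[i, ])
    s0 <- obs$s0
    hs <- idx[s0, ]
    h_start[i] <- s0 - 1L
    modes[i, hs] <- "H"
    a <- amp[i, hs]; b <- amp[i, -hs]
    mh[i] <- mean(a); ml[i] <- mean(b)
    wp[i] <- suppressWarnings(stats::wilcox.test(a, b)$p.value)
    null_stat <- vapply(seq_len(n_perm), function(p)
      max_win_stat(sample(amp[i, ]))$stat, numeric(1))
    pv[i] <- (1 + sum(null_stat >= obs$stat)) / (1 + n_perm)
  }
  out <- data.frame(neuron = seq_len(d[1]), h_start = h_start,
                    mean_H = mh, mean_L = ml, p_value = pv, wilcox_p = wp)
  attr(out, "mode_matrix") <- modes
  out
}
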