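## Population time decoding: PCA trajectory of hourly population activity,
## 6:1:3 neuron partition, cohort-polling convolutional time predictor,
## accuracy curves, and feature-space views.
##
## Cohort handling: each cohort is a set of per-neuron z-scored session
## traces. The first convolutional layer is linear, so averaging its
## per-neuron outputs equals convolving the cohort-mean trace; cohorts are
## therefore reduced to their mean trace before the network, which keeps
## the predictor permutation-invariant in the neurons and makes training
## cost independent of cohort size.

#' PCA trajectory of hourly population activity
#'
#' Uses the per-neuron session-mean dF/F as the population feature vector
#' of each hour, runs PCA across the hourly vectors, and reports the
#' PC1-PC2 trajectory together with a circularity score (ratio of the
#' convex-hull perimeter to the hour-ordered closed path length; 1 means
#' the hourly path is convex and loop-like).
#'
#' @param dataset an `scn_dataset` with >= 3 sessions and >= 2 neurons.
#' @return list with `points` (\[S x 2\]), `explained` (variance
#'   fractions), `circularity`, `pca` (the `prcomp` fit).
#' @export
pca_trajectory <- function(dataset) {
  stopifnot(inherits(dataset, "scn_dataset"))
  d <- dim(dataset$fluorescence)
  if (d[2] < 3) stop("need at least 3 sessions")
  if (d[1] < 2) stop("need at least 2 neurons")
  amp <- t(sapply(seq_len(d[2]), function(s) rowMeans(session_dff(dataset, s))))
  pc <- stats::prcomp(amp, center = TRUE, scale. = FALSE)
  pts <- pc$x[, 1:2, drop = FALSE]
  path_len <- sum(sqrt(rowSums((pts - pts[c(2:nrow(pts), 1), ])^2)))
  circ <- 0
  if (path_len > 1e-12) {
    hull <- grDevices::chull(pts)
    if (length(hull) >= 3) {
      hp <- pts[hull, , drop = FALSE]
      circ <- sum(sqrt(rowSums((hp - hp[c(2:nrow(hp), 1), ])^2))) / path_len
    }
  }
  list(points = pts,
       explained = pc$sdev^2 / sum(pc$sdev^2),
       circularity = circ, pca = pc)
}

#' Partition neurons into train/validation/test pools
#'
#' Disjoint neuron pools at a 6:1:3 ratio (floor arithmetic, remainder to
#' the test pool). Cohorts must later be drawn within a single pool so no
#' neuron's trace leaks between training and evaluation.
#'
#' @param n_neurons total neuron count (>= 10), or an `scn_dataset`.
#' @param ratio three non-negative integers summing to 10.
#' @param seed RNG seed for the permutation.
#' @return list with integer index vectors `train`, `val`, `test`.
#' @export
partition_neurons <- function(n_neurons, ratio = c(6, 1, 3), seed = 0) {
  if (inherits(n_neurons, "scn_dataset"))
    n_neurons <- dim(n_neurons$fluorescence)[1]
  if (sum(ratio) != 10) stop("ratio must sum to 10 (e.g. 6:1:3)")
  if (n_neurons < 10) stop("need at least 10 neurons to partition")
  with_seed(seed, {
    perm <- sample.int(n_neurons)
    n_tr <- floor(ratio[1] / 10 * n_neurons)
    n_va <- floor(ratio[2] / 10 * n_neurons)
    list(train = sort(perm[seq_len(n_tr)]),
         val = sort(perm[n_tr + seq_len(n_va)]),
         test = sort(perm[(n_tr + n_va + 1):n_neurons]))
  })
}

# Z-scored session traces for a set of neurons: [length(pool) x T].
pool_session_z <- function(dataset, pool, session) {
  zscore_rows(matrix(session_dff(dataset, session)[pool, ], length(pool)))
}

# Draw `n` cohort-mean traces with random hour labels from one pool.
# `size` may be a vector of candidate cohort sizes (sampled per draw).
# Returns X [n x T] and labels (1-based session index).
draw_cohort_means <- function(dataset, pool, size, n, zcache = NULL) {
  d <- dim(dataset$fluorescence)
  if (max(size) > length(pool)) stop("cohort_size exceeds pool size")
  lab <- sample.int(d[2], n, replace = TRUE)
  sz <- if (length(size) > 1) sample(size, n, replace = TRUE)
        else rep(size, n)
  X <- matrix(0, n, d[3])
  for (i in seq_len(n)) {
    ids <- pool[sample.int(length(pool), sz[i])]
    z <- if (is.null(zcache)) {
      zscore_rows(matrix(session_dff(dataset, lab[i])[ids, ], sz[i]))
    } else zcache[[lab[i]]][match(ids, pool), , drop = FALSE]
    X[i, ] <- colMeans(z)
  }
  list(X = X, labels = lab)
}

# Precompute z-scored traces of a pool for all sessions (list of [P x T]).
pool_zcache <- function(dataset, pool) {
  d <- dim(dataset$fluorescence)
  lapply(seq_len(d[2]), function(s) pool_session_z(dataset, pool, s))
}

## --- conv + residual block + FC predictor -------------------------------

tp_init <- function(n_class, n_time, width = 32, k = 7, pool_s = 4) {
  n_seg <- n_time %/% pool_s
  list(c1 = conv1d_init(k, 1, width), c2 = conv1d_init(k, width, width),
       c3 = conv1d_init(k, width, width),
       fc = dense_init(n_seg * width, n_class), pool_s = pool_s)
}

# Strided average pooling over time: [B x T x C] -> [B x (T/s * C)].
# The hour signatures are session-locked, so the head keeps (coarse)
# positional information rather than pooling time away globally.
pool_flatten <- function(H, s) {
  d <- dim(H)
  n_seg <- d[2] %/% s
  A <- array(H[, seq_len(n_seg * s), , drop = FALSE],
             c(d[1], s, n_seg, d[3]))
  Z <- array(0, c(d[1], n_seg, d[3]))
  for (j in seq_len(s)) Z <- Z + array(A[, j, , ], c(d[1], n_seg, d[3]))
  matrix(Z / s, d[1], n_seg * d[3])
}

pool_flatten_back <- function(dZ, d, s) {
  n_seg <- d[2] %/% s
  dZa <- array(dZ, c(d[1], n_seg, d[3]))
  out <- array(0, d)
  for (j in seq_len(s)) {
    idx <- (seq_len(n_seg) - 1) * s + j
    out[, idx, ] <- dZa / s
  }
  out
}

tp_forward <- function(p, X) {
  # X: [B x T] cohort-mean traces
  d <- dim(X)
  X3 <- array(X, c(d[1], d[2], 1))
  f1 <- conv1d_forward(p$c1, X3); h1 <- pmax(f1$Y, 0)
  f2 <- conv1d_forward(p$c2, h1); h2 <- pmax(f2$Y, 0)   # feature view
  f3 <- conv1d_forward(p$c3, h2)
  a <- f3$Y + h1                                        # residual skip
  h3 <- pmax(a, 0)
  z <- pool_flatten(h3, p$pool_s)
  fc <- dense_forward(p$fc, z)
  list(logits = fc$Y,
       cache = list(f1 = f1, h1 = h1, f2 = f2, h2 = h2, f3 = f3, a = a,
                    h3 = h3, z = z, fc = fc, Tlen = d[2],
                    pool_s = p$pool_s))
}

# mean over the time axis of [B x T x C] (feature views)
apply_mean_time <- function(H) {
  d <- dim(H)
  matrix(colMeans(matrix(aperm(H, c(2, 1, 3)), d[2], d[1] * d[3])),
         d[1], d[3])
}

tp_backward <- function(p, cache, dlogits) {
  g <- list()
  db <- dense_backward(p$fc, cache$fc, dlogits)
  g$fc.W <- db$dW; g$fc.b <- db$db
  d <- dim(cache$h3)
  dh3 <- pool_flatten_back(db$dX, d, cache$pool_s)
  da <- dh3 * (cache$a > 0)
  b3 <- conv1d_backward(p$c3, cache$f3, da)
  g$c3.W <- b3$dW; g$c3.b <- b3$db
  dh2 <- b3$dX
  da2 <- dh2 * (cache$f2$Y > 0)
  b2 <- conv1d_backward(p$c2, cache$f2, da2)
  g$c2.W <- b2$dW; g$c2.b <- b2$db
  dh1 <- b2$dX + da   # skip connection gradient
  da1 <- dh1 * (cache$f1$Y > 0)
  b1 <- conv1d_backward(p$c1, cache$f1, da1)
  g$c1.W <- b1$dW; g$c1.b <- b1$db
  g
}

tp_flatten <- function(p) {
  list(c1.W = p$c1$W, c1.b = p$c1$b, c2.W = p$c2$W, c2.b = p$c2$b,
       c3.W = p$c3$W, c3.b = p$c3$b, fc.W = p$fc$W, fc.b = p$fc$b)
}

tp_unflatten <- function(fl, k = 7, pool_s = 4) {
  list(c1 = list(W = fl$c1.W, b = fl$c1.b, k = k),
       c2 = list(W = fl$c2.W, b = fl$c2.b, k = k),
       c3 = list(W = fl$c3.W, b = fl$c3.b, k = k),
       fc = list(W = fl$fc.W, b = fl$fc.b), pool_s = pool_s)
}

#' Train the cohort-polling time predictor
#'
#' Convolutional network (one conv layer, a residual block of `width`
#' channels, global average pooling and one fully connected layer) trained
#' with cross-entropy and Adam on randomly drawn labeled cohorts from the
#' training pool, with early stopping on validation-pool cohorts.
#'
#' @param dataset an `scn_dataset`.
#' @param pools neuron partition from [partition_neurons()].
#' @param cohort_size neurons per cohort (<= training pool size).
#' @param cohorts_per_hour training cohorts drawn per hour and epoch.
#' @param epochs maximum epochs.
#' @param lr Adam learning rate.
#' @param batch_size minibatch size.
#' @param width residual block channels.
#' @param val_cohorts validation cohorts for early stopping.
#' @param patience stop after this many epochs without val improvement
#'   (or immediately at perfect validation accuracy).
#' @param aug_noise_sd SD of Gaussian noise added to training cohort
#'   means (regularizer emulating the neuron-resampling shift between
#'   pools); `"auto"` uses sqrt(1/cohort_size + 1/pool_size).
#' @param weight_decay decoupled L2 weight decay.
#' @param seed RNG seed.
#' @return `scn_time_predictor` with `params`, `history` (per-epoch loss
#'   and validation accuracy), `cohort_size`, `n_class`.
#' @export
train_time_predictor <- function(dataset, pools, cohort_size,
                                 cohorts_per_hour = 20, epochs = 60,
                                 lr = 1e-3, batch_size = 128, width = 32,
                                 val_cohorts = 240, patience = 12,
                                 aug_noise_sd = 0,
                                 weight_decay = 1e-4, seed = 0) {
  stopifnot(inherits(dataset, "scn_dataset"))
  d <- dim(dataset$fluorescence)
  if (cohort_size > length(pools$train))
    stop("cohort_size exceeds training pool size")
  n_class <- d[2]
  with_seed(seed, {
    ztr <- pool_zcache(dataset, pools$train)
    zva <- pool_zcache(dataset, pools$val)
    val_size <- min(cohort_size, length(pools$val))
    val <- draw_cohort_means(dataset, pools$val, val_size, val_cohorts,
                             zcache = zva)
    p <- tp_init(n_class, d[3], width)
    fl <- tp_flatten(p)
    st <- adam_init(fl)
    n_train <- cohorts_per_hour * n_class
    best <- -Inf; best_fl <- fl; stall <- 0
    hist <- data.frame(epoch = integer(), loss = numeric(),
                       val_acc = numeric())
    if (identical(aug_noise_sd, "auto"))
      aug_noise_sd <- sqrt(1 / cohort_size + 1 / length(pools$train))
    # neuron-resampling augmentation: train on a mix of cohort sizes down
    # to 1/4 of the target so the model is robust to the structured
    # sampling noise that separates the neuron pools
    train_sizes <- unique(pmax(1L, round(cohort_size / c(4, 2, 1.5, 1))))
    for (ep in seq_len(epochs)) {
      tr <- draw_cohort_means(dataset, pools$train, train_sizes, n_train,
                              zcache = ztr)
      if (aug_noise_sd > 0)
        tr$X <- tr$X + stats::rnorm(length(tr$X), sd = aug_noise_sd)
      ord <- sample.int(n_train)
      tot <- 0
      for (start in seq(1, n_train, by = batch_size)) {
        idx <- ord[start:min(n_train, start + batch_size - 1)]
        p <- tp_unflatten(fl)
        fw <- tp_forward(p, tr$X[idx, , drop = FALSE])
        ce <- softmax_xent(fw$logits, tr$labels[idx])
        g <- tp_backward(p, fw$cache, ce$grad)
        upd <- adam_step(fl, g, st, lr, weight_decay = weight_decay)
        fl <- upd$params; st <- upd$state
        tot <- tot + ce$loss * length(idx)
      }
      fw <- tp_forward(tp_unflatten(fl), val$X)
      acc <- mean(max.col(fw$logits) == val$labels)
      hist <- rbind(hist, data.frame(epoch = ep, loss = tot / n_train,
                                     val_acc = acc))
      if (acc > best) { best <- acc; best_fl <- fl; stall <- 0 }
      else stall <- stall + 1
      if (best >= 1 - 1e-9 || stall >= patience) break
    }
    res <- list(params = tp_unflatten(best_fl), history = hist,
                cohort_size = cohort_size, n_class = n_class,
                width = width)
    class(res) <- "scn_time_predictor"
    res
  })
}

#' Predict hour labels for cohort-mean traces
#'
#' @param predictor a trained `scn_time_predictor`.
#' @param X matrix \[B x T\] of cohort-mean z-scored traces.
#' @return list with `hour` (1-based session index) and `probs`.
#' @export
predict_hours <- function(predictor, X) {
  fw <- tp_forward(predictor$params, X)
  probs <- softmax_rows(fw$logits)
  list(hour = max.col(probs), probs = probs)
}

#' Evaluate cohort-polling accuracy on a neuron pool
#'
#' @param predictor trained predictor.
#' @param dataset an `scn_dataset`.
#' @param pool neuron indices to poll (e.g. the test pool).
#' @param size cohort size.
#' @param trials number of random cohorts.
#' @param seed RNG seed.
#' @return fraction of correctly decoded cohorts.
#' @export
cohort_accuracy <- function(predictor, dataset, pool, size, trials = 500,
                            seed = 0) {
  with_seed(seed, {
    zc <- pool_zcache(dataset, pool)
    te <- draw_cohort_means(dataset, pool, size, trials, zcache = zc)
    mean(predict_hours(predictor, te$X)$hour == te$labels)
  })
}

#' Accuracy as a function of cohort size
#'
#' Trains one predictor per cohort size and seed and evaluates it on
#' random test-pool cohorts, reporting mean +/- SEM across seeds and a
#' one-sided paired trend statistic across sizes.
#'
#' @param dataset an `scn_dataset`.
#' @param sizes cohort sizes to test.
#' @param trials evaluation cohorts per size and seed.
#' @param seeds integer vector of seeds.
#' @param ... passed on to [train_time_predictor()].
#' @return list with `table` (size, seed, accuracy), `summary`
#'   (mean, sem per size), `trend_p` (one-sided p-value that accuracy
#'   increases with size, paired across seeds).
#' @export
accuracy_curve <- function(dataset, sizes = c(1, 100, 300, 900),
                           trials = 500, seeds = 0:4, ...) {
  if (trials < 30) warning("fewer than 30 trials: accuracy estimates noisy")
  pools <- partition_neurons(dataset, seed = 0)
  rows <- list()
  for (sd_ in seeds) {
    for (sz in sizes) {
      pred <- train_time_predictor(dataset, pools, sz, seed = sd_, ...)
      acc <- cohort_accuracy(pred, dataset, pools$test,
                             min(sz, length(pools$test)), trials,
                             seed = sd_ + 1000)
      rows[[length(rows) + 1]] <- data.frame(size = sz, seed = sd_,
                                             accuracy = acc)
    }
  }
  tab <- do.call(rbind, rows)
  sm <- do.call(rbind, lapply(split(tab, tab$size), function(df)
    data.frame(size = df$size[1], mean = mean(df$accuracy),
               sem = stats::sd(df$accuracy) / sqrt(nrow(df)))))
  sm <- sm[order(sm$size), ]
  trend_p <- NA_real_
  if (length(sizes) >= 2 && nrow(tab) >= 4 &&
      stats::sd(tab$accuracy) > 1e-12) {
    # one-sided rank trend over all (size, accuracy) pairs pooled
    # across seeds; Kendall handles the ties among saturated accuracies
    tt <- tryCatch(suppressWarnings(
      stats::cor.test(tab$size, tab$accuracy, method = "kendall",
                      alternative = "greater")),
      error = function(e) NULL)
    if (!is.null(tt)) trend_p <- tt$p.value
  }
  list(table = tab, summary = sm, trend_p = trend_p)
}

#' Feature-space view of cohorts via t-SNE
#'
#' Embeds the time-pooled output of the second convolutional layer of the
#' predictor for a set of cohorts into 2-D with t-SNE and reports the mean
#' silhouette width of the hour labels in that plane.
#'
#' @param predictor trained `scn_time_predictor`.
#' @param dataset an `scn_dataset`.
#' @param pool neuron pool to draw display cohorts from.
#' @param size cohort size.
#' @param n_cohorts cohorts to embed.
#' @param perplexity t-SNE perplexity.
#' @param seed RNG seed.
#' @return list with `coords` (\[n x 2\]), `hour`, `silhouette`.
#' @export
embed_feature_space <- function(predictor, dataset, pool, size,
                                n_cohorts = 240, perplexity = 20,
                                seed = 0) {
  with_seed(seed, {
    zc <- pool_zcache(dataset, pool)
    dr <- draw_cohort_means(dataset, pool, size, n_cohorts, zcache = zc)
    if (length(unique(dr$labels)) < 2)
      stop("need at least 2 hour labels to embed")
    fw <- tp_forward(predictor$params, dr$X)
    feats <- apply_mean_time(fw$cache$h2)
    coords <- tsne_embed(feats, perplexity = perplexity, seed = seed)
    sil <- cluster::silhouette(dr$labels, stats::dist(coords))
    list(coords = coords, hour = dr$labels,
         silhouette = mean(sil[, "sil_width"]))
  })
}
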