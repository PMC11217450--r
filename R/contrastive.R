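## Contrastive time-series representation learning for functional neuron
## subtype discovery: overlapping-crop view pairs with masking, noise and
## wavelet-detail augmentations; an input projection + timestamp masking +
## ten dilated residual conv blocks encoder; and a hierarchical dual
## (temporal + instance-wise) contrastive loss.

## --- Daubechies-4 wavelet (periodized, detail-only reconstruction) ------

.db4_h <- c(1 + sqrt(3), 3 + sqrt(3), 3 - sqrt(3), 1 - sqrt(3)) / (4 * sqrt(2))
.db4_g <- rev(.db4_h) * c(1, -1, 1, -1)

# One periodized analysis step: x (even length) -> list(a, d).
.dwt_step <- function(x) {
  n <- length(x)
  idx <- outer(seq(1, n, by = 2) - 1, 0:3, `+`) %% n + 1
  xm <- matrix(x[idx], ncol = 4)
  list(a = as.numeric(xm %*% .db4_h), d = as.numeric(xm %*% .db4_g))
}

# Inverse of .dwt_step.
.idwt_step <- function(a, d) {
  n <- 2 * length(a)
  x <- numeric(n)
  pos <- seq(1, n, by = 2) - 1
  for (k in 0:3) {
    tgt <- (pos + k) %% n + 1
    x[tgt] <- x[tgt] + a * .db4_h[k + 1] + d * .db4_g[k + 1]
  }
  x
}

#' High-pass (detail-only) wavelet reconstruction of a trace
#'
#' Decomposes the trace with a periodized Daubechies-4 wavelet over
#' `levels` levels, zeroes the final approximation coefficients, and
#' reconstructs, keeping only the burst-carrying high-frequency content.
#' Odd-length inputs are truncated by one sample internally and the last
#' value is repeated on output.
#'
#' @param x numeric trace.
#' @param levels decomposition depth (default 3).
#' @return numeric vector, same length as `x`.
#' @export
wavelet_detail <- function(x, levels = 3) {
  n0 <- length(x)
  n <- n0 - n0 %% 2
  v <- x[seq_len(n)]
  details <- vector("list", levels)
  in_len <- integer(levels)   # pre-padding length at each level
  for (l in seq_len(levels)) {
    in_len[l] <- length(v)
    if (length(v) %% 2 == 1) v <- c(v, v[length(v)])
    st <- .dwt_step(v)
    details[[l]] <- st$d
    v <- st$a
  }
  v <- v * 0  # drop the approximation: detail-only signal
  for (l in rev(seq_len(levels))) {
    v <- v[seq_len(length(details[[l]]))]   # undo odd-length padding
    v <- .idwt_step(v, details[[l]])
    v <- v[seq_len(in_len[l])]
  }
  if (n0 > n) v <- c(v, v[n])
  v
}

## --- view sampling -------------------------------------------------------

#' Draw a binomial timestamp mask
#'
#' Bernoulli(p) per timestamp; 1 keeps the latent vector, 0 zeroes it.
#'
#' @param n mask length.
#' @param p keep probability (default 0.5).
#' @return integer vector of 0/1.
#' @export
timestamp_mask <- function(n, p = 0.5) {
  stats::rbinom(n, 1L, p)
}

#' Sample contrastive view pairs and positive/negative index sets
#'
#' For each neuron, draws two overlapping random crops (lengths uniform in
#' \[T'/2, T'\]) and augmentation tags (binomial(0.5) timestamp mask,
#' additive Gaussian noise at `noise_frac` of the trace SD, wavelet
#' detail-only reconstruction). Positive pairs are aligned
#' (neuron, timestamp) latents across the two views inside the overlap;
#' negatives are drawn from other timestamps of the same neuron or the
#' same timestamp of other neurons, in an exact 1:1 ratio with the
#' positives.
#'
#' @param series matrix \[N x T'\] of per-neuron concatenated traces.
#' @param noise_frac Gaussian-noise SD as a fraction of each trace's SD.
#' @param mask_p timestamp-mask keep probability.
#' @return list with `views` (per neuron: crop windows, overlap, masks,
#'   augmentation tags, augmented crop matrices `x1`, `x2`), `positives`
#'   and `negatives` (data frames of index pairs, equal row counts).
#' @export
make_contrastive_views <- function(series, noise_frac = 0.1, mask_p = 0.5) {
  stopifnot(is.matrix(series))
  N <- nrow(series); Tn <- ncol(series)
  if (Tn < 16) stop("series too short: need T' >= 16")
  len1 <- sample(seq(ceiling(Tn / 2), Tn), N, replace = TRUE)
  len2 <- sample(seq(ceiling(Tn / 2), Tn), N, replace = TRUE)
  st1 <- vapply(len1, function(l) sample.int(Tn - l + 1L, 1), integer(1))
  st2 <- vapply(len2, function(l) sample.int(Tn - l + 1L, 1), integer(1))
  aug_tags <- c("crop", "mask", "noise", "wavelet-highpass")
  views <- vector("list", N)
  pos <- vector("list", N)
  for (i in seq_len(N)) {
    w1 <- st1[i]:(st1[i] + len1[i] - 1L)
    w2 <- st2[i]:(st2[i] + len2[i] - 1L)
    ov <- intersect(w1, w2)   # non-empty: both crops cover >= half
    x1 <- series[i, w1]; x2 <- series[i, w2]
    a1 <- sample(aug_tags, 1); a2 <- sample(aug_tags, 1)
    s <- stats::sd(series[i, ])
    apply_aug <- function(x, tag) {
      switch(tag,
        crop = x,
        mask = x * timestamp_mask(length(x), mask_p),
        noise = x + stats::rnorm(length(x), sd = noise_frac * s),
        `wavelet-highpass` = wavelet_detail(x))
    }
    views[[i]] <- list(neuron = i, window1 = w1, window2 = w2,
                       overlap = ov, tags = c(a1, a2),
                       x1 = apply_aug(x1, a1), x2 = apply_aug(x2, a2))
    pos[[i]] <- data.frame(neuron = i, timestamp = ov)
  }
  positives <- do.call(rbind, pos)
  n_pos <- nrow(positives)
  # negatives: other timestamp (same neuron) or other neuron (same
  # timestamp), exactly one per positive
  other_t <- vapply(positives$timestamp, function(t) {
    tt <- sample.int(Tn, 1)
    if (tt == t) (tt %% Tn) + 1L else tt
  }, integer(1))
  other_n <- vapply(positives$neuron, function(nn) {
    if (N == 1) return(nn)
    m <- sample.int(N, 1)
    if (m == nn) (m %% N) + 1L else m
  }, integer(1))
  use_t <- stats::runif(n_pos) < 0.5 | N == 1
  negatives <- data.frame(
    neuron = ifelse(use_t, positives$neuron, other_n),
    timestamp = ifelse(use_t, other_t, positives$timestamp))
  list(views = views, positives = positives, negatives = negatives)
}

## --- dilated residual encoder -------------------------------------------

enc_init <- function(hidden = 32, out = 64, blocks = 10, k = 3) {
  # small output gain keeps initial dot-product similarities O(1) so the
  # contrastive softmax is not saturated at the start of training
  p <- list(proj = dense_init(1, hidden), out = dense_init(hidden, out,
                                                           gain = 0.1))
  for (b in seq_len(blocks)) {
    p[[paste0("b", b, "c1")]] <- conv1d_init(k, hidden, hidden)
    p[[paste0("b", b, "c2")]] <- conv1d_init(k, hidden, hidden)
  }
  p$blocks <- blocks
  p
}

#' Encode traces into latent sequences
#'
#' Input projection, optional timestamp masking (training only: masked
#' timestamps have their latent vector zeroed), ten dilated residual
#' convolution blocks (kernel 3, dilation 2^(b-1)), and a per-timestep
#' output projection. The receptive field after ten blocks exceeds
#' 2^10 - 1 frames.
#'
#' @param params encoder parameters from `enc_init()` (internal) or a
#'   trained `scn_encoder$params`.
#' @param X matrix \[B x T\] of traces (or \[B x T x 1\] array).
#' @param mask optional 0/1 matrix \[B x T\]; 0 zeroes the latent.
#' @param keep_cache keep forward caches for backprop.
#' @return list with `Z` (\[B x T x D\]) and (optionally) `cache`.
#' @export
encode_traces <- function(params, X, mask = NULL, keep_cache = FALSE) {
  if (length(dim(X)) == 2) X <- array(X, c(nrow(X), ncol(X), 1))
  d <- dim(X)
  proj <- tensor_mat(X, params$proj$W)
  proj <- sweep(proj, 3, params$proj$b, `+`)
  if (!is.null(mask)) {
    mk <- array(rep(as.numeric(mask), dim(proj)[3]), dim(proj))
    proj <- proj * mk
  }
  h <- proj
  caches <- list()
  for (b in seq_len(params$blocks)) {
    dil <- 2^(b - 1)
    f1 <- conv1d_forward(params[[paste0("b", b, "c1")]], h, dil)
    r1 <- pmax(f1$Y, 0)
    f2 <- conv1d_forward(params[[paste0("b", b, "c2")]], r1, dil)
    hn <- f2$Y + h
    if (keep_cache) caches[[b]] <- list(f1 = f1, f2 = f2)
    h <- hn
  }
  Z <- tensor_mat(h, params$out$W)
  Z <- sweep(Z, 3, params$out$b, `+`)
  out <- list(Z = Z)
  if (keep_cache)
    out$cache <- list(X = X, mask = mask, caches = caches, h_final = h)
  out
}

# Backward through the encoder given dZ; returns parameter gradients.
encode_backward <- function(params, cache, dZ) {
  g <- list()
  d <- dim(dZ)
  h_final <- cache$h_final
  g$out.W <- crossprod(matrix(h_final, d[1] * d[2], dim(h_final)[3]),
                       matrix(dZ, d[1] * d[2], d[3]))
  g$out.b <- colSums(matrix(dZ, d[1] * d[2], d[3]))
  dh <- tensor_mat(dZ, t(params$out$W))
  for (b in rev(seq_len(params$blocks))) {
    cb <- cache$caches[[b]]
    b2 <- conv1d_backward(params[[paste0("b", b, "c2")]], cb$f2, dh)
    g[[paste0("b", b, "c2.W")]] <- b2$dW
    g[[paste0("b", b, "c2.b")]] <- b2$db
    dr1 <- b2$dX * (cb$f1$Y > 0)
    b1 <- conv1d_backward(params[[paste0("b", b, "c1")]], cb$f1, dr1)
    g[[paste0("b", b, "c1.W")]] <- b1$dW
    g[[paste0("b", b, "c1.b")]] <- b1$db
    dh <- dh + b1$dX     # residual skip
  }
  if (!is.null(cache$mask)) {
    mk <- array(rep(as.numeric(cache$mask), dim(dh)[3]), dim(dh))
    dh <- dh * mk
  }
  X <- cache$X
  dm <- dim(X)
  g$proj.W <- crossprod(matrix(X, dm[1] * dm[2], dm[3]),
                        matrix(dh, dm[1] * dm[2], dim(dh)[3]))
  g$proj.b <- colSums(matrix(dh, dm[1] * dm[2], dim(dh)[3]))
  g
}

## --- hierarchical dual contrastive loss ---------------------------------

# Dual contrastive loss at one scale. z1, z2: [B x T x D] aligned latents.
# Returns loss and gradients.
dual_contrastive_level <- function(z1, z2, want_grad = TRUE) {
  d <- dim(z1)
  B <- d[1]; Tn <- d[2]; D <- d[3]
  dz1 <- array(0, d); dz2 <- array(0, d)
  # --- temporal: per sample, contrast timestamps ---
  lt <- 0
  if (Tn > 1) {
    for (b in seq_len(B)) {
      U <- matrix(z1[b, , ], Tn, D)
      V <- matrix(z2[b, , ], Tn, D)
      r <- .dual_ce(U, V, want_grad)
      lt <- lt + r$loss
      if (want_grad) {
        dz1[b, , ] <- dz1[b, , ] + r$dU
        dz2[b, , ] <- dz2[b, , ] + r$dV
      }
    }
    lt <- lt / B
    if (want_grad) { dz1 <- dz1 / B; dz2 <- dz2 / B }
  }
  # --- instance: per timestamp, contrast samples ---
  li <- 0
  di1 <- array(0, d); di2 <- array(0, d)
  if (B > 1) {
    for (t in seq_len(Tn)) {
      U <- matrix(z1[, t, ], B, D)
      V <- matrix(z2[, t, ], B, D)
      r <- .dual_ce(U, V, want_grad)
      li <- li + r$loss
      if (want_grad) {
        di1[, t, ] <- r$dU
        di2[, t, ] <- r$dV
      }
    }
    li <- li / Tn
    if (want_grad) { di1 <- di1 / Tn; di2 <- di2 / Tn }
  }
  active <- (Tn > 1) + (B > 1)
  if (active == 0) return(list(loss = 0, dz1 = dz1, dz2 = dz2,
                               temporal = 0, instance = 0))
  list(loss = (lt + li) / active,
       dz1 = (dz1 + di1) / active, dz2 = (dz2 + di2) / active,
       temporal = lt, instance = li)
}

# Symmetric InfoNCE over rows of U against [U (no diag), V]: row i's
# positive is V_i; candidates are all other rows of U plus all rows of V.
# Temperature 1, dot-product similarity. Returns mean loss and gradients.
.dual_ce <- function(U, V, want_grad = TRUE) {
  n <- nrow(U)
  one_dir <- function(U, V) {
    A <- tcrossprod(U)          # [n x n] within-view
    Bm <- tcrossprod(U, V)      # [n x n] cross-view; diag = positives
    L <- cbind(A, Bm)
    L[cbind(seq_len(n), seq_len(n))] <- -Inf   # exclude self within-view
    mx <- apply(L, 1, max)
    P <- exp(L - mx)
    P <- P / rowSums(P)
    idx <- cbind(seq_len(n), n + seq_len(n))
    loss <- -mean(log(pmax(P[idx], 1e-300)))
    if (!want_grad) return(list(loss = loss))
    G <- P
    G[idx] <- G[idx] - 1
    G <- G / n
    GA <- G[, seq_len(n), drop = FALSE]
    GA[cbind(seq_len(n), seq_len(n))] <- 0
    GB <- G[, n + seq_len(n), drop = FALSE]
    dU <- GA %*% U + t(GA) %*% U + GB %*% V
    dV <- t(GB) %*% U
    list(loss = loss, dU = dU, dV = dV)
  }
  r1 <- one_dir(U, V)
  r2 <- one_dir(V, U)
  if (!want_grad) return(list(loss = (r1$loss + r2$loss) / 2))
  list(loss = (r1$loss + r2$loss) / 2,
       dU = (r1$dU + r2$dV) / 2,
       dV = (r1$dV + r2$dU) / 2)
}

# Max-pool time by 2 with argmax bookkeeping.
.pool2 <- function(z) {
  d <- dim(z)
  Th <- d[2] %/% 2
  z1 <- z[, seq(1, 2 * Th, by = 2), , drop = FALSE]
  z2 <- z[, seq(2, 2 * Th, by = 2), , drop = FALSE]
  take2 <- z2 > z1
  out <- z1
  out[take2] <- z2[take2]
  list(z = out, take2 = take2, Tin = d[2])
}

.pool2_back <- function(dz, pool) {
  d <- dim(dz)
  Th <- d[2]
  out <- array(0, c(d[1], pool$Tin, d[3]))
  d1 <- dz; d1[pool$take2] <- 0
  d2 <- dz; d2[!pool$take2] <- 0
  out[, seq(1, 2 * Th, by = 2), ] <- d1
  out[, seq(2, 2 * Th, by = 2), ] <- d2
  out
}

#' Hierarchical temporal + instance contrastive loss
#'
#' At each pyramid level (time max-pooled by 2 between levels) computes a
#' temporal InfoNCE term (same neuron, same timestamp across views vs
#' other timestamps) and an instance-wise term (same timestamp across
#' neurons), dot-product similarity at temperature 1; the total is the
#' mean over levels.
#'
#' @param z1,z2 aligned latent arrays \[B x T x D\] (overlap region).
#' @param want_grad also return gradients.
#' @return list with `loss`, per-level breakdown, and (if requested)
#'   `dz1`, `dz2`.
#' @export
hierarchical_contrastive_loss <- function(z1, z2, want_grad = TRUE) {
  stopifnot(length(dim(z1)) == 3, all(dim(z1) == dim(z2)))
  if (dim(z1)[2] < 1) stop("empty overlap between views")
  levels <- list()
  pools1 <- list(); pools2 <- list()
  cur1 <- z1; cur2 <- z2
  lv <- 0
  total <- 0
  grads <- list()
  repeat {
    lv <- lv + 1
    r <- dual_contrastive_level(cur1, cur2, want_grad)
    levels[[lv]] <- c(loss = r$loss, temporal = r$temporal,
                      instance = r$instance)
    total <- total + r$loss
    if (want_grad) grads[[lv]] <- list(dz1 = r$dz1, dz2 = r$dz2)
    if (dim(cur1)[2] <= 1) break
    p1 <- .pool2(cur1); p2 <- .pool2(cur2)
    pools1[[lv]] <- p1; pools2[[lv]] <- p2
    cur1 <- p1$z; cur2 <- p2$z
  }
  n_lv <- lv
  out <- list(loss = total / n_lv,
              levels = do.call(rbind, levels))
  if (want_grad) {
    # push each level's gradient back down through the pooling chain
    dz1 <- grads[[n_lv]]$dz1; dz2 <- grads[[n_lv]]$dz2
    for (l in rev(seq_len(n_lv - 1))) {
      dz1 <- .pool2_back(dz1, pools1[[l]])
      dz2 <- .pool2_back(dz2, pools2[[l]])
      dz1 <- dz1 + grads[[l]]$dz1
      dz2 <- dz2 + grads[[l]]$dz2
    }
    out$dz1 <- dz1 / n_lv
    out$dz2 <- dz2 / n_lv
  }
  out
}

#' Train the contrastive encoder and extract neuron representations
#'
#' Optimizes the hierarchical dual contrastive loss over random
#' overlapping crop pairs (timestamp masking active during training) with
#' Adam, until the relative loss change falls below `tol` or `max_iter`
#' iterations. The final per-neuron representation is the time-axis max
#' pooling of the unmasked encoding of the full series.
#'
#' @param series matrix \[N x T'\] (e.g. z-scored per-session dF/F
#'   concatenated over sessions) or an `scn_dataset`.
#' @param hidden,out_dim encoder widths.
#' @param max_iter iteration cap.
#' @param min_iter iterations before the convergence test applies.
#' @param tol relative loss-change convergence threshold.
#' @param lr Adam learning rate.
#' @param max_train_length crops are further cropped to this length for
#'   training cost control.
#' @param seed RNG seed.
#' @return `scn_encoder` with `params`, `representations` (\[N x D\]),
#'   `loss_curve`, `converged`.
#' @export
train_encoder <- function(series, hidden = 32, out_dim = 64, max_iter = 30,
                          min_iter = 8, tol = 1e-3, lr = 1e-3,
                          max_train_length = 300, seed = 0) {
  if (inherits(series, "scn_dataset")) series <- dataset_series(series)
  stopifnot(is.matrix(series))
  N <- nrow(series); Tn <- ncol(series)
  if (N < 2) stop("need at least 2 neurons")
  with_seed(seed, {
    p <- enc_init(hidden, out_dim)
    flat_names <- setdiff(names(p), "blocks")
    fl <- list()
    for (nm in flat_names) {
      fl[[paste0(nm, ".W")]] <- p[[nm]]$W
      fl[[paste0(nm, ".b")]] <- p[[nm]]$b
    }
    st <- adam_init(fl)
    unflat <- function(fl) {
      q <- list(blocks = p$blocks)
      for (nm in flat_names)
        q[[nm]] <- list(W = fl[[paste0(nm, ".W")]],
                        b = fl[[paste0(nm, ".b")]],
                        k = if (!is.null(p[[nm]]$k)) p[[nm]]$k else NULL)
      q
    }
    loss_curve <- numeric(0)
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      # two overlapping random crops shared across the batch
      L <- min(Tn, max_train_length)
      lo <- sample.int(Tn - L + 1L, 1)
      win <- lo:(lo + L - 1L)
      c1 <- sort(sample.int(L, 2)); c2 <- sort(sample.int(L, 2))
      # force substantial windows with overlap
      a1 <- 1L; b1 <- max(c1[2], L %/% 2 + 1L)
      a2 <- min(c2[1], L %/% 2); b2 <- L
      w1 <- win[a1:b1]; w2 <- win[a2:b2]
      ov <- intersect(w1, w2)
      X1 <- series[, w1, drop = FALSE]
      X2 <- series[, w2, drop = FALSE]
      m1 <- matrix(timestamp_mask(N * length(w1)), N)
      m2 <- matrix(timestamp_mask(N * length(w2)), N)
      q <- unflat(fl)
      e1 <- encode_traces(q, X1, mask = m1, keep_cache = TRUE)
      e2 <- encode_traces(q, X2, mask = m2, keep_cache = TRUE)
      i1 <- match(ov, w1); i2 <- match(ov, w2)
      hl <- hierarchical_contrastive_loss(
        e1$Z[, i1, , drop = FALSE], e2$Z[, i2, , drop = FALSE])
      if (!is.finite(hl$loss))
        stop("contrastive training diverged (NaN loss) at seed ", seed)
      dZ1 <- array(0, dim(e1$Z)); dZ1[, i1, ] <- hl$dz1
      dZ2 <- array(0, dim(e2$Z)); dZ2[, i2, ] <- hl$dz2
      g1 <- encode_backward(q, e1$cache, dZ1)
      g2 <- encode_backward(q, e2$cache, dZ2)
      g <- g1
      for (nm in names(g2)) g[[nm]] <- g[[nm]] + g2[[nm]]
      upd <- adam_step(fl, g, st, lr)
      fl <- upd$params; st <- upd$state
      loss_curve <- c(loss_curve, hl$loss)
      if (it >= min_iter) {
        rel <- abs(loss_curve[it] - loss_curve[it - 1]) /
          max(abs(loss_curve[it - 1]), 1e-12)
        if (rel < tol) { converged <- TRUE; break }
      }
    }
    q <- unflat(fl)
    reps <- representations_from(q, series)
    res <- list(params = q, representations = reps,
                loss_curve = loss_curve, converged = converged,
                hidden = hidden, out_dim = out_dim)
    class(res) <- "scn_encoder"
    res
  })
}

# Encode a full series (chunked over neurons) and max-pool over time.
representations_from <- function(params, series) {
  N <- nrow(series)
  D <- ncol(params$out$W)
  reps <- matrix(0, N, D)
  chunk <- max(1L, floor(4e6 / ncol(series) / 64))
  for (lo in seq(1, N, by = chunk)) {
    hi <- min(N, lo + chunk - 1L)
    Z <- encode_traces(params, series[lo:hi, , drop = FALSE])$Z
    reps[lo:hi, ] <- max_pool_time(Z)$pool
  }
  reps
}

#' Concatenated per-neuron dF/F series of a dataset
#'
#' By default sessions are concatenated as raw dF/F, preserving the
#' absolute amplitude differences (and the 12-h mode cycle) that
#' distinguish functional subtypes; `"session_z"` z-scores each session
#' trace first (the time-decoder convention).
#'
#' @param dataset an `scn_dataset`.
#' @param normalize `"none"` or `"session_z"`.
#' @return matrix \[N x S*T\].
#' @export
dataset_series <- function(dataset, normalize = c("none", "session_z")) {
  normalize <- match.arg(normalize)
  d <- dim(dataset$fluorescence)
  do.call(cbind, lapply(seq_len(d[2]), function(s) {
    m <- matrix(session_dff(dataset, s), d[1])
    if (normalize == "session_z") zscore_rows(m) else m
  }))
}
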