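## Per-neuron contribution coefficients to time prediction. The dataset is
## transformed into 24 all-neuron samples (one per hour); a slimmed-down
## predictor with 2-channel convolutional layers is trained to 100%
## accuracy on them, and integrated gradients from a zero baseline assign
## each neuron's trace its contribution to the predicted hour.

attr_init <- function(n_time, n_class, ch = 2, k = 7) {
  list(c1 = conv1d_init(k, 1, ch), c2 = conv1d_init(k, ch, ch),
       c3 = conv1d_init(k, ch, ch),
       fc = dense_init(n_time * ch, n_class))
}

# Forward over samples; X is [Bs x N x T] (Bs samples of N neurons).
# Neuron pooling is by mean AFTER the nonlinear conv stack, so per-neuron
# gradients are informative.
attr_forward <- function(p, X) {
  ds <- dim(X)
  Bs <- ds[1]; N <- ds[2]; Tn <- ds[3]
  Xr <- array(aperm(X, c(2, 1, 3)), c(N * Bs, Tn, 1)) # rows: neuron-within-sample
  f1 <- conv1d_forward(p$c1, Xr); h1 <- pmax(f1$Y, 0)
  f2 <- conv1d_forward(p$c2, h1); h2 <- pmax(f2$Y, 0)
  f3 <- conv1d_forward(p$c3, h2)
  a <- f3$Y + h1
  h3 <- pmax(a, 0)
  ch <- dim(h3)[3]
  # mean over neurons within each sample -> [Bs x (T*ch)]
  Hm <- matrix(h3, N * Bs, Tn * ch)
  grp <- rep(seq_len(Bs), each = N)
  Z <- rowsum(Hm, grp) / N
  fc <- dense_forward(p$fc, Z)
  list(logits = fc$Y,
       cache = list(Xr = Xr, f1 = f1, f2 = f2, f3 = f3, a = a, h3 = h3,
                    Z = Z, fc = fc, Bs = Bs, N = N, Tn = Tn, ch = ch))
}

attr_backward <- function(p, cache, dlogits, want_input_grad = FALSE) {
  g <- list()
  db <- dense_backward(p$fc, cache$fc, dlogits)
  g$fc.W <- db$dW; g$fc.b <- db$db
  N <- cache$N; Bs <- cache$Bs; Tn <- cache$Tn; ch <- cache$ch
  dh3 <- array(db$dX[rep(seq_len(Bs), each = N), ] / N,
               c(N * Bs, Tn, ch))
  da <- dh3 * (cache$a > 0)
  b3 <- conv1d_backward(p$c3, cache$f3, da)
  g$c3.W <- b3$dW; g$c3.b <- b3$db
  da2 <- b3$dX * (cache$f2$Y > 0)
  b2 <- conv1d_backward(p$c2, cache$f2, da2)
  g$c2.W <- b2$dW; g$c2.b <- b2$db
  da1 <- (b2$dX + da) * (cache$f1$Y > 0)
  b1 <- conv1d_backward(p$c1, cache$f1, da1)
  g$c1.W <- b1$dW; g$c1.b <- b1$db
  if (want_input_grad)
    g$dX <- aperm(array(b1$dX, c(N, Bs, Tn)), c(2, 1, 3))
  g
}

attr_flatten <- function(p) {
  list(c1.W = p$c1$W, c1.b = p$c1$b, c2.W = p$c2$W, c2.b = p$c2$b,
       c3.W = p$c3$W, c3.b = p$c3$b, fc.W = p$fc$W, fc.b = p$fc$b)
}

attr_unflatten <- function(fl, k = 7) {
  list(c1 = list(W = fl$c1.W, b = fl$c1.b, k = k),
       c2 = list(W = fl$c2.W, b = fl$c2.b, k = k),
       c3 = list(W = fl$c3.W, b = fl$c3.b, k = k),
       fc = list(W = fl$fc.W, b = fl$fc.b))
}

#' Train the all-neuron attribution network
#'
#' One sample per hour (all neurons' z-scored traces); convolutional
#' channels reduced to 2. Training continues until the 24 hourly samples
#' are classified perfectly (a precondition for attribution) or `max_epochs`
#' is reached.
#'
#' @param dataset an `scn_dataset`.
#' @param max_epochs training cap.
#' @param lr Adam learning rate.
#' @param seed RNG seed.
#' @return `scn_attr_net` with `params`, `X` (the \[S x N x T\] training
#'   tensor), `train_acc`, `epochs_run`.
#' @export
train_attribution_net <- function(dataset, max_epochs = 800, lr = 3e-3,
                                  seed = 0) {
  stopifnot(inherits(dataset, "scn_dataset"))
  d <- dim(dataset$fluorescence)
  X <- array(0, c(d[2], d[1], d[3]))
  for (s in seq_len(d[2]))
    X[s, , ] <- zscore_rows(matrix(session_dff(dataset, s), d[1]))
  y <- seq_len(d[2])
  with_seed(seed, {
    p <- attr_init(d[3], d[2])
    fl <- attr_flatten(p)
    st <- adam_init(fl)
    acc <- 0; ep <- 0
    while (ep < max_epochs) {
      ep <- ep + 1
      p <- attr_unflatten(fl)
      fw <- attr_forward(p, X)
      ce <- softmax_xent(fw$logits, y)
      acc <- mean(max.col(fw$logits) == y)
      if (acc >= 1 && ce$loss < 0.05) break
      g <- attr_backward(p, fw$cache, ce$grad)
      upd <- adam_step(fl, g, st, lr)
      fl <- upd$params; st <- upd$state
    }
    res <- list(params = attr_unflatten(fl), X = X, train_acc = acc,
                epochs_run = ep, n_class = d[2])
    class(res) <- "scn_attr_net"
    res
  })
}

#' Integrated gradients of a target logit from a zero baseline
#'
#' Midpoint-Riemann path integral with `M` steps: attribution =
#' x * mean_k grad f_c(a_k x) over a_k = (k - 1/2)/M. By the completeness
#' property the attributions sum approximately to f_c(x) - f_c(0).
#'
#' @param net an `scn_attr_net`.
#' @param sample_idx hour sample (1-based) to attribute.
#' @param target target class (default: the sample's own hour).
#' @param M number of path steps.
#' @return list with `attribution` (\[N x T\]), `completeness_gap`
#'   (relative error of the completeness identity), `f_x`, `f_0`.
#' @export
integrated_gradients <- function(net, sample_idx, target = sample_idx,
                                 M = 64) {
  x <- net$X[sample_idx, , , drop = FALSE]
  N <- dim(x)[2]; Tn <- dim(x)[3]
  alphas <- (seq_len(M) - 0.5) / M
  grad_sum <- matrix(0, N, Tn)
  onehot <- matrix(0, 1, net$n_class); onehot[1, target] <- 1
  for (a in alphas) {
    fw <- attr_forward(net$params, x * a)
    g <- attr_backward(net$params, fw$cache, onehot,
                       want_input_grad = TRUE)
    grad_sum <- grad_sum + matrix(g$dX[1, , ], N, Tn)
  }
  attribution <- matrix(x[1, , ], N, Tn) * grad_sum / M
  f_x <- attr_forward(net$params, x)$logits[1, target]
  f_0 <- attr_forward(net$params, x * 0)$logits[1, target]
  gap <- abs(sum(attribution) - (f_x - f_0)) / max(abs(f_x - f_0), 1e-12)
  list(attribution = attribution, completeness_gap = gap,
       f_x = f_x, f_0 = f_0)
}

#' Per-neuron contribution coefficients to hourly time prediction
#'
#' Trains the 2-channel all-neuron network (refusing attribution if it
#' does not reach 100% training accuracy), computes integrated-gradients
#' attributions for every hour, aggregates them to one coefficient per
#' neuron and hour (mean absolute attribution over the time axis), min-max
#' normalizes within each hour, fits a Gaussian to each hour's coefficient
#' histogram, and reports the 24-h average per neuron with its 5%-95%
#' spread.
#'
#' @param dataset an `scn_dataset`.
#' @param M integrated-gradients steps.
#' @param n_bins histogram bins for the Gaussian fits.
#' @param ... passed to [train_attribution_net()].
#' @return `scn_attribution` list: `contribution` (\[N x S\] in \[0,1\]),
#'   `time_avg`, `spread` (95th - 5th percentile of `time_avg`),
#'   `gaussian_fit` (per-hour mu, sigma, R2), `completeness_gaps`, `net`.
#' @export
contribution_coefficients <- function(dataset, M = 64, n_bins = 30, ...) {
  net <- train_attribution_net(dataset, ...)
  if (net$train_acc < 1)
    stop("attribution refused: network below 100% training accuracy")
  S <- net$n_class
  N <- dim(net$X)[2]
  contrib <- matrix(NA_real_, N, S)
  gaps <- numeric(S)
  for (s in seq_len(S)) {
    ig <- integrated_gradients(net, s, M = M)
    co <- rowMeans(abs(ig$attribution))
    rng <- range(co)
    contrib[, s] <- if (diff(rng) > 0) (co - rng[1]) / diff(rng)
                    else co * 0
    gaps[s] <- ig$completeness_gap
  }
  fits <- do.call(rbind, lapply(seq_len(S), function(s)
    gaussian_hist_fit(contrib[, s], n_bins)))
  time_avg <- rowMeans(contrib)
  qs <- stats::quantile(time_avg, c(0.05, 0.95), names = FALSE)
  res <- list(contribution = contrib, time_avg = time_avg,
              spread = qs[2] - qs[1], gaussian_fit = fits,
              completeness_gaps = gaps, net = net)
  class(res) <- "scn_attribution"
  res
}

# Moment-based Gaussian fit to a histogram with R^2 of the fitted density
# against the empirical bin densities.
gaussian_hist_fit <- function(x, n_bins = 30) {
  h <- graphics::hist(x, breaks = n_bins, plot = FALSE)
  mu <- mean(x); sigma <- stats::sd(x)
  yhat <- stats::dnorm(h$mids, mu, sigma)
  ss_res <- sum((h$density - yhat)^2)
  ss_tot <- sum((h$density - mean(h$density))^2)
  data.frame(mu = mu, sigma = sigma,
             R2 = if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_)
}
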