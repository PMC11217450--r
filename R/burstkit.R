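## Burst-level analysis: K-means classification on (duration, amplitude)
## with gap-statistic model selection, class-switching dynamics, and
## population burst statistics.

#' Cluster bursts into classes by duration and amplitude
#'
#' Z-scores (duration, amplitude), runs K-means (k-means++-like multiple
#' restarts via `nstart`) for each candidate K, and selects K by the gap
#' statistic with B uniform reference datasets and the standard one-SE
#' rule. Degenerate inputs (all events identical) return K = 1.
#'
#' @param events data.frame with columns `duration_s` and `amplitude`.
#' @param K_range candidate class counts (contiguous from 1 or higher).
#' @param B number of uniform reference datasets for the gap statistic.
#' @param nstart K-means restarts per K.
#' @param seed RNG seed for restarts and references.
#' @return `scn_burst_classes` object: `K`, `centroids` (original units),
#'   `assignments`, `gap_curve` (K, gap, SE), `scale` (z-scoring params).
#' @export
cluster_bursts <- function(events, K_range = 1:8, B = 50, nstart = 20,
                           seed = 0) {
  stopifnot(all(c("duration_s", "amplitude") %in% names(events)))
  x <- cbind(events$duration_s, events$amplitude)
  if (nrow(x) < max(K_range)) stop("need at least max(K_range) events")
  ctr <- colMeans(x); sc <- apply(x, 2, stats::sd)
  degenerate <- any(sc < 1e-12) && all(sc < 1e-12)
  if (degenerate || nrow(unique(x)) == 1) {
    res <- list(K = 1L, centroids = matrix(ctr, 1,
                  dimnames = list(NULL, c("duration_s", "amplitude"))),
                assignments = rep(1L, nrow(x)),
                gap_curve = data.frame(K = 1L, gap = 0, SE = 0),
                scale = list(center = ctr, sd = pmax(sc, 1)))
    class(res) <- "scn_burst_classes"
    return(res)
  }
  sc <- pmax(sc, 1e-12)
  z <- scale(x, center = ctr, scale = sc)
  with_seed(seed, {
    kmax <- max(K_range)
    gap <- cluster::clusGap(z, FUNcluster = function(xx, k)
      stats::kmeans(xx, k, nstart = nstart, iter.max = 50), K.max = kmax,
      B = B, verbose = FALSE)
    tab <- gap$Tab
    sel_all <- cluster::maxSE(tab[, "gap"], tab[, "SE.sim"],
                              method = "Tibs2001SEmax")
    # restrict to the requested range, keeping the one-SE choice if inside
    K <- if (sel_all %in% K_range) sel_all else
      K_range[which.max(tab[K_range, "gap"])]
    km <- stats::kmeans(z, K, nstart = nstart, iter.max = 50)
    centroids <- sweep(sweep(km$centers, 2, sc, `*`), 2, ctr, `+`)
    colnames(centroids) <- c("duration_s", "amplitude")
    res <- list(K = as.integer(K), centroids = centroids,
                assignments = as.integer(km$cluster),
                gap_curve = data.frame(K = seq_len(kmax),
                                       gap = tab[, "gap"],
                                       SE = tab[, "SE.sim"]),
                scale = list(center = ctr, sd = sc))
    class(res) <- "scn_burst_classes"
    res
  })
}

#' @export
print.scn_burst_classes <- function(x, ...) {
  cat(sprintf("Burst class model: K = %d (%d events)\n", x$K,
              length(x$assignments)))
  print(round(x$centroids, 2))
  invisible(x)
}

#' Class-switching matrix of consecutive bursts
#'
#' Counts class transitions between consecutive bursts of the same neuron
#' (ordered by session then onset) and row-normalizes them; also reports
#' the net flow per class pair and the mean signed duration change per
#' transition (negative = drift toward shorter-duration classes).
#'
#' @param events data.frame with `neuron`, `class`, `onset_s`, optionally
#'   `session` and `duration_s`.
#' @param K number of classes (default: max class id observed).
#' @return list with `P` (row-stochastic \[K x K\]), `counts`, `net_flow`
#'   (antisymmetric count differences), `duration_drift`.
#' @export
switching_matrix <- function(events, K = NULL) {
  stopifnot(all(c("neuron", "class", "onset_s") %in% names(events)))
  K <- K %||% max(events$class)
  ses <- if (!is.null(events$session)) events$session
         else rep(0L, nrow(events))
  ord <- order(events$neuron, ses, events$onset_s)
  ev <- events[ord, , drop = FALSE]
  same <- ev$neuron[-1] == ev$neuron[-nrow(ev)]
  from <- ev$class[-nrow(ev)][same]
  to <- ev$class[-1][same]
  if (length(from) == 0) stop("no same-neuron transitions available")
  counts <- matrix(0, K, K)
  for (i in seq_along(from)) counts[from[i], to[i]] <-
    counts[from[i], to[i]] + 1
  P <- counts / pmax(rowSums(counts), 1)
  empty <- rowSums(counts) == 0
  P[empty, ] <- NA_real_
  drift <- if (!is.null(ev$duration_s)) {
    d_from <- ev$duration_s[-nrow(ev)][same]
    d_to <- ev$duration_s[-1][same]
    mean(d_to - d_from)
  } else NA_real_
  list(P = P, counts = counts, net_flow = counts - t(counts),
       duration_drift = drift, n_transitions = length(from))
}

#' Population burst statistics
#'
#' 5%/95% percentiles of burst duration and of per-neuron burst rate, and
#' a maximum-likelihood exponential fit to the inter-burst intervals
#' (within neuron and session), with a Kolmogorov-Smirnov fit statistic.
#'
#' @param events data.frame with `neuron`, `onset_s`, `duration_s`,
#'   optionally `session`.
#' @param total_s total recorded seconds per neuron (for rates).
#' @return list with `duration_q` (5%/95%), `rate_q`, `rates` (per
#'   neuron), `interval_fit` (rate lambda, KS statistic) or `NULL` when
#'   fewer than 20 events are available (with a warning).
#' @export
burst_statistics <- function(events, total_s) {
  if (nrow(events) < 20) {
    warning("fewer than 20 events: skipping interval fit")
    fit <- NULL
  }
  duration_q <- stats::quantile(events$duration_s, c(0.05, 0.95),
                                names = FALSE)
  n_per <- table(events$neuron)
  rates <- as.numeric(n_per) / total_s
  rate_q <- stats::quantile(rates, c(0.05, 0.95), names = FALSE)
  fit <- NULL
  if (nrow(events) >= 20) {
    ses <- if (!is.null(events$session)) events$session
           else rep(1L, nrow(events))
    ord <- order(events$neuron, ses, events$onset_s)
    ev <- events[ord, , drop = FALSE]
    ses <- ses[ord]
    same <- ev$neuron[-1] == ev$neuron[-nrow(ev)] &
            ses[-1] == ses[-length(ses)]
    iv <- (ev$onset_s[-1] - ev$onset_s[-nrow(ev)])[same]
    iv <- iv[iv > 0]
    if (length(iv) >= 5) {
      lambda <- 1 / mean(iv)                       # ML estimator
      ks <- suppressWarnings(stats::ks.test(iv, "pexp", rate = lambda))
      fit <- list(lambda = lambda, ks_stat = unname(ks$statistic),
                  n_intervals = length(iv))
    }
  }
  list(duration_q = duration_q, rate_q = rate_q, rates = rates,
       interval_fit = fit)
}
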