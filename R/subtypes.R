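## Subtype discovery on learned representations: K-means clustering with
## t-SNE and spatial views, partition-agreement measures, and robustness
## subsampling (spatial, temporal, single-sided, segment-wise).

#' Farthest point sampling
#'
#' Greedy subsampling that repeatedly picks the point maximizing the
#' minimum distance to the already chosen set.
#'
#' @param points numeric matrix \[n x d\].
#' @param k number of points to keep.
#' @param start index of the first point (default 1).
#' @return integer indices of the selected points, in selection order.
#' @export
farthest_point_sampling <- function(points, k, start = 1L) {
  points <- as.matrix(points)
  n <- nrow(points)
  stopifnot(k >= 1, k <= n)
  sel <- integer(k)
  sel[1] <- start
  mind <- sqrt(rowSums(sweep(points, 2, points[start, ])^2))
  if (k > 1) for (i in 2:k) {
    nxt <- which.max(mind)
    sel[i] <- nxt
    d <- sqrt(rowSums(sweep(points, 2, points[nxt, ])^2))
    mind <- pmin(mind, d)
  }
  sel
}

#' Adjusted mutual information between two partitions
#'
#' Chance-corrected (hypergeometric model, arithmetic normalization)
#' mutual information between two label vectors.
#'
#' @param a,b integer/factor label vectors of equal length.
#' @return AMI in (-1, 1\]; 1 means identical partitions.
#' @export
adjusted_mutual_info <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  n <- sum(tab)
  ai <- rowSums(tab); bj <- colSums(tab)
  pij <- tab / n
  nz <- tab > 0
  mi <- sum(pij[nz] * log(pij[nz] / (outer(ai, bj) / n^2)[nz]))
  ha <- -sum((ai / n) * log(ai / n))
  hb <- -sum((bj / n) * log(bj / n))
  emi <- 0
  for (i in seq_along(ai)) for (j in seq_along(bj)) {
    lo <- max(1, ai[i] + bj[j] - n)
    hi <- min(ai[i], bj[j])
    if (hi < lo) next
    nij <- lo:hi
    pr <- stats::dhyper(nij, bj[j], n - bj[j], ai[i])
    emi <- emi + sum(pr * (nij / n) * log(pmax(n * nij / (ai[i] * bj[j]),
                                               1e-300)))
  }
  denom <- (ha + hb) / 2 - emi
  if (abs(denom) < 1e-12) return(1)
  (mi - emi) / denom
}

#' Cluster neuron representations into functional subtypes
#'
#' K-means (fixed seed, multiple restarts) on learned representations for
#' each requested K, with a t-SNE view of the feature space.
#'
#' @param representations matrix \[N x D\] (or an `scn_encoder`).
#' @param K integer vector of cluster counts (default 2:5).
#' @param positions optional \[N x 3\] neuron positions for spatial maps.
#' @param nstart K-means restarts.
#' @param transform preprocessing of the representation matrix before
#'   K-means: `"rank"` (per-feature rank normalization, robust to the
#'   heavy-tailed max-pooled activations; the default), `"scale"`
#'   (z-score columns) or `"none"`.
#' @param tsne compute a 2-D t-SNE of the representations.
#' @param seed RNG seed.
#' @return `scn_subtypes`: `labels` (\[N x length(K)\] matrix, one column
#'   per K), `K`, `tsne` (\[N x 2\] or NULL), `positions`,
#'   `refinement_ami` (AMI between successive K columns).
#' @export
cluster_subtypes <- function(representations, K = 2:5, positions = NULL,
                             nstart = 20,
                             transform = c("rank", "scale", "none"),
                             tsne = FALSE, seed = 0) {
  if (inherits(representations, "scn_encoder"))
    representations <- representations$representations
  transform <- match.arg(transform)
  X <- as.matrix(representations)
  if (transform == "rank") X <- apply(X, 2, rank)
  if (transform %in% c("rank", "scale")) {
    sds <- apply(X, 2, stats::sd)
    X <- scale(X[, sds > 1e-12, drop = FALSE])
  }
  N <- nrow(X)
  if (any(K > N)) stop("K exceeds the number of neurons")
  labels <- matrix(NA_integer_, N, length(K),
                   dimnames = list(NULL, paste0("K", K)))
  with_seed(seed, {
    for (j in seq_along(K)) {
      labels[, j] <- if (K[j] == 1) rep(1L, N) else
        as.integer(stats::kmeans(X, K[j], nstart = nstart,
                                 iter.max = 100)$cluster)
    }
    co <- if (tsne && N >= 4) tsne_embed(X, seed = seed) else NULL
    ref <- if (length(K) > 1)
      vapply(seq_len(length(K) - 1), function(j)
        adjusted_mutual_info(labels[, j], labels[, j + 1]), numeric(1))
    else numeric(0)
    res <- list(labels = labels, K = K, tsne = co, positions = positions,
                refinement_ami = ref)
    class(res) <- "scn_subtypes"
    res
  })
}

#' Robustness of the subtype map under subsampling
#'
#' Re-runs the encoder + clustering pipeline on a degraded copy of the
#' data and reports the adjusted Rand index between the resulting labels
#' and the full-data labels. Modes: `"spatial_fps"` (keep 50% of neurons
#' by farthest point sampling), `"temporal_decimate"` (drop every other
#' frame), `"left_only"`, `"right_only"` (one nucleus), `"left_vs_right"`
#' (cluster each side independently, compare on mirrored pairs),
#' `"segments_8h"` (three 8-h session blocks, each clustered separately
#' and compared with the full labels).
#'
#' @param dataset an `scn_dataset`.
#' @param mode one of the modes above.
#' @param K cluster count for the comparison.
#' @param full optional precomputed full-data result from
#'   [train_encoder()] + [cluster_subtypes()] (list with `labels`), to
#'   avoid re-training.
#' @param encoder_args list of arguments passed to [train_encoder()].
#' @param seed RNG seed.
#' @return list with `mode`, `ari` (or per-segment ARIs), `labels`,
#'   `subset` (neuron indices used).
#' @export
robustness_subsample <- function(dataset, mode, K = 3, full = NULL,
                                 encoder_args = list(), seed = 0) {
  stopifnot(inherits(dataset, "scn_dataset"))
  modes <- c("spatial_fps", "temporal_decimate", "left_only", "right_only",
             "left_vs_right", "segments_8h")
  if (!mode %in% modes) stop("unknown robustness mode: ", mode)
  series <- dataset_series(dataset)
  N <- nrow(series)
  run <- function(ser, sd_off = 1) {
    enc <- do.call(train_encoder,
                   c(list(series = ser, seed = seed + sd_off),
                     encoder_args))
    cluster_subtypes(enc$representations, K = K,
                     seed = seed)$labels[, 1]
  }
  if (is.null(full)) full <- list(labels = run(series, sd_off = 0))
  full_lab <- if (is.matrix(full$labels)) full$labels[, 1] else full$labels
  if (mode == "spatial_fps") {
    keep <- sort(farthest_point_sampling(dataset$positions,
                                         max(2L, floor(N / 2))))
    lab <- run(series[keep, , drop = FALSE])
    ari <- mclust::adjustedRandIndex(lab, full_lab[keep])
    return(list(mode = mode, ari = ari, labels = lab, subset = keep))
  }
  if (mode == "temporal_decimate") {
    lab <- run(series[, seq(1, ncol(series), by = 2), drop = FALSE])
    ari <- mclust::adjustedRandIndex(lab, full_lab)
    return(list(mode = mode, ari = ari, labels = lab, subset = seq_len(N)))
  }
  if (mode %in% c("left_only", "right_only")) {
    side <- sub("_only", "", mode)
    keep <- which(dataset$truth$side == side)
    lab <- run(series[keep, , drop = FALSE])
    ari <- mclust::adjustedRandIndex(lab, full_lab[keep])
    return(list(mode = mode, ari = ari, labels = lab, subset = keep))
  }
  if (mode == "left_vs_right") {
    left <- which(dataset$truth$side == "left")
    right <- which(dataset$truth$side == "right")
    lab_l <- run(series[left, , drop = FALSE], sd_off = 1)
    lab_r <- run(series[right, , drop = FALSE], sd_off = 2)
    # mirrored pairs: right neuron i's partner index lives in truth$pair
    partner <- dataset$truth$pair[right]
    ok <- !is.na(partner)
    ari <- mclust::adjustedRandIndex(lab_r[ok],
                                     lab_l[match(partner[ok], left)])
    return(list(mode = mode, ari = ari,
                labels = list(left = lab_l, right = lab_r),
                subset = list(left = left, right = right)))
  }
  # segments_8h
  S <- dim(dataset$fluorescence)[2]
  Tn <- dim(dataset$fluorescence)[3]
  n_seg <- 3
  per <- S %/% n_seg
  aris <- numeric(n_seg); labs <- vector("list", n_seg)
  for (g in seq_len(n_seg)) {
    cols <- ((g - 1) * per * Tn + 1):(g * per * Tn)
    labs[[g]] <- run(series[, cols, drop = FALSE], sd_off = g)
    aris[g] <- mclust::adjustedRandIndex(labs[[g]], full_lab)
  }
  list(mode = mode, ari = aris, labels = labs, subset = seq_len(N))
}
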