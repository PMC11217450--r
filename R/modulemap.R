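## Module-level statistics: amplitude and variance gradients across the
## concentric modules, within-module coupling strength via MIC, and
## module-specific time predictors with the same/cross-module accuracy
## matrix.

#' Per-module amplitude statistics and gradient test
#'
#' Computes each neuron's amplitude (session-mean dF/F averaged over
#' sessions), aggregates mean and across-neuron variance per module, and
#' tests for a monotone ordering of amplitude along the module sequence
#' (ventrolateral to dorsomedial band order) with a Spearman trend test.
#'
#' @param dataset an `scn_dataset`.
#' @param labels integer module labels covering all neurons (defaults to
#'   the planted truth).
#' @return list with `stats` (module, n_neurons, mean_amplitude,
#'   var_amplitude), `trend` (Spearman rho and p-value of neuron
#'   amplitude vs module index), `amplitude` (per neuron).
#' @export
module_stats <- function(dataset, labels = NULL) {
  stopifnot(inherits(dataset, "scn_dataset"))
  labels <- labels %||% dataset$truth$module
  d <- dim(dataset$fluorescence)
  if (length(labels) != d[1]) stop("labels must cover all neurons")
  if (any(tabulate(labels) == 0)) stop("empty module in labels")
  amp_session <- sapply(seq_len(d[2]), function(s)
    rowMeans(session_dff(dataset, s)))
  amplitude <- rowMeans(amp_session)
  ks <- sort(unique(labels))
  stats_df <- do.call(rbind, lapply(ks, function(k) {
    a <- amplitude[labels == k]
    data.frame(module = k, n_neurons = length(a), mean_amplitude = mean(a),
               var_amplitude = stats::var(a))
  }))
  tr <- suppressWarnings(
    stats::cor.test(as.numeric(labels), amplitude, method = "spearman"))
  list(stats = stats_df,
       trend = list(rho = unname(tr$estimate), p_value = tr$p.value),
       amplitude = amplitude)
}

#' Average within-module MIC coupling
#'
#' Samples random within-module neuron pairs, z-scores each session trace,
#' concatenates sessions, and computes the maximal information coefficient
#' per pair; reports the module average with SEM. Constant traces are
#' skipped.
#'
#' @param dataset an `scn_dataset`.
#' @param labels module labels (defaults to planted truth).
#' @param pairs_per_module random pairs sampled per module (capped).
#' @param max_points evenly subsample the concatenated series to at most
#'   this many time points before MIC (cost control).
#' @param seed RNG seed.
#' @return data.frame: module, n_pairs, mean_mic, sem_mic.
#' @export
module_mic <- function(dataset, labels = NULL, pairs_per_module = 100,
                       max_points = 2400, seed = 0) {
  stopifnot(inherits(dataset, "scn_dataset"))
  labels <- labels %||% dataset$truth$module
  pairs_per_module <- min(pairs_per_module, 500)
  series <- dataset_series(dataset)
  if (ncol(series) > max_points)
    series <- series[, round(seq(1, ncol(series), length.out = max_points)),
                     drop = FALSE]
  ks <- sort(unique(labels))
  with_seed(seed, {
    rows <- lapply(ks, function(k) {
      idx <- which(labels == k)
      if (length(idx) < 2) stop("module ", k, " has fewer than 2 neurons")
      vals <- numeric(0)
      for (p in seq_len(pairs_per_module)) {
        pr <- sample(idx, 2)
        m <- tryCatch(mic(series[pr[1], ], series[pr[2], ])$mic,
                      error = function(e) NA_real_)
        if (is.finite(m)) vals <- c(vals, m)
      }
      data.frame(module = k, n_pairs = length(vals), mean_mic = mean(vals),
                 sem_mic = stats::sd(vals) / sqrt(length(vals)))
    })
    do.call(rbind, rows)
  })
}

#' Same- and cross-module time-prediction accuracy matrix
#'
#' Trains one cohort-polling predictor per module using only that module's
#' neurons (6:1:3 split within the module) and evaluates every predictor
#' on every module's test-pool cohorts.
#'
#' @param dataset an `scn_dataset`.
#' @param labels module labels (defaults to planted truth).
#' @param cohort_size cohort size; shrunk with a warning for modules whose
#'   training pool is smaller.
#' @param trials evaluation cohorts per matrix cell.
#' @param seed RNG seed.
#' @param ... passed to [train_time_predictor()].
#' @return list with `accuracy` (\[K x K\]: row = training module,
#'   column = evaluation module), `chance` (1 / n_sessions),
#'   `predictors`.
#' @export
cross_module_eval <- function(dataset, labels = NULL, cohort_size = 100,
                              trials = 200, seed = 0, ...) {
  stopifnot(inherits(dataset, "scn_dataset"))
  labels <- labels %||% dataset$truth$module
  ks <- sort(unique(labels))
  K <- length(ks)
  pools <- lapply(ks, function(k) {
    idx <- which(labels == k)
    pp <- partition_neurons(length(idx), seed = seed)
    lapply(pp, function(v) idx[v])
  })
  acc <- matrix(NA_real_, K, K,
                dimnames = list(paste0("train_m", ks), paste0("eval_m", ks)))
  preds <- vector("list", K)
  for (i in seq_len(K)) {
    size_i <- cohort_size
    if (size_i > length(pools[[i]]$train)) {
      size_i <- length(pools[[i]]$train)
      warning("module ", ks[i], " smaller than cohort: shrinking to ",
              size_i)
    }
    preds[[i]] <- train_time_predictor(dataset, pools[[i]], size_i,
                                       seed = seed, ...)
    for (j in seq_len(K)) {
      size_j <- min(size_i, length(pools[[j]]$test))
      acc[i, j] <- cohort_accuracy(preds[[i]], dataset, pools[[j]]$test,
                                   size_j, trials, seed = seed + 7 * j)
    }
  }
  list(accuracy = acc, chance = 1 / dim(dataset$fluorescence)[2],
       predictors = preds)
}
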