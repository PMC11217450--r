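## Full synthetic dataset assembly: geometry + per-neuron specs + per-session
## traces with planted ground truth, plus optional image-stack rendering and
## plain-text container IO.

# Draw per-neuron generator specs (burst rate, baseline, mode boundary, F0).
draw_neuron_specs <- function(config, module) {
  n <- config$n_neurons
  s <- config$n_sessions
  rho <- config$module_rate_correlation %||% 0
  z <- stats::rnorm(n)
  if (rho > 0 && config$n_modules > 1) {
    # copula tilt: module position shifts the rate percentile
    zm <- stats::qnorm((module - 0.5) / config$n_modules)
    z <- rho * zm + sqrt(1 - rho^2) * z
  }
  rates <- stats::qlnorm(stats::pnorm(z), config$rate_lognorm$meanlog,
                         config$rate_lognorm$sdlog)
  mode_start <- (round(config$mode_start_hour +
                       stats::rnorm(n, sd = config$mode_jitter_sd))) %% s
  list(rate = rates,
       f0 = config$baseline_f0 * stats::runif(n, 0.8, 1.2),
       mode_start = as.integer(mode_start),
       baseline_amp = stats::runif(n, 0.04, 0.12),
       baseline_period = stats::runif(n, 100, 250),
       module = as.integer(module))
}

#' Generate a full synthetic SCN dataset with planted ground truth
#'
#' Runs the geometry generator and the per-session trace synthesizer for
#' every neuron and session, planting burst classes, state archetypes, H/L
#' activity modes, hour-specific population signatures, module-shared
#' coupling drives, and (optionally) a slow traveling hyperactivity wave.
#' All planted structure is logged in `truth`. Output is bit-identical for
#' a fixed `config$seed`.
#'
#' @param config an [synth_config()] object.
#' @return an object of class `scn_dataset`: list with
#'   `fluorescence` (array \[N x S x T\], arbitrary units), `positions`
#'   (\[N x 3\], um), `session_times` (CT hours), `hour_labels`
#'   (0-based session indices), `config`, and `truth` (module ids, per
#'   neuron-session states and modes, burst table, F0, signatures, mode
#'   boundaries, wave passage hours).
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "scn_synth_config"))
  n <- config$n_neurons; s <- config$n_sessions; nT <- config$frames_per_session
  if (as.double(n) * s * nT > config$max_elements)
    stop("refusing to generate: dataset exceeds max_elements")
  geo <- generate_geometry(config)
  with_seed(config$seed, {
    specs <- draw_neuron_specs(config, geo$module)
    n_sets <- if (config$module_specific_signatures) config$n_modules else 1L
    sig <- make_signature_waves(n_sets, s, nT)
    use_drive <- any(config$coupling_gradient > 0)
    drive <- if (use_drive) {
      d <- array(0, dim = c(config$n_modules, s, nT))
      for (m in seq_len(config$n_modules))
        for (h in seq_len(s)) d[m, h, ] <- ou_drive(nT)
      d
    } else NULL
    states <- matrix(sample.int(6, n * s, replace = TRUE,
                                prob = config$state_probs), n, s)
    # wave passage hour per neuron: projection along the propagation
    # direction from the entry point (most upstream neuron)
    pw <- config$pwha
    t_pass <- rep(NA_real_, n)
    if (isTRUE(pw$enabled)) {
      dir <- pw$direction / sqrt(sum(pw$direction^2))
      proj <- as.numeric(geo$positions %*% dir)
      t_pass <- pw$onset_hour + (proj - min(proj)) / pw$speed
    }
    fl <- array(NA_real_, dim = c(n, s, nT))
    modes <- matrix(NA_character_, n, s)
    burst_list <- vector("list", n * s)
    sig_group <- if (config$module_specific_signatures) geo$module
                 else rep(1L, n)
    for (i in seq_len(n)) {
      spec_i <- list(module = specs$module[i], rate = specs$rate[i],
                     f0 = specs$f0[i], mode_start = specs$mode_start[i],
                     baseline_amp = specs$baseline_amp[i],
                     baseline_period = specs$baseline_period[i],
                     class_weights = module_class_weights(config,
                                                          specs$module[i]))
      for (h in seq_len(s)) {
        out <- synthesize_session(
          spec_i, h - 1L, config, state = states[i, h],
          signature_wave = sig[sig_group[i], h, ],
          drive = if (use_drive) drive[specs$module[i], h, ] else NULL)
        dff <- out$dff
        if (isTRUE(pw$enabled)) {
          lvl <- pw$amplitude *
            exp(-((h - 1L) - t_pass[i])^2 / (2 * pw$width_h^2))
          if (lvl > 1e-4) dff <- dff + lvl
        }
        fl[i, h, ] <- specs$f0[i] * (1 + dff)
        modes[i, h] <- out$mode
        ev <- out$events
        if (nrow(ev) > 0) {
          ev$neuron <- i; ev$session <- h
          burst_list[[(i - 1L) * s + h]] <- ev
        }
      }
    }
    bursts <- do.call(rbind, burst_list[!vapply(burst_list, is.null,
                                                logical(1))])
    if (is.null(bursts))
      bursts <- data.frame(class = integer(), onset_s = numeric(),
                           peak_time_s = numeric(), amplitude = numeric(),
                           duration_s = numeric(), neuron = integer(),
                           session = integer())
    rownames(bursts) <- NULL
    ds <- list(
      fluorescence = fl,
      positions = geo$positions,
      session_times = 12 + 0:(s - 1),
      hour_labels = 0:(s - 1),
      config = config,
      truth = list(module = geo$module, side = geo$side, pair = geo$pair,
                   anchor = geo$anchor, states = states, modes = modes,
                   mode_start = specs$mode_start, bursts = bursts,
                   f0 = specs$f0, rate = specs$rate,
                   signatures = sig, signature_group = sig_group,
                   wave_pass_hour = t_pass))
    class(ds) <- "scn_dataset"
    ds
  })
}

#' @export
print.scn_dataset <- function(x, ...) {
  d <- dim(x$fluorescence)
  cat(sprintf("Synthetic SCN dataset: %d neurons x %d sessions x %d frames\n",
              d[1], d[2], d[3]))
  cat(sprintf("  sessions CT%d..CT%d, %d planted modules, %d logged bursts\n",
              min(x$session_times), max(x$session_times),
              x$config$n_modules, nrow(x$truth$bursts)))
  invisible(x)
}

#' Convert a dataset's fluorescence to dF/F
#'
#' Uses the stored per-neuron baseline F0 (ground truth for synthetic data)
#' to compute (F - F0) / F0.
#'
#' @param dataset an `scn_dataset`.
#' @return array \[N x S x T\] of dF/F values.
#' @export
dataset_dff <- function(dataset) {
  stopifnot(inherits(dataset, "scn_dataset"))
  sweep(dataset$fluorescence, 1, dataset$truth$f0, `/`) - 1
}

# Matrix [N x T] of one session's dF/F.
session_dff <- function(dataset, session) {
  f0 <- dataset$truth$f0
  dataset$fluorescence[, session, ] / f0 - 1
}

#' Render a session as a synthetic image stack
#'
#' Projects neuron positions onto the x-y plane and renders each neuron as
#' a small disk whose intensity follows its fluorescence trace, over a flat
#' background. Used to exercise the image-to-trace pipeline.
#'
#' @param dataset an `scn_dataset` (keep `n_neurons` small).
#' @param session session index (1-based).
#' @param px image side length in pixels.
#' @param radius disk radius in pixels.
#' @param background background intensity (a.u.).
#' @return list with `stack` (array \[px x px x T\]), `masks` (list of
#'   pixel-index matrices, one ROI per neuron), `centers` (\[N x 2\] pixel
#'   coordinates).
#' @export
render_image_stack <- function(dataset, session = 1, px = 64, radius = 2,
                               background = 10) {
  stopifnot(inherits(dataset, "scn_dataset"))
  n <- dim(dataset$fluorescence)[1]
  nT <- dim(dataset$fluorescence)[3]
  xy <- dataset$positions[, 1:2, drop = FALSE]
  rng <- apply(xy, 2, range)
  pad <- radius + 2
  cx <- pad + (xy[, 1] - rng[1, 1]) / max(1e-9, diff(rng[, 1])) * (px - 2 * pad)
  cy <- pad + (xy[, 2] - rng[1, 2]) / max(1e-9, diff(rng[, 2])) * (px - 2 * pad)
  centers <- cbind(round(cx), round(cy))
  stack <- array(background, dim = c(px, px, nT))
  masks <- vector("list", n)
  grid <- expand.grid(x = seq_len(px), y = seq_len(px))
  for (i in seq_len(n)) {
    sel <- (grid$x - centers[i, 1])^2 + (grid$y - centers[i, 2])^2 <= radius^2
    pix <- as.matrix(grid[sel, , drop = FALSE])
    masks[[i]] <- pix
    tr <- dataset$fluorescence[i, session, ]
    for (p in seq_len(nrow(pix)))
      stack[pix[p, 1], pix[p, 2], ] <- stack[pix[p, 1], pix[p, 2], ] + tr
  }
  list(stack = stack, masks = masks, centers = centers)
}

#' Write / read a dataset as a plain-text container
#'
#' Serializes the dataset to a directory of CSV files plus a JSON config
#' sidecar (fluorescence in wide format, one row per neuron-session).
#' Intended for small exchange datasets.
#'
#' @param dataset an `scn_dataset`.
#' @param dir target directory (created if missing).
#' @return `write_scn_dataset` returns `dir` invisibly;
#'   `read_scn_dataset` returns the reconstructed `scn_dataset`.
#' @export
write_scn_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "scn_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  d <- dim(dataset$fluorescence)
  fl <- matrix(aperm(dataset$fluorescence, c(3, 2, 1)), nrow = d[1] * d[2],
               byrow = TRUE)
  idx <- expand.grid(session = seq_len(d[2]), neuron = seq_len(d[1]))
  idx <- idx[order(idx$neuron, idx$session), ]
  utils::write.csv(cbind(idx[, c("neuron", "session")], fl),
                   file.path(dir, "fluorescence.csv"), row.names = FALSE)
  utils::write.csv(data.frame(x = dataset$positions[, 1],
                              y = dataset$positions[, 2],
                              z = dataset$positions[, 3],
                              module = dataset$truth$module,
                              f0 = dataset$truth$f0),
                   file.path(dir, "neurons.csv"), row.names = FALSE)
  utils::write.csv(data.frame(session = seq_along(dataset$session_times),
                              ct = dataset$session_times,
                              hour_label = dataset$hour_labels),
                   file.path(dir, "sessions.csv"), row.names = FALSE)
  utils::write.csv(dataset$truth$bursts, file.path(dir, "bursts.csv"),
                   row.names = FALSE)
  cfg <- dataset$config
  cfg$burst_class_params <- as.list(cfg$burst_class_params)
  jsonlite::write_json(unclass(cfg), file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_scn_dataset
#' @export
read_scn_dataset <- function(dir) {
  fl_df <- utils::read.csv(file.path(dir, "fluorescence.csv"))
  neurons <- utils::read.csv(file.path(dir, "neurons.csv"))
  sessions <- utils::read.csv(file.path(dir, "sessions.csv"))
  bursts <- utils::read.csv(file.path(dir, "bursts.csv"))
  n <- nrow(neurons); s <- nrow(sessions)
  nT <- ncol(fl_df) - 2L
  fl <- array(NA_real_, dim = c(n, s, nT))
  m <- as.matrix(fl_df[, -(1:2), drop = FALSE])
  for (r in seq_len(nrow(fl_df)))
    fl[fl_df$neuron[r], fl_df$session[r], ] <- m[r, ]
  ds <- list(fluorescence = fl,
             positions = as.matrix(neurons[, c("x", "y", "z")]),
             session_times = sessions$ct,
             hour_labels = sessions$hour_label,
             config = NULL,
             truth = list(module = neurons$module, f0 = neurons$f0,
                          bursts = bursts))
  class(ds) <- "scn_dataset"
  ds
}
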