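## Orchestration: a single structured configuration drives the staged
## pipeline (simulate -> bursts -> states -> timecode -> subtypes ->
## modules -> pwha), with provenance logging (config hash, seeds, stage
## timing) and partial-output preservation on failure.

#' Build a pipeline configuration
#'
#' @param synth an [synth_config()] for the simulate stage.
#' @param stages named logical vector toggling the stages
#'   (`simulate`, `bursts`, `states`, `timecode`, `subtypes`, `modules`,
#'   `pwha`).
#' @param out_dir output directory for tables and the manifest.
#' @param cohort_size,trials time-predictor settings.
#' @param predictor_epochs,predictor_patience training bounds for the
#'   time-predictor stage.
#' @param subtype_K cluster counts for the subtype stage.
#' @param encoder_iter iteration cap for the contrastive-encoder stage.
#' @param states_per_class labeled archetype traces per state for
#'   classifier training.
#' @param state_epochs GCN training epochs.
#' @param seed master seed; each stochastic stage derives its own seed
#'   from it (all recorded in the manifest).
#' @return `scn_pipeline_config` list.
#' @export
pipeline_config <- function(synth = synth_config(n_neurons = 300),
                            stages = c(simulate = TRUE, bursts = TRUE,
                                       states = TRUE, timecode = TRUE,
                                       subtypes = TRUE, modules = FALSE,
                                       pwha = TRUE),
                            out_dir = tempfile("scnca_run_"),
                            cohort_size = 60, trials = 100,
                            predictor_epochs = 20, predictor_patience = 6,
                            subtype_K = 2:3, states_per_class = 20,
                            state_epochs = 60, encoder_iter = 20,
                            seed = 0) {
  cfg <- list(synth = synth, stages = stages, out_dir = out_dir,
              cohort_size = cohort_size, trials = trials,
              predictor_epochs = predictor_epochs,
              predictor_patience = predictor_patience,
              subtype_K = subtype_K, states_per_class = states_per_class,
              state_epochs = state_epochs, encoder_iter = encoder_iter,
              seed = as.integer(seed))
  class(cfg) <- "scn_pipeline_config"
  cfg
}

# Stable md5 hash of an R object via serialization to a temp file.
config_hash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(x, f, version = 2)
  unname(tools::md5sum(f))
}

#' Run the staged analysis pipeline
#'
#' Executes the toggled stages in dependency order, writes per-stage CSV
#' outputs and a provenance manifest (config hash, per-stage seeds and
#' timings, package version) under `config$out_dir`, and halts with a
#' stage-scoped error - preserving completed outputs - if a stage fails.
#' Stages whose dependencies are toggled off fail with a named dependency
#' error.
#'
#' @param config an [pipeline_config()] object.
#' @return invisible list of stage results (also written to disk).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "scn_pipeline_config"))
  st <- config$stages
  need <- function(dep, stage) {
    if (!isTRUE(st[dep]))
      stop("stage '", stage, "' requires stage '", dep,
           "' to be enabled", call. = FALSE)
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  results <- list()
  manifest <- list(config_hash = config_hash(config),
                   package_version = as.character(
                     utils::packageVersion("scnca")),
                   master_seed = config$seed, stages = list())
  run_stage <- function(name, fun) {
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(fun(), error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    manifest$stages[[name]] <<- list(
      seed = config$seed + which(names(st) == name),
      elapsed_s = round(proc.time()[["elapsed"]] - t0, 2))
    out
  }
  sseed <- function(name) config$seed + which(names(st) == name)

  if (isTRUE(st["simulate"])) {
    results$dataset <- run_stage("simulate", function() {
      synth <- config$synth
      synth$seed <- config$seed
      ds <- generate_dataset(synth)
      utils::write.csv(data.frame(x = ds$positions[, 1],
                                  y = ds$positions[, 2],
                                  z = ds$positions[, 3],
                                  module = ds$truth$module),
                       file.path(config$out_dir, "neurons.csv"),
                       row.names = FALSE)
      ds
    })
  }
  if (isTRUE(st["bursts"])) {
    need("simulate", "bursts")
    results$bursts <- run_stage("bursts", function() {
      ds <- results$dataset
      d <- dim(ds$fluorescence)
      dff <- dataset_dff(ds)
      ev_list <- list()
      for (i in seq_len(d[1])) for (s in seq_len(d[2])) {
        ev <- detect_bursts(dff[i, s, ], frame_rate = ds$config$frame_rate)
        if (nrow(ev) > 0) {
          ev$neuron <- i; ev$session <- s
          ev_list[[length(ev_list) + 1]] <- ev
        }
      }
      events <- do.call(rbind, ev_list)
      model <- cluster_bursts(events, K_range = 1:8, B = 25,
                              seed = sseed("bursts"))
      events$class <- model$assignments
      sw <- tryCatch(switching_matrix(events, model$K),
                     error = function(e) NULL)
      stats_ <- burst_statistics(events,
                                 total_s = d[2] * d[3] / ds$config$frame_rate)
      utils::write.csv(events, file.path(config$out_dir, "burst_events.csv"),
                       row.names = FALSE)
      utils::write.csv(model$gap_curve,
                       file.path(config$out_dir, "gap_curve.csv"),
                       row.names = FALSE)
      list(events = events, model = model, switching = sw, stats = stats_)
    })
  }
  if (isTRUE(st["states"])) {
    need("simulate", "states")
    results$states <- run_stage("states", function() {
      ds <- results$dataset
      with_seed(sseed("states"), {
        per <- config$states_per_class
        mans <- list(); labs <- integer(0)
        for (cls in 1:6) for (r in seq_len(per)) {
          tr <- archetype_trace(cls, dim(ds$fluorescence)[3],
                                ds$config$frame_rate)
          mans[[length(mans) + 1]] <- embed_manifold(tr)
          labs <- c(labs, cls)
        }
        aug <- augment_labeled_manifolds(mans, labs)
        clf <- train_state_classifier(aug$manifolds, aug$labels,
                                      epochs = config$state_epochs,
                                      seed = sseed("states"))
        cl <- classify_states(ds, clf)
        modes <- assign_modes(ds)
        utils::write.csv(as.data.frame(cl$fractions),
                         file.path(config$out_dir, "state_fractions.csv"),
                         row.names = FALSE)
        utils::write.csv(modes, file.path(config$out_dir, "modes.csv"),
                         row.names = FALSE)
        list(classifier = clf, states = cl, modes = modes)
      })
    })
  }
  if (isTRUE(st["timecode"])) {
    need("simulate", "timecode")
    results$timecode <- run_stage("timecode", function() {
      ds <- results$dataset
      pools <- partition_neurons(ds, seed = sseed("timecode"))
      size <- min(config$cohort_size, length(pools$train))
      pred <- train_time_predictor(ds, pools, size,
                                   epochs = config$predictor_epochs %||% 20,
                                   patience = config$predictor_patience %||% 6,
                                   seed = sseed("timecode"))
      acc <- cohort_accuracy(pred, ds, pools$test,
                             min(size, length(pools$test)),
                             trials = config$trials,
                             seed = sseed("timecode"))
      pc <- pca_trajectory(ds)
      utils::write.csv(data.frame(cohort_size = size, accuracy = acc),
                       file.path(config$out_dir, "time_accuracy.csv"),
                       row.names = FALSE)
      utils::write.csv(data.frame(hour = ds$hour_labels,
                                  pc1 = pc$points[, 1],
                                  pc2 = pc$points[, 2]),
                       file.path(config$out_dir, "pca_trajectory.csv"),
                       row.names = FALSE)
      list(predictor = pred, accuracy = acc, pca = pc, pools = pools)
    })
  }
  if (isTRUE(st["subtypes"])) {
    need("simulate", "subtypes")
    results$subtypes <- run_stage("subtypes", function() {
      ds <- results$dataset
      enc <- train_encoder(ds, max_iter = config$encoder_iter %||% 20,
                           seed = sseed("subtypes"))
      sub <- cluster_subtypes(enc$representations, K = config$subtype_K,
                              positions = ds$positions,
                              seed = sseed("subtypes"))
      lab <- as.data.frame(sub$labels)
      lab$neuron <- seq_len(nrow(lab))
      utils::write.csv(lab, file.path(config$out_dir, "subtypes.csv"),
                       row.names = FALSE)
      list(encoder = enc, subtypes = sub)
    })
  }
  if (isTRUE(st["modules"])) {
    need("simulate", "modules")
    need("subtypes", "modules")
    results$modules <- run_stage("modules", function() {
      ds <- results$dataset
      ms <- module_stats(ds)
      mm <- module_mic(ds, pairs_per_module = 30, seed = sseed("modules"))
      utils::write.csv(ms$stats, file.path(config$out_dir,
                                           "module_stats.csv"),
                       row.names = FALSE)
      utils::write.csv(mm, file.path(config$out_dir, "module_mic.csv"),
                       row.names = FALSE)
      list(stats = ms, mic = mm)
    })
  }
  if (isTRUE(st["pwha"])) {
    need("simulate", "pwha")
    results$pwha <- run_stage("pwha", function() {
      ds <- results$dataset
      maps <- hourly_intensity_maps(ds)
      exc <- detect_excited(maps)
      wf <- tryCatch(trace_wavefront(exc), error = function(e) NULL)
      if (!is.null(wf))
        utils::write.csv(wf$front, file.path(config$out_dir,
                                             "wavefront.csv"),
                         row.names = FALSE)
      list(excitation = exc, wavefront = wf)
    })
  }
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(results)
}
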