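#' Configuration for the synthetic SCN dataset generator
#'
#' Builds a validated configuration describing a simulated pair of
#' suprachiasmatic nuclei imaged as hourly 5-min calcium sessions. The
#' defaults emulate the multiscale structure of adult SCN slice recordings:
#' five burst classes with heavy class imbalance, six dynamical state
#' archetypes dominated by the irregular one, a 12-h high/low activity mode
#' split, a weak hour-specific population signature, concentric spatial
#' modules carrying opposing amplitude and coupling gradients, and an
#' optional slow traveling hyperactivity wave.
#'
#' @param n_neurons total neuron count across both nuclei.
#' @param n_sessions number of hourly sessions (default 24, one circadian
#'   cycle).
#' @param frames_per_session frames per 5-min session (default 200 at
#'   ~0.67 Hz).
#' @param frame_rate volumetric imaging rate in Hz.
#' @param n_modules number of planted concentric spatial modules.
#' @param burst_class_params data frame with one row per burst class and
#'   columns `class`, `mean_duration` (s, FWHM), `mean_amplitude`
#'   (peak dF/F), `prevalence` (mixture weight), `shape` (one of
#'   `"spiky"`, `"triangle"`, `"echelon"`, `"square"`).
#' @param rate_lognorm per-neuron burst-rate distribution, list with
#'   `meanlog`, `sdlog` (rates in Hz). The default puts the 5%/95%
#'   percentiles near 0.001 and 0.011 Hz.
#' @param state_probs named probabilities of the six state archetypes
#'   (I ring, II three-lobed, III plateau, IV hyperactive, V inverted,
#'   VI irregular) used to draw per-neuron per-session states.
#' @param mode_ratio amplitude scale of the low-activity (L) 12-h mode
#'   relative to the high-activity (H) mode.
#' @param mode_dc sustained baseline dF/F elevation expressed during the
#'   H mode (scaled by `mode_ratio` in the L mode), the main carrier of
#'   the circadian session-mean rhythm.
#' @param mode_start_hour session index (0-based) where the H-mode window
#'   starts for the population; individual neurons jitter around it.
#' @param mode_jitter_sd SD (hours) of the per-neuron mode-boundary jitter.
#' @param hourly_signature_strength dF/F amplitude of the hour-specific
#'   population signature waveform (dimensionless SNR dial).
#' @param module_specific_signatures if `TRUE` every module gets its own
#'   independent set of 24 hourly signature waveforms; otherwise all
#'   modules share one set.
#' @param coupling_gradient per-module mixing weight in \[0,1\] of the
#'   module-shared Ornstein-Uhlenbeck drive; default decreases
#'   ventrolateral to dorsomedial.
#' @param amplitude_gradient per-module dF/F scale factor; default
#'   increases ventrolateral to dorsomedial (opposite to coupling).
#' @param pwha list describing the phase wave of hyperactivity:
#'   `enabled`, `onset_hour` (session index at which the wave enters at the
#'   dorsal tip), `speed` (um/h), `direction` (length-3 unit vector),
#'   `amplitude` (dF/F), `width_h` (temporal Gaussian half-width, h).
#' @param module_rate_correlation in \[0, 1\]: copula correlation tying
#'   each neuron's burst-rate percentile to its module's position along
#'   the ventrolateral-dorsomedial axis (0 = rates independent of module;
#'   the population marginal stays approximately lognormal).
#' @param module_class_contrast strength (>= 0) of the module-varying
#'   burst-class composition: each module's burst-class mixture is tilted
#'   as prevalence * exp(contrast * cos(phase(module) - phase(class))),
#'   so the dominant burst waveform rotates smoothly across the
#'   concentric modules. 0 disables the tilt.
#' @param module_banding `"area"` (equal-width distance bands; band
#'   populations follow band area) or `"equal"` (equal-frequency bands,
#'   i.e. equal neuron counts per module).
#' @param noise_sd frame-wise Gaussian noise SD in dF/F units.
#' @param baseline_f0 mean raw-fluorescence baseline (a.u.).
#' @param max_elements refuse to generate datasets with more than this many
#'   fluorescence values (memory guard).
#' @param seed integer seed; a fixed seed yields bit-identical datasets.
#'
#' @return an object of class `scn_synth_config`.
#' @export
synth_config <- function(n_neurons = 3000,
                         n_sessions = 24,
                         frames_per_session = 200,
                         frame_rate = 0.67,
                         n_modules = 5,
                         burst_class_params = default_burst_classes(),
                         rate_lognorm = list(meanlog = -5.71, sdlog = 0.73),
                         state_probs = c(I = 0.006, II = 0.008, III = 0.02,
                                         IV = 0.015, V = 0.001, VI = 0.95),
                         mode_ratio = 0.4,
                         mode_dc = 0.25,
                         mode_start_hour = 2,
                         mode_jitter_sd = 1,
                         hourly_signature_strength = 0.008,
                         module_specific_signatures = FALSE,
                         coupling_gradient = NULL,
                         amplitude_gradient = NULL,
                         pwha = list(enabled = FALSE, onset_hour = 14,
                                     speed = 60, direction = c(0, -1, 0),
                                     amplitude = 0.6, width_h = 1.5),
                         module_rate_correlation = 0,
                         module_class_contrast = 0,
                         module_banding = c("area", "equal"),
                         noise_sd = 0.1,
                         baseline_f0 = 100,
                         max_elements = 2e8,
                         seed = 0) {
  if (n_modules < 1) stop("n_modules must be >= 1")
  if (n_neurons < 2 * n_modules)
    stop("invalid config: n_neurons must be at least 2 * n_modules")
  if (frames_per_session < 16) stop("frames_per_session must be >= 16")
  if (n_sessions < 1) stop("n_sessions must be >= 1")
  stopifnot(is.data.frame(burst_class_params),
            all(c("class", "mean_duration", "mean_amplitude", "prevalence",
                  "shape") %in% names(burst_class_params)))
  if (any(burst_class_params$prevalence < 0))
    stop("burst class prevalences must be >= 0")
  if (any(burst_class_params$mean_duration <= 0))
    stop("burst durations must be positive")
  if (is.null(coupling_gradient))
    coupling_gradient <- if (n_modules == 1) 0.01 else
      seq(0.02, 0.004, length.out = n_modules)
  if (is.null(amplitude_gradient))
    amplitude_gradient <- if (n_modules == 1) 1 else
      seq(1, 2, length.out = n_modules)
  if (length(coupling_gradient) != n_modules ||
      length(amplitude_gradient) != n_modules)
    stop("module gradient vectors must have length n_modules")
  if (any(coupling_gradient < 0 | coupling_gradient > 1))
    stop("coupling_gradient weights must lie in [0, 1]")
  module_banding <- match.arg(module_banding)
  if (module_class_contrast < 0) stop("module_class_contrast must be >= 0")
  if (module_rate_correlation < 0 || module_rate_correlation > 1)
    stop("module_rate_correlation must lie in [0, 1]")
  state_probs <- state_probs / sum(state_probs)
  if (as.double(n_neurons) * n_sessions * frames_per_session > max_elements)
    stop("refusing to generate: n_neurons * n_sessions * frames_per_session ",
         "exceeds max_elements")
  cfg <- list(n_neurons = as.integer(n_neurons),
              n_sessions = as.integer(n_sessions),
              frames_per_session = as.integer(frames_per_session),
              frame_rate = frame_rate,
              n_modules = as.integer(n_modules),
              burst_class_params = burst_class_params,
              rate_lognorm = rate_lognorm,
              state_probs = state_probs,
              mode_ratio = mode_ratio,
              mode_dc = mode_dc,
              mode_start_hour = mode_start_hour,
              mode_jitter_sd = mode_jitter_sd,
              hourly_signature_strength = hourly_signature_strength,
              module_specific_signatures = isTRUE(module_specific_signatures),
              coupling_gradient = coupling_gradient,
              amplitude_gradient = amplitude_gradient,
              module_rate_correlation = module_rate_correlation,
              module_class_contrast = module_class_contrast,
              module_banding = module_banding,
              pwha = utils::modifyList(
                list(enabled = FALSE, onset_hour = 14, speed = 60,
                     direction = c(0, -1, 0), amplitude = 0.6, width_h = 1.5),
                pwha),
              noise_sd = noise_sd,
              baseline_f0 = baseline_f0,
              max_elements = max_elements,
              seed = as.integer(seed))
  class(cfg) <- "scn_synth_config"
  cfg
}

#' Default burst class parameter table
#'
#' Five classes differing in duration, amplitude and waveform shape, with
#' prevalences following the strong class imbalance seen in SCN recordings.
#' Class means are calibrated so that the pooled population burst-duration
#' distribution spans roughly 17-130 s between its 5% and 95% percentiles.
#'
#' @return data frame of per-class generator parameters.
#' @export
default_burst_classes <- function() {
  data.frame(
    class = 1:5,
    mean_duration = c(25, 55, 100, 130, 180),   # s (FWHM)
    mean_amplitude = c(0.8, 1.5, 1.0, 1.8, 2.5), # peak dF/F
    prevalence = c(0.50, 0.34, 0.082, 0.069, 0.011),
    shape = c("spiky", "spiky", "triangle", "echelon", "square"),
    stringsAsFactors = FALSE
  )
}

#' @export
print.scn_synth_config <- function(x, ...) {
  cat("Synthetic SCN generator config\n")
  cat(sprintf("  neurons: %d   sessions: %d x %d frames (%.2f Hz)\n",
              x$n_neurons, x$n_sessions, x$frames_per_session, x$frame_rate))
  cat(sprintf("  modules: %d   burst classes: %d   signature strength: %g\n",
              x$n_modules, nrow(x$burst_class_params),
              x$hourly_signature_strength))
  cat(sprintf("  PWHA: %s   seed: %d\n",
              if (x$pwha$enabled) "on" else "off", x$seed))
  invisible(x)
}

# Per-module base burst-class mixture implementing the module-varying
# composition tilt.
module_class_weights <- function(config, module) {
  prev <- config$burst_class_params$prevalence
  ct <- config$module_class_contrast %||% 0
  if (ct <= 0 || config$n_modules == 1) return(prev)
  k <- length(prev)
  ph_m <- 2 * pi * (module - 1) / config$n_modules
  ph_c <- 2 * pi * (seq_len(k) - 1) / k
  w <- prev * exp(ct * cos(ph_m - ph_c))
  w / sum(w)
}

#' Module-structured study configuration
#'
#' The generator configuration used for the functional-subtype and
#' module-gradient analyses: three equal-population concentric modules
#' with a strong coupling gradient running opposite to the amplitude
#' gradient and a module-varying burst-class composition, so that module
#' membership is recoverable from single-neuron dynamics.
#'
#' @param n_neurons,n_sessions,frames_per_session,seed as in
#'   [synth_config()].
#' @param n_modules module count (default 3).
#' @param ... further overrides passed to [synth_config()].
#' @return an `scn_synth_config`.
#' @export
module_structured_config <- function(n_neurons = 60, n_sessions = 24,
                                     frames_per_session = 200,
                                     n_modules = 3,
                                     module_rate_correlation = 0.98,
                                     module_class_contrast = 3,
                                     coupling_gradient =
                                       seq(0.6, 0.15,
                                           length.out = n_modules),
                                     amplitude_gradient =
                                       seq(1, 4, length.out = n_modules),
                                     seed = 0, ...) {
  synth_config(n_neurons = n_neurons, n_sessions = n_sessions,
               frames_per_session = frames_per_session,
               n_modules = n_modules, module_banding = "equal",
               coupling_gradient = coupling_gradient,
               amplitude_gradient = amplitude_gradient,
               module_class_contrast = module_class_contrast,
               module_rate_correlation = module_rate_correlation,
               seed = seed, ...)
}
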