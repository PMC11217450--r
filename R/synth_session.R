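## Trace-level building blocks of the synthetic generator: burst waveform
## kernels, state-archetype motifs, hourly signature waveforms, and the
## module-shared Ornstein-Uhlenbeck drive. The single-session synthesizer
## composes exactly the same components as the batched dataset generator.

# Waveform kernel of one burst, sampled on the session frame grid.
# `duration` is the target FWHM (s); returns dF/F values starting at the
# onset frame. Peak value equals `amplitude` for every shape.
burst_kernel <- function(shape, duration, amplitude, dt) {
  if (shape == "spiky") {
    theta <- duration / 2.446            # gamma(k=2) kernel: FWHM = 2.446*theta
    t <- seq(0, 8 * theta, by = dt)
    v <- (t / theta) * exp(1 - t / theta)
  } else if (shape == "triangle") {
    base <- 2 * duration                  # FWHM of a triangle = base / 2
    rise <- 0.3 * base
    t <- seq(0, base, by = dt)
    v <- ifelse(t <= rise, t / rise, pmax(0, (base - t) / (base - rise)))
  } else if (shape == "echelon") {
    base <- duration / 0.8                # trapezoid: FWHM = p + (r + f)/2
    r <- 0.2 * base; p <- 0.6 * base
    t <- seq(0, base, by = dt)
    v <- ifelse(t <= r, t / r,
                ifelse(t <= r + p, 1, pmax(0, (base - t) / (base - r - p))))
  } else if (shape == "square") {
    base <- duration / 0.96
    r <- 0.04 * base; p <- 0.92 * base
    t <- seq(0, base, by = dt)
    v <- ifelse(t <= r, t / r,
                ifelse(t <= r + p, 1, pmax(0, (base - t) / (base - r - p))))
  } else stop("unknown burst shape: ", shape)
  amplitude * v
}

# Time from onset to peak, per shape, as a function of FWHM duration.
burst_peak_offset <- function(shape, duration) {
  switch(shape,
    spiky = duration / 2.446,
    triangle = 0.6 * duration,       # rise = 0.3 * base = 0.6 * FWHM
    echelon = 0.25 * duration,       # rise = 0.2 * base = 0.2 * FWHM / 0.8
    square = duration / 24,          # rise = 0.04 * base
    stop("unknown burst shape: ", shape))
}

# Dynamical-state archetype motif added on top of bursts and noise.
# States: I ring, II three-lobed, III plateau, IV hyperactive,
# V inverted-spiking, VI irregular (no motif).
state_motif <- function(state, n_frames, frame_rate) {
  t <- seq_len(n_frames)
  switch(as.character(state),
    "1" = 0.9 * sin(2 * pi * t / 40 + stats::runif(1, 0, 2 * pi)),
    "2" = {
      ph <- stats::runif(1, 0, 2 * pi)
      sin(2 * pi * t / 36 + ph) * (0.55 + 0.45 * cos(2 * pi * t / 108))
    },
    "3" = {
      ph <- stats::runif(1, 0, 2 * pi)
      0.8 * tanh(3 * sin(2 * pi * t / 80 + ph))
    },
    "4" = 1.4 + 1.0 * sin(2 * pi * t / 8 + stats::runif(1, 0, 2 * pi)),
    "5" = {
      v <- rep(1.2, n_frames)
      n_dip <- stats::rpois(1, n_frames / 50)
      if (n_dip > 0) {
        at <- sample.int(max(1, n_frames - 8), n_dip, replace = TRUE)
        for (a in at) {
          idx <- a:min(n_frames, a + 6)
          v[idx] <- v[idx] - 1.1 * exp(-((idx - a - 3)^2) / 4)
        }
      }
      v
    },
    "6" = numeric(n_frames),
    stop("unknown state archetype id: ", state)
  )
}

#' Generate a labeled state-archetype trace
#'
#' Produces a z-scored synthetic 5-min trace realizing one of the six
#' dynamical-state archetypes (I ring-like oscillation, II three-lobed,
#' III plateau, IV hyperactive, V inverted-spiking, VI irregular), used as
#' ground-truth labeled material for the state classifier.
#'
#' @param state integer 1..6.
#' @param n_frames trace length in frames.
#' @param frame_rate sampling rate (Hz).
#' @param noise_sd additive Gaussian noise SD (dF/F).
#' @return numeric vector of length `n_frames` (z-scored).
#' @export
archetype_trace <- function(state, n_frames = 200, frame_rate = 0.67,
                            noise_sd = 0.15) {
  base <- state_motif(state, n_frames, frame_rate)
  if (state == 6) {
    # irregular: sparse random bursts over a drifting baseline
    n_ev <- stats::rpois(1, 2) + 1L
    dt <- 1 / frame_rate
    for (i in seq_len(n_ev)) {
      k <- burst_kernel("spiky", stats::runif(1, 15, 60),
                        stats::runif(1, 0.5, 1.5), dt)
      on <- sample.int(n_frames, 1)
      idx <- on:min(n_frames, on + length(k) - 1L)
      base[idx] <- base[idx] + k[seq_along(idx)]
    }
    base <- base +
      0.3 * sin(2 * pi * seq_len(n_frames) / stats::runif(1, 120, 300) +
                stats::runif(1, 0, 2 * pi))
  }
  zscore(base + stats::rnorm(n_frames, sd = noise_sd))
}

# Hour-specific population signature waveforms: array [n_sets, S, T] of
# smooth unit-SD curves (sums of 1..3-cycle sinusoids with random phases).
make_signature_waves <- function(n_sets, n_sessions, n_frames) {
  out <- array(0, dim = c(n_sets, n_sessions, n_frames))
  t <- seq_len(n_frames) / n_frames
  for (g in seq_len(n_sets)) {
    for (s in seq_len(n_sessions)) {
      co <- stats::rnorm(3)
      ph <- stats::runif(3, 0, 2 * pi)
      w <- co[1] * sin(2 * pi * t + ph[1]) +
           co[2] * sin(4 * pi * t + ph[2]) +
           co[3] * sin(6 * pi * t + ph[3])
      out[g, s, ] <- w / stats::sd(w)
    }
  }
  out
}

# Discrete Ornstein-Uhlenbeck (AR(1)) drive with unit stationary SD.
ou_drive <- function(n_frames, corr_frames = 15) {
  rho <- exp(-1 / corr_frames)
  innov <- stats::rnorm(n_frames)
  x <- numeric(n_frames)
  x[1] <- innov[1]
  scale <- sqrt(1 - rho^2)
  for (i in 2:n_frames) x[i] <- rho * x[i - 1] + scale * innov[i]
  x
}

# Hour-dependent burst-class mixture: base prevalences modulated by a
# rotating sinusoid so the class composition slowly changes over the day.
hour_class_weights <- function(prev, hour_label, n_sessions) {
  k <- length(prev)
  w <- prev * (1 + 0.3 * sin(2 * pi * hour_label / n_sessions +
                             2 * pi * (seq_len(k) - 1) / k))
  w <- pmax(w, 0)
  w / sum(w)
}

# FWHM-to-peak-offset factors per waveform shape (see burst_peak_offset).
.peak_frac <- c(spiky = 1 / 2.446, triangle = 0.6, echelon = 0.25,
                square = 1 / 24)

.empty_events <- data.frame(class = integer(), onset_s = numeric(),
                            peak_time_s = numeric(), amplitude = numeric(),
                            duration_s = numeric())

# Draw burst events for one neuron-session: Poisson count, class sampled
# from the mixture, lognormal duration/amplitude jitter (25% CV), uniform
# onsets constrained so the burst body fits inside the session.
draw_burst_events <- function(rate, class_weights, classes, session_sec,
                              amp_scale = 1) {
  n_ev <- stats::rpois(1, rate * session_sec)
  if (n_ev == 0) return(.empty_events)
  cl <- sample.int(nrow(classes), n_ev, replace = TRUE, prob = class_weights)
  dur <- stats::rlnorm(n_ev, log(classes$mean_duration[cl]) - 0.5 * 0.25^2,
                       0.25)
  amp <- amp_scale *
    stats::rlnorm(n_ev, log(classes$mean_amplitude[cl]) - 0.5 * 0.25^2, 0.25)
  onset <- stats::runif(n_ev, 0, pmax(1e-6, session_sec - dur))
  pk <- dur * .peak_frac[classes$shape[cl]]
  o <- order(onset)
  df <- list(class = classes$class[cl][o], onset_s = onset[o],
             peak_time_s = (onset + pk)[o], amplitude = amp[o],
             duration_s = dur[o])
  class(df) <- "data.frame"
  attr(df, "row.names") <- .set_row_names(n_ev)
  df
}

# Add burst kernels onto a trace (dF/F, length n_frames).
add_bursts <- function(trace, events, classes, frame_rate) {
  n_ev <- nrow(events)
  if (n_ev == 0) return(trace)
  dt <- 1 / frame_rate
  shapes <- classes$shape[match(events$class, classes$class)]
  n <- length(trace)
  for (i in seq_len(n_ev)) {
    k <- burst_kernel(shapes[i], events$duration_s[i],
                      events$amplitude[i], dt)
    on_f <- floor(events$onset_s[i] * frame_rate) + 1L
    if (on_f > n) next
    idx <- on_f:min(n, on_f + length(k) - 1L)
    trace[idx] <- trace[idx] + k[seq_along(idx)]
  }
  trace
}

# Is 0-based session index h inside the 12-session H window starting at s0?
in_h_window <- function(h, s0, n_sessions) {
  half <- n_sessions %/% 2
  ((h - s0) %% n_sessions) < half
}

#' Synthesize one neuron's 5-min session trace
#'
#' Composes a single session as baseline oscillation + class-tagged burst
#' train + state-archetype motif + 12-h mode amplitude scaling +
#' hour-specific signature + module-shared drive + Gaussian noise, and logs
#' every planted burst. This is the per-trace counterpart of
#' [generate_dataset()]; both compose the same components.
#'
#' @param spec per-neuron spec: list with `module`, `rate` (Hz, >= 0),
#'   `f0` (baseline fluorescence a.u.), `mode_start` (0-based session index
#'   where the H-mode window starts), `baseline_amp`, `baseline_period`
#'   (frames), `class_weights` (optional base mixture over burst classes).
#' @param hour 0-based session index (0..n_sessions-1).
#' @param config an [synth_config()] object.
#' @param state archetype id 1..6 for this session (default 6, irregular).
#' @param signature_wave optional length-T signature waveform (unit SD); if
#'   `NULL` no signature is added.
#' @param drive optional length-T shared drive; if `NULL` none is added.
#' @return list with `dff` (dF/F trace), `f` (raw fluorescence a.u.),
#'   `events` (burst truth table), `mode` (`"H"` or `"L"`).
#' @export
synthesize_session <- function(spec, hour, config, state = 6,
                               signature_wave = NULL, drive = NULL) {
  stopifnot(inherits(config, "scn_synth_config"))
  if (!is.numeric(spec$rate) || spec$rate < 0)
    stop("negative configured burst rate")
  if (hour < 0 || hour >= config$n_sessions)
    stop("hour must be a 0-based session index within n_sessions")
  nT <- config$frames_per_session
  fr <- config$frame_rate
  session_sec <- nT / fr
  classes <- config$burst_class_params
  module <- spec$module %||% 1L
  amp_scale <- config$amplitude_gradient[module]
  in_h <- in_h_window(hour, spec$mode_start %||% config$mode_start_hour,
                      config$n_sessions)
  mode_scale <- if (in_h) 1 else config$mode_ratio
  base_w <- spec$class_weights %||% classes$prevalence
  w <- hour_class_weights(base_w, hour, config$n_sessions)
  # logged amplitudes carry the full module x mode scaling
  events <- draw_burst_events(spec$rate, w, classes, session_sec,
                              amp_scale * mode_scale)
  dff <- add_bursts(numeric(nT), events, classes, fr)
  bamp <- spec$baseline_amp %||% 0.08
  if (bamp > 0) {
    per <- spec$baseline_period %||% 150
    dff <- dff + amp_scale * mode_scale * bamp *
      sin(2 * pi * seq_len(nT) / per + stats::runif(1, 0, 2 * pi))
  }
  if (state != 6)
    dff <- dff + amp_scale * mode_scale * state_motif(state, nT, fr)
  # sustained activity-mode baseline elevation (session-mean rhythm)
  dff <- dff + amp_scale * mode_scale * (config$mode_dc %||% 0)
  if (!is.null(signature_wave))
    dff <- dff + config$hourly_signature_strength * signature_wave
  if (!is.null(drive))
    dff <- dff + config$coupling_gradient[module] * drive
  if (config$noise_sd > 0)
    dff <- dff + stats::rnorm(nT, sd = config$noise_sd)
  f0 <- spec$f0 %||% config$baseline_f0
  list(dff = dff, f = f0 * (1 + dff), events = events,
       mode = if (in_h) "H" else "L")
}
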