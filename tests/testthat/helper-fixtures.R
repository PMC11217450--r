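# Shared fixtures, generated once per test run and memoized.

.fix <- new.env(parent = emptyenv())

# Small default-config dataset (3 modules, 8 h x 100 frames).
small_dataset <- function() {
  if (is.null(.fix$small))
    .fix$small <- generate_dataset(
      synth_config(n_neurons = 60, n_sessions = 8, frames_per_session = 100,
                   n_modules = 3, seed = 1))
  .fix$small
}

# Module-structured dataset + trained encoder (subtype fixtures).
module_fixture <- function() {
  if (is.null(.fix$mod)) {
    ds <- generate_dataset(module_structured_config(n_neurons = 48, seed = 2))
    enc <- train_encoder(ds, hidden = 16, max_iter = 10, seed = 102)
    .fix$mod <- list(ds = ds, enc = enc)
  }
  .fix$mod
}

# Build an scn_dataset whose session means follow a given [N x S] profile
# (plus frame noise), for mode/PCA tests with a known schedule.
profile_dataset <- function(profile, n_frames = 40, noise_sd = 0.05,
                            f0 = 100, seed = 0) {
  withr::with_seed(seed, {
    n <- nrow(profile); s <- ncol(profile)
    fl <- array(0, c(n, s, n_frames))
    for (i in seq_len(n)) for (h in seq_len(s))
      fl[i, h, ] <- f0 * (1 + profile[i, h] +
                          stats::rnorm(n_frames, sd = noise_sd))
    ds <- list(fluorescence = fl,
               positions = matrix(stats::rnorm(3 * n), n, 3),
               session_times = 12 + 0:(s - 1), hour_labels = 0:(s - 1),
               config = NULL,
               truth = list(f0 = rep(f0, n), module = rep(1L, n)))
    class(ds) <- "scn_dataset"
    ds
  })
}

# Labeled archetype manifolds for the state classifier.
archetype_set <- function(per_class, n_frames = 200, noise_sd = 0.15) {
  mans <- list(); labs <- integer(0)
  for (cls in 1:6) for (r in seq_len(per_class)) {
    mans[[length(mans) + 1]] <- embed_manifold(
      archetype_trace(cls, n_frames, noise_sd = noise_sd))
    labs <- c(labs, cls)
  }
  list(manifolds = mans, labels = labs)
}
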