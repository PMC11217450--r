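test_that("neuron pools follow the 6:1:3 floor arithmetic", {
  p <- partition_neurons(100, seed = 0)
  expect_equal(lengths(p), c(train = 60L, val = 10L, test = 30L))
  p2 <- partition_neurons(6049, seed = 1)
  expect_equal(lengths(p2), c(train = 3629L, val = 604L, test = 1816L))
  all_ids <- sort(c(p2$train, p2$val, p2$test))
  expect_equal(all_ids, 1:6049)           # disjoint and exhaustive
  expect_error(partition_neurons(100, ratio = c(5, 1, 3)), "sum to 10")
  expect_error(partition_neurons(5), "at least 10")
})

test_that("hourly population vectors trace an ordered circular trajectory", {
  # planted two-phase sinusoidal signature: half the population leads,
  # half lags, so PC1-PC2 must order the hours around the circle
  n <- 40
  prof <- rbind(
    t(sapply(1:(n / 2), function(i) 0.3 * cos(2 * pi * (0:23) / 24))),
    t(sapply(1:(n / 2), function(i) 0.3 * sin(2 * pi * (0:23) / 24))))
  ds <- profile_dataset(prof, n_frames = 30, noise_sd = 0.05, seed = 5)
  pc <- pca_trajectory(ds)
  ang <- atan2(pc$points[, 2], pc$points[, 1])
  # angle-sort oracle: unwrapped angles of consecutive hours are monotone
  d <- diff(ang)
  d <- (d + pi) %% (2 * pi) - pi
  expect_true(all(d > 0) || all(d < 0))
  expect_gt(pc$circularity, 0.9)
  # identical sessions collapse to a single point
  ds0 <- profile_dataset(matrix(0.2, 10, 6), n_frames = 20, noise_sd = 0,
                         seed = 6)
  pc0 <- pca_trajectory(ds0)
  expect_lt(max(stats::dist(pc0$points)), 1e-8)
})

test_that("an uninformative dataset decodes at chance level", {
  cfg <- synth_config(n_neurons = 240, n_sessions = 24,
                      frames_per_session = 60,
                      hourly_signature_strength = 0,
                      coupling_gradient = rep(0, 5), seed = 21)
  ds <- generate_dataset(cfg)
  pools <- partition_neurons(ds, seed = 0)
  pred <- train_time_predictor(ds, pools, 40, cohorts_per_hour = 10,
                               epochs = 8, val_cohorts = 96, seed = 0)
  acc <- cohort_accuracy(pred, ds, pools$test, 40, trials = 600, seed = 5)
  expect_lt(acc, 0.12)   # chance is 1/24
})

test_that("cohort size errors and accuracy-curve bookkeeping behave", {
  ds <- small_dataset()
  pools <- partition_neurons(ds, seed = 0)
  expect_error(train_time_predictor(ds, pools, 10 * length(pools$train)),
               "exceeds")
  expect_warning(accuracy_curve(ds, sizes = 4, trials = 10, seeds = 0,
                                cohorts_per_hour = 3, epochs = 2,
                                val_cohorts = 16),
                 "fewer than 30 trials")
})

test_that("accuracy grows with cohort size on signature-bearing data", {
  # small decoding-calibrated dataset; one-sided trend over 5 seeds
  cfg <- synth_config(n_neurons = 300, n_sessions = 24,
                      frames_per_session = 60,
                      hourly_signature_strength = 0.04, seed = 22)
  ds <- generate_dataset(cfg)
  curve <- accuracy_curve(ds, sizes = c(1, 30, 120), trials = 200,
                          seeds = 0:4, cohorts_per_hour = 6, epochs = 6,
                          val_cohorts = 72, patience = 3)
  sm <- curve$summary
  expect_true(all(diff(sm$mean[order(sm$size)]) >= 0))
  expect_lt(curve$trend_p, 0.01)
})

test_that("cohort feature clouds tighten as cohorts grow", {
  cfg <- synth_config(n_neurons = 200, n_sessions = 12,
                      frames_per_session = 60,
                      hourly_signature_strength = 0.15, seed = 23)
  ds <- generate_dataset(cfg)
  pools <- partition_neurons(ds, seed = 0)
  pred <- train_time_predictor(ds, pools, 40, cohorts_per_hour = 10,
                               epochs = 10, val_cohorts = 60, seed = 0)
  big <- embed_feature_space(pred, ds, pools$test, size = 40,
                             n_cohorts = 120, seed = 1)
  small <- embed_feature_space(pred, ds, pools$test, size = 1,
                               n_cohorts = 120, seed = 1)
  expect_gt(big$silhouette, small$silhouette)
  # shuffled labels give near-zero silhouette (permutation baseline)
  shuf <- withr::with_seed(2, sample(big$hour))
  sil0 <- mean(cluster::silhouette(shuf,
                                   stats::dist(big$coords))[, "sil_width"])
  expect_lt(sil0, 0.1)
  expect_error(embed_feature_space(pred, ds, pools$test, size = 2000),
               "exceeds|cohort")
})
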