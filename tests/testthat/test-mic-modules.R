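test_that("MIC scores functional relations and independence correctly", {
  x <- seq(-3, 3, length.out = 200)
  expect_gte(mic(x, x^2)$mic, 0.99)          # noiseless functional relation
  expect_gte(mic(1:200, (1:200) * 2)$mic, 0.99)
  withr::with_seed(1, {
    a <- stats::rnorm(4800); b <- stats::rnorm(4800)
    expect_lt(mic(a, b)$mic, 0.3)            # independent white noise
    expect_equal(mic(a, b)$mic, mic(b, a)$mic, tolerance = 1e-12)
  })
  expect_error(mic(rep(1, 50), stats::rnorm(50)), "constant")
  expect_error(mic(1:5, 1:5), "at least 8")
})

test_that("MIC stays within [0, 1] on assorted inputs", {
  withr::with_seed(2, {
    for (i in 1:5) {
      x <- stats::rnorm(300)
      y <- 0.3 * x + stats::rnorm(300, sd = i / 3)
      m <- mic(x, y)$mic
      expect_gte(m, 0); expect_lte(m, 1)
    }
  })
})

test_that("module statistics expose the planted amplitude gradient", {
  fx <- module_fixture()
  ms <- module_stats(fx$ds)
  expect_equal(ms$stats$n_neurons,
               as.integer(table(fx$ds$truth$module)))
  expect_true(all(diff(ms$stats$mean_amplitude) > 0))
  expect_lt(ms$trend$p_value, 0.01)
  expect_error(module_stats(fx$ds, labels = rep(1, 10)), "cover")
})

test_that("flat gradients show no amplitude ordering", {
  cfg <- synth_config(n_neurons = 60, n_sessions = 8,
                      frames_per_session = 60, n_modules = 3,
                      amplitude_gradient = rep(1, 3),
                      coupling_gradient = rep(0.01, 3), seed = 41)
  ms <- module_stats(generate_dataset(cfg))
  expect_gt(ms$trend$p_value, 0.01)
})

test_that("coupling and amplitude gradients run in opposite directions", {
  fx <- module_fixture()
  ms <- module_stats(fx$ds)
  mm <- module_mic(fx$ds, pairs_per_module = 25, max_points = 1600,
                   seed = 0)
  expect_equal(mm$module, ms$stats$module)
  # amplitude rises ventrolateral -> dorsomedial while MIC falls
  expect_gt(stats::cor(ms$stats$module, ms$stats$mean_amplitude,
                       method = "spearman"), 0)
  expect_lt(stats::cor(mm$module, mm$mean_mic, method = "spearman"), 0)
})

test_that("module predictors decode their own module but not others", {
  cfg <- synth_config(n_neurons = 660, n_sessions = 24,
                      frames_per_session = 60, n_modules = 3,
                      module_banding = "equal",
                      module_specific_signatures = TRUE,
                      hourly_signature_strength = 0.06, seed = 42)
  ds <- generate_dataset(cfg)
  cm <- cross_module_eval(ds, cohort_size = 60, trials = 150, seed = 0,
                          cohorts_per_hour = 10, epochs = 18,
                          val_cohorts = 72, patience = 6)
  di <- diag(cm$accuracy)
  off <- cm$accuracy[row(cm$accuracy) != col(cm$accuracy)]
  expect_gt(mean(di), mean(off))
  expect_gt(mean(di), 0.85)
  expect_lt(mean(off), 0.25)

  # shared signatures leave cross-module prediction intact
  cfg2 <- synth_config(n_neurons = 330, n_sessions = 24,
                       frames_per_session = 60, n_modules = 3,
                       module_banding = "equal",
                       module_specific_signatures = FALSE,
                       hourly_signature_strength = 0.06, seed = 43)
  ds2 <- generate_dataset(cfg2)
  cm2 <- cross_module_eval(ds2, cohort_size = 40, trials = 150, seed = 0,
                           cohorts_per_hour = 10, epochs = 18,
                           val_cohorts = 72, patience = 6)
  di2 <- mean(diag(cm2$accuracy))
  off2 <- mean(cm2$accuracy[row(cm2$accuracy) != col(cm2$accuracy)])
  expect_gt(off2, 0.6 * di2)
})
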