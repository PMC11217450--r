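test_that("config validation rejects inconsistent settings", {
  expect_error(synth_config(n_neurons = 4, n_modules = 3), "invalid config")
  expect_error(synth_config(frames_per_session = 8), "frames_per_session")
  expect_error(synth_config(coupling_gradient = rep(2, 5)), "coupling")
  expect_error(synth_config(n_neurons = 1e5, n_sessions = 24,
                            frames_per_session = 200, max_elements = 1e6),
               "exceeds")
  expect_error(synthesize_session(list(rate = -1), 0, synth_config()),
               "negative")
})

test_that("geometry plants mirrored concentric modules", {
  cfg1 <- synth_config(n_neurons = 200, n_modules = 1, seed = 3)
  g1 <- generate_geometry(cfg1)
  expect_true(all(g1$module == 1))

  cfg <- synth_config(n_neurons = 3000, n_modules = 3, seed = 3)
  geo <- generate_geometry(cfg)
  # brute-force oracle: recompute band membership by sorting distances to
  # the anchor into equal-width bands on the right-side points
  right <- geo$side == "right"
  d <- sqrt(rowSums(sweep(geo$positions[right, ], 2, geo$anchor)^2))
  br <- seq(min(d), max(d), length.out = 4)
  oracle <- pmin(pmax(findInterval(d, br, rightmost.closed = TRUE), 1L), 3L)
  expect_equal(unname(geo$module[right]), unname(oracle))

  # mirrored partners share module id, left/right histograms match
  pr <- geo$pair[right]
  ok <- !is.na(pr)
  expect_equal(geo$module[right][ok], geo$module[pr[ok]])
  expect_equal(as.integer(table(geo$module[right])),
               as.integer(table(geo$module[!right])))
  # reflecting x about the midline recovers the partner within jitter
  mirr <- geo$positions[pr[ok], ]
  mirr[, 1] <- -mirr[, 1]
  err <- sqrt(rowSums((geo$positions[right, ][ok, ] - mirr)^2))
  expect_lt(max(err), 5 * 5)  # 5 um jitter per axis
})

test_that("equal banding yields equal module populations", {
  cfg <- synth_config(n_neurons = 600, n_modules = 3,
                      module_banding = "equal", seed = 0)
  expect_equal(as.integer(table(generate_geometry(cfg)$module)),
               rep(200L, 3))
})

test_that("datasets are deterministic with consistent shapes and truth", {
  cfg <- synth_config(n_neurons = 40, n_sessions = 6,
                      frames_per_session = 50, n_modules = 2, seed = 7)
  ds1 <- generate_dataset(cfg)
  ds2 <- generate_dataset(cfg)
  expect_identical(ds1$fluorescence, ds2$fluorescence)
  expect_identical(ds1$truth$bursts, ds2$truth$bursts)
  expect_equal(dim(ds1$fluorescence), c(40L, 6L, 50L))
  expect_equal(dim(ds1$positions), c(40L, 3L))
  expect_false(anyNA(ds1$fluorescence))
  # planted truth self-consistency
  b <- ds1$truth$bursts
  expect_true(all(b$onset_s >= 0))
  expect_true(all(b$onset_s <= 50 / cfg$frame_rate))
  expect_true(all(b$session %in% 1:6))
  expect_equal(sort(unique(ds1$truth$module)), 1:2)
})

test_that("a burst-free noiseless flat session is constant", {
  cfg <- synth_config(n_neurons = 10, noise_sd = 0, seed = 0)
  out <- synthesize_session(list(rate = 0, baseline_amp = 0, f0 = 50),
                            hour = 3, config = cfg)
  expect_equal(stats::sd(out$dff), 0)
  expect_equal(out$f[1], 50 * (1 + out$dff[1]))
})

test_that("burst counts follow the configured Poisson rate", {
  # 0.005 Hz over a 200-s session => ~1 event per session on average
  cfg <- synth_config(n_neurons = 10, frames_per_session = 200,
                      frame_rate = 1, noise_sd = 0, seed = 0)
  spec <- list(rate = 0.005, class_weights = c(0, 1, 0, 0, 0),
               baseline_amp = 0)
  n_rep <- 4000
  counts <- withr::with_seed(11, vapply(seq_len(n_rep), function(i)
    nrow(synthesize_session(spec, 0, cfg)$events), numeric(1)))
  expected <- 0.005 * 200
  se <- sqrt(expected / n_rep)   # Poisson-thinning oracle
  expect_lt(abs(mean(counts) - expected), 3 * se)
})

test_that("population burst statistics match the calibrated ranges", {
  cfg <- synth_config(n_neurons = 1200, seed = 3)
  ds <- generate_dataset(cfg)
  b <- ds$truth$bursts
  q <- stats::quantile(b$duration_s, c(0.05, 0.95), names = FALSE)
  expect_gt(q[1], 17.4 * 0.85); expect_lt(q[1], 17.4 * 1.15)
  expect_gt(q[2], 129 * 0.85); expect_lt(q[2], 129 * 1.15)
  total_s <- cfg$n_sessions * cfg$frames_per_session / cfg$frame_rate
  st <- burst_statistics(b, total_s = total_s)
  expect_gt(st$rate_q[1], 0.001 * 0.6); expect_lt(st$rate_q[1], 0.001 * 1.6)
  expect_gt(st$rate_q[2], 0.011 * 0.8); expect_lt(st$rate_q[2], 0.011 * 1.25)
})

test_that("stronger hourly signatures carry more time information", {
  # MI between hour label and the population mean vector, estimated from
  # group-mean traces via leave-one-group-out nearest-centroid partitions
  mi_at <- function(strength) {
    cfg <- synth_config(n_neurons = 320, n_sessions = 8,
                        frames_per_session = 60,
                        hourly_signature_strength = strength,
                        coupling_gradient = rep(0, 5), seed = 5)
    ds <- generate_dataset(cfg)
    dff <- dataset_dff(ds)
    G <- 16L
    grp <- rep(seq_len(G), each = 320 / G)
    pred <- integer(0); truth <- integer(0)
    means <- lapply(seq_len(G), function(g)
      sapply(1:8, function(s) colMeans(dff[grp == g, s, ])))
    for (g in seq_len(G)) {
      cent <- Reduce(`+`, means[-g]) / (G - 1)
      for (s in 1:8) {
        pred <- c(pred, which.min(colSums((cent - means[[g]][, s])^2)))
        truth <- c(truth, s)
      }
    }
    tab <- table(factor(truth, levels = 1:8), factor(pred, levels = 1:8))
    p <- tab / sum(tab)
    px <- rowSums(p); py <- colSums(p)
    nz <- p > 0
    sum(p[nz] * log2(p[nz] / outer(px, py)[nz]))
  }
  mis <- vapply(c(0, 0.05, 0.3), mi_at, numeric(1))
  expect_lt(mis[1], mis[2])
  expect_lt(mis[2], mis[3])
})

test_that("the planted traveling wave orders activity along its axis", {
  cfg <- synth_config(n_neurons = 150, n_sessions = 24,
                      frames_per_session = 30,
                      pwha = list(enabled = TRUE, onset_hour = 4,
                                  speed = 40, direction = c(0, -1, 0),
                                  amplitude = 0.8, width_h = 1.5),
                      seed = 6)
  ds <- generate_dataset(cfg)
  dirv <- c(0, -1, 0)
  proj <- as.numeric(ds$positions %*% dirv)
  expect_gt(stats::cor(proj, ds$truth$wave_pass_hour), 0.999)
  # leading third (early passage) peaks before the trailing third
  amp <- sapply(1:24, function(s) rowMeans(session_dff(ds, s)))
  thirds <- cut(proj, stats::quantile(proj, c(0, 1/3, 2/3, 1)),
                include.lowest = TRUE, labels = FALSE)
  lead <- colMeans(amp[thirds == 1, ])
  trail <- colMeans(amp[thirds == 3, ])
  # exhaustive lag search on the cross-correlation
  lags <- -6:6
  cc <- vapply(lags, function(l) {
    if (l >= 0) stats::cor(lead[1:(24 - l)], trail[(1 + l):24])
    else stats::cor(lead[(1 - l):24], trail[1:(24 + l)])
  }, numeric(1))
  expect_gt(lags[which.max(cc)], 0)
})

test_that("dataset round-trips through the plain-text container", {
  ds <- generate_dataset(synth_config(n_neurons = 8, n_sessions = 3,
                                      frames_per_session = 20, n_modules = 2,
                                      seed = 4))
  dir <- tempfile("scnds_")
  write_scn_dataset(ds, dir)
  back <- read_scn_dataset(dir)
  expect_equal(back$fluorescence, ds$fluorescence, tolerance = 1e-8)
  expect_equal(back$truth$module, ds$truth$module)
  expect_equal(back$session_times, ds$session_times)
  unlink(dir, recursive = TRUE)
})
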