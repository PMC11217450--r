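test_that("background is the mean of the lowest pixel decile", {
  expect_equal(estimate_background(matrix(0:99, 10)), 4.5)
  expect_equal(estimate_background(matrix(7, 5, 5)), 7)
  px <- withr::with_seed(1, stats::runif(500, 0, 200))
  oracle <- mean(sort(px)[1:50])   # full sort-and-slice
  expect_equal(estimate_background(px), oracle)
  expect_error(estimate_background(1:5), "at least 10")
})

test_that("ROI traces recover rendered disk intensities", {
  ds <- generate_dataset(synth_config(n_neurons = 4, n_sessions = 2,
                                      frames_per_session = 40, n_modules = 2,
                                      seed = 8))
  img <- render_image_stack(ds, session = 1, px = 48, radius = 2,
                            background = 10)
  tr <- extract_traces(img$stack, img$masks, frame_rate = ds$config$frame_rate,
                       f0 = ds$truth$f0)
  for (i in 1:4) {
    # direct pixel-average oracle for one frame
    pix <- img$masks[[i]]
    frame <- img$stack[, , 5]
    oracle <- mean(frame[pix]) - estimate_background(frame)
    expect_equal(tr[[i]]$F[5], oracle)
    # the rendered trace is fluorescence + background; after background
    # subtraction the recovered F tracks the neuron's own trace
    expect_gt(stats::cor(tr[[i]]$F, ds$fluorescence[i, 1, ]), 0.99)
  }
  # dF/F with known baseline: F = 2 F0 => dF/F = 1
  stack1 <- array(30, c(8, 8, 5)); stack1[1, 1:7, ] <- 0  # background pixels
  m <- list(cbind(4:5, 4:5))
  t1 <- extract_traces(stack1, m, frame_rate = 1, f0 = rep(15, 1))
  expect_equal(unique(round(t1[[1]]$dff, 10)), 1)
  expect_error(extract_traces(stack1, list(cbind(20, 2)), 1), "outside")
  expect_error(extract_traces(stack1, list(cbind(integer(), integer())), 1),
               "empty")
})

test_that("traces from disjoint independent sources are uncorrelated", {
  withr::with_seed(2, {
    stack <- array(10, c(16, 16, 500))
    s1 <- abs(stats::rnorm(500)); s2 <- abs(stats::rnorm(500))
    for (t in 1:500) {
      stack[3:5, 3:5, t] <- 10 + 20 * s1[t]
      stack[12:14, 12:14, t] <- 10 + 20 * s2[t]
    }
    m <- list(as.matrix(expand.grid(3:5, 3:5)),
              as.matrix(expand.grid(12:14, 12:14)))
    tr <- extract_traces(stack, m, frame_rate = 1, f0 = c(10, 10))
    expect_lt(abs(stats::cor(tr[[1]]$F, tr[[2]]$F)), 0.1)  # n = 500
  })
})

test_that("dF/F is invariant to joint multiplicative gain", {
  ds <- generate_dataset(synth_config(n_neurons = 2, n_sessions = 1,
                                      frames_per_session = 30, n_modules = 1,
                                      seed = 9))
  img <- render_image_stack(ds, px = 32)
  a <- extract_traces(img$stack, img$masks, 1, f0 = ds$truth$f0)
  b <- extract_traces(img$stack * 3, img$masks, 1, f0 = ds$truth$f0 * 3)
  expect_equal(a[[1]]$dff, b[[1]]$dff, tolerance = 1e-10)
})

test_that("burst detection measures triangle geometry exactly", {
  tr <- numeric(200)
  tr[51:70] <- c(seq(0.1, 1, length.out = 10), seq(0.9, 0, length.out = 10))
  ev <- detect_bursts(tr, frame_rate = 1, prominence = 0.3)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$amplitude, 1.0)
  expect_equal(ev$duration_s, 10)
  expect_lte(ev$onset_s, ev$peak_time_s)
  expect_equal(ev$polarity, 1)
})

test_that("quiet traces yield no events and NaN traces error", {
  withr::with_seed(3, {
    flat <- stats::rnorm(200, sd = 0.02)
    expect_equal(nrow(detect_bursts(flat, 1, prominence = 0.3)), 0)
  })
  expect_error(detect_bursts(rep(NA_real_, 50)), "NaN")
  expect_error(detect_bursts(1:10), "too short")
})

test_that("planted burst trains are recovered with accurate onsets", {
  withr::with_seed(4, {
    n <- 1000
    tr <- stats::rnorm(n, sd = 0.05)
    onsets <- seq(50, 950, by = 100)
    k <- burst_kernel("spiky", 20, 1, 1)
    for (o in onsets) {
      idx <- o:min(n, o + length(k) - 1)
      tr[idx] <- tr[idx] + k[seq_along(idx)]
    }
    ev <- detect_bursts(tr, frame_rate = 1, prominence = 0.4,
                        detect_negative = FALSE)
    # recall >= 0.9 with onset error < 2 frames
    hits <- vapply(onsets - 1, function(o) any(abs(ev$onset_s - o) < 2),
                   logical(1))
    expect_gte(mean(hits), 0.9)
  })
})

test_that("raising the prominence threshold never adds events", {
  withr::with_seed(5, {
    tr <- stats::rnorm(400, sd = 0.1)
    for (o in sample(350, 6)) {
      k <- burst_kernel("triangle", stats::runif(1, 10, 30),
                        stats::runif(1, 0.3, 1.5), 1)
      idx <- o:min(400, o + length(k) - 1)
      tr[idx] <- tr[idx] + k[seq_along(idx)]
    }
    counts <- vapply(c(0.2, 0.4, 0.6, 0.9), function(p)
      nrow(detect_bursts(tr, 1, prominence = p)), numeric(1))
    expect_true(all(diff(counts) <= 0))
  })
})

test_that("negative deflections are detected and flagged", {
  tr <- numeric(120)
  tr[41:60] <- -c(seq(0.1, 1, length.out = 10), seq(0.9, 0, length.out = 10))
  ev <- detect_bursts(tr, frame_rate = 1, prominence = 0.3)
  expect_equal(ev$polarity, -1)
  expect_equal(ev$amplitude, 1.0)
})

test_that("image stacks round-trip through multi-page TIFF", {
  st <- array(stats::runif(16 * 16 * 4, 0, 50), c(16, 16, 4))
  f <- tempfile(fileext = ".tif")
  sm <- write_stack_tiff(st, f)
  back <- read_stack_tiff(f, scale_max = sm)
  expect_equal(back, st, tolerance = 1e-3)
  unlink(f)
})
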