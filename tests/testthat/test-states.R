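test_that("the graph classifier learns the six archetypes", {
  tr <- withr::with_seed(10, archetype_set(15))
  aug <- withr::with_seed(11, augment_labeled_manifolds(tr$manifolds,
                                                        tr$labels))
  clf <- train_state_classifier(aug$manifolds, aug$labels, epochs = 160,
                                n_nodes = 80, seed = 0)
  te <- withr::with_seed(12, archetype_set(15))
  pr <- predict_states(clf, te$manifolds)
  acc <- mean(pr$state == te$labels)
  expect_gte(acc, 0.9)
  # must clearly beat chance and a nearest-centroid baseline on resampled
  # node coordinates
  Xtr <- t(sapply(tr$manifolds, function(m)
    as.numeric(scnca:::resample_rows(m$nodes, 40))))
  Xte <- t(sapply(te$manifolds, function(m)
    as.numeric(scnca:::resample_rows(m$nodes, 40))))
  cent <- sapply(1:6, function(k) colMeans(Xtr[tr$labels == k, ]))
  base <- mean(apply(Xte, 1, function(p)
    which.min(colSums((cent - p)^2))) == te$labels)
  expect_gt(acc, base)
  expect_gt(acc, 1 / 6)
  # training loss decreases overall
  lc <- clf$loss_curve
  expect_lt(mean(utils::tail(lc, 10)), mean(utils::head(lc, 10)))
  # class probabilities sum to one
  expect_equal(rowSums(as.matrix(pr[, -1])), rep(1, nrow(pr)),
               tolerance = 1e-8)

  # accuracy degrades monotonically with archetype noise (3-point check)
  acc_at <- function(noise) {
    s <- withr::with_seed(13, archetype_set(10, noise_sd = noise))
    mean(predict_states(clf, s$manifolds)$state == s$labels)
  }
  accs <- vapply(c(0.15, 0.8, 2.5), acc_at, numeric(1))
  expect_true(all(diff(accs) <= 0))

  # permuted labels leave held-out accuracy at chance
  perm <- withr::with_seed(14, sample(aug$labels))
  clf0 <- train_state_classifier(aug$manifolds, perm, epochs = 24,
                                 n_nodes = 80, seed = 0)
  acc0 <- mean(predict_states(clf0, te$manifolds)$state == te$labels)
  expect_lt(acc0, 0.35)

  expect_error(train_state_classifier(aug$manifolds[1:5], rep(1, 5)),
               "at least 2 classes")
})

test_that("classified states recover the planted session schedule", {
  # labeled material drawn from the generator's own session synthesizer
  # (the synthetic stand-in for manually labeled recordings), with the
  # irregular state over-represented as it is in the population
  ds <- small_dataset()
  cfg <- ds$config
  withr::with_seed(20, {
    mans <- list(); labs <- integer(0)
    counts <- c(8, 8, 8, 8, 8, 60)
    for (cls in 1:6) for (r in seq_len(counts[cls])) {
      spec <- list(rate = stats::rlnorm(1, -5.71, 0.73),
                   module = sample(3, 1))
      tr <- synthesize_session(spec, sample(0:7, 1), cfg,
                               state = cls)$dff
      mans[[length(mans) + 1]] <- embed_manifold(tr)
      labs <- c(labs, cls)
    }
  })
  aug <- withr::with_seed(21, augment_labeled_manifolds(mans, labs))
  clf <- train_state_classifier(aug$manifolds, aug$labels, epochs = 120,
                                n_nodes = 80, seed = 0)
  cl <- classify_states(ds, clf)
  expect_equal(unname(rowSums(cl$fractions)), rep(1, 8), tolerance = 1e-8)
  # the irregular archetype dominates every hour, mirroring its planted
  # prevalence
  expect_equal(unname(apply(cl$fractions, 1, which.max)), rep(6L, 8))
  expect_gte(mean(cl$states == ds$truth$states, na.rm = TRUE), 0.85)
})

test_that("a square-wave activity schedule gives exact mode boundaries", {
  prof <- matrix(rep(c(rep(0.5, 12), rep(0.05, 12)), each = 20), 20, 24,
                 byrow = FALSE)
  # shift each neuron's H window start to session 5 (0-based index 4)
  prof <- prof[, ((0:23 - 4) %% 24) + 1]
  ds <- profile_dataset(prof, noise_sd = 0.01, seed = 1)
  md <- assign_modes(ds, n_perm = 100)
  expect_true(all(md$h_start == 4))
  expect_true(all(md$mean_H > md$mean_L))
  mm <- attr(md, "mode_matrix")
  expect_equal(unname(rowSums(mm == "H")), rep(12, 20))
})

test_that("sinusoidal modulation at SNR 2 localizes boundaries within 1 h", {
  withr::with_seed(2, {
    n <- 60
    starts <- sample(0:23, n, replace = TRUE)
    amp <- 0.2
    # positive lobe spans h in [s0, s0+11], so the max-mean 12-session
    # window starts at s0
    prof <- t(sapply(starts, function(s0)
      amp * sin(2 * pi * ((0:23) - s0 + 0.5) / 24)))
    # session-mean noise after averaging 40 frames at SNR 2:
    # sd(profile)/sd(session-mean noise) = 2
    noise_sd <- stats::sd(prof[1, ]) / 2 * sqrt(40)
    ds <- profile_dataset(prof, n_frames = 40, noise_sd = noise_sd, seed = 3)
    md <- assign_modes(ds, n_perm = 50)
    err <- pmin((md$h_start - starts) %% 24, (starts - md$h_start) %% 24)
    expect_gte(mean(err <= 1), 0.9)
  })
})

test_that("without modulation the H/L split is rarely significant", {
  prof <- matrix(0, 40, 24)
  ds <- profile_dataset(prof, n_frames = 40, noise_sd = 0.3, seed = 4)
  md <- assign_modes(ds, n_perm = 200)
  expect_gte(mean(md$p_value >= 0.05), 0.9)
})

test_that("mode assignment requires complete even session sets", {
  ds <- small_dataset()
  ds$fluorescence <- ds$fluorescence[, 1:7, , drop = FALSE]
  expect_error(assign_modes(ds), "even number")
})
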