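test_that("timestamp masks keep half the timestamps on average", {
  m <- withr::with_seed(0, matrix(timestamp_mask(1e4 * 200), 1e4))
  frac_masked <- mean(m == 0)
  se <- sqrt(0.25 / length(m))
  expect_lt(abs(frac_masked - 0.5), 3 * se)
  expect_true(all(m %in% 0:1))
})

test_that("the view sampler keeps positives and negatives balanced", {
  v <- withr::with_seed(1, make_contrastive_views(matrix(stats::rnorm(600),
                                                         6)))
  expect_identical(nrow(v$positives), nrow(v$negatives))
  for (vw in v$views) {
    expect_gt(length(vw$overlap), 0)
    expect_true(all(vw$tags %in% c("crop", "mask", "noise",
                                   "wavelet-highpass")))
  }
  # negatives differ from their positive in neuron or timestamp
  same <- v$positives$neuron == v$negatives$neuron &
          v$positives$timestamp == v$negatives$timestamp
  expect_false(any(same))
  expect_error(make_contrastive_views(matrix(1, 2, 8)), "T' >= 16")
})

test_that("wavelet high-pass removes slow oscillations", {
  x <- sin(2 * pi * (1:256) / 128)
  hp <- wavelet_detail(x)
  expect_lt(sum(hp^2) / sum(x^2), 0.05)
  expect_length(hp, 256)
  # fast content survives
  f <- withr::with_seed(2, stats::rnorm(256))
  expect_gt(sum(wavelet_detail(f)^2) / sum(f^2), 0.5)
  # odd lengths are handled
  expect_length(wavelet_detail(x[1:255]), 255)
})

test_that("the encoder is deterministic and honors masking", {
  withr::with_seed(3, {
    p <- scnca:::enc_init(hidden = 8, out = 12, blocks = 10)
    X <- matrix(stats::rnorm(4 * 600), 4)
    z1 <- encode_traces(p, X)$Z
    z2 <- encode_traces(p, X)$Z
    expect_identical(z1, z2)
    # fully masked input ignores the signal values
    mask0 <- matrix(0L, 4, 600)
    za <- encode_traces(p, X, mask = mask0)$Z
    zb <- encode_traces(p, X * 5 + 2, mask = mask0)$Z
    expect_equal(za, zb, tolerance = 1e-10)
    # receptive field after ten dilated blocks spans >= 2^10 - 1 frames:
    # an impulse at t=1 reaches the latent at t=600
    X0 <- matrix(0, 1, 600)
    X1 <- X0; X1[1, 1] <- 1
    d <- abs(encode_traces(p, X1)$Z[1, 600, ] -
             encode_traces(p, X0)$Z[1, 600, ])
    expect_gt(max(d), 0)
  })
})

test_that("the hierarchical loss prefers aligned positives", {
  # hand-built embeddings: positives identical, negatives orthogonal
  z1 <- array(0, c(2, 2, 4)); z2 <- array(0, c(2, 2, 4))
  basis <- diag(4) * 2
  for (b in 1:2) for (t in 1:2) {
    v <- basis[(b - 1) * 2 + t, ]
    z1[b, t, ] <- v
    z2[b, t, ] <- v          # positive pairs identical
  }
  good <- hierarchical_contrastive_loss(z1, z2, want_grad = FALSE)$loss
  # swap positive/negative roles: pair each embedding with a different
  # timestamp's embedding
  z2_swapped <- z2[, 2:1, , drop = FALSE]
  bad <- hierarchical_contrastive_loss(z1, z2_swapped,
                                       want_grad = FALSE)$loss
  expect_lt(good, bad)
})

test_that("identical embeddings give the closed-form uniform-softmax loss", {
  B <- 3; Tn <- 4; D <- 5
  z <- array(1 / sqrt(D), c(B, Tn, D))
  out <- hierarchical_contrastive_loss(z, z, want_grad = FALSE)
  # every candidate has equal similarity, so each softmax is uniform over
  # (2n - 1) candidates; mean the temporal and instance terms over the
  # pyramid levels (T = 4, 2, 1)
  level_loss <- function(Tl) {
    lt <- if (Tl > 1) log(2 * Tl - 1) else 0
    li <- log(2 * B - 1)
    (lt + li) / ((Tl > 1) + 1)
  }
  expected <- mean(c(level_loss(4), level_loss(2), level_loss(1)))
  expect_equal(out$loss, expected, tolerance = 1e-10)
})

test_that("the loss is invariant to joint rotations of the embeddings", {
  withr::with_seed(4, {
    z1 <- array(stats::rnorm(2 * 4 * 6), c(2, 4, 6))
    z2 <- array(stats::rnorm(2 * 4 * 6), c(2, 4, 6))
    Q <- qr.Q(qr(matrix(stats::rnorm(36), 6)))
    rot <- function(z) {
      d <- dim(z)
      array(matrix(z, d[1] * d[2], d[3]) %*% Q, d)
    }
    # the dual dot-product loss at a single scale is rotation invariant
    # (the pyramid's elementwise max pooling is coordinate-dependent)
    l0 <- scnca:::dual_contrastive_level(z1, z2, want_grad = FALSE)$loss
    l1 <- scnca:::dual_contrastive_level(rot(z1), rot(z2),
                                         want_grad = FALSE)$loss
    expect_equal(l0, l1, tolerance = 1e-9)
  })
})

test_that("loss gradients match finite differences", {
  withr::with_seed(5, {
    z1 <- array(stats::rnorm(2 * 4 * 3, sd = 0.5), c(2, 4, 3))
    z2 <- array(stats::rnorm(2 * 4 * 3, sd = 0.5), c(2, 4, 3))
    hl <- hierarchical_contrastive_loss(z1, z2)
    eps <- 1e-6
    for (probe in list(c(1, 2, 3), c(2, 4, 1))) {
      zp <- z1; zp[probe[1], probe[2], probe[3]] <- zp[probe[1], probe[2],
                                                      probe[3]] + eps
      zm <- z1; zm[probe[1], probe[2], probe[3]] <- zm[probe[1], probe[2],
                                                      probe[3]] - eps
      num <- (hierarchical_contrastive_loss(zp, z2, want_grad = FALSE)$loss -
              hierarchical_contrastive_loss(zm, z2,
                                            want_grad = FALSE)$loss) /
             (2 * eps)
      expect_equal(hl$dz1[probe[1], probe[2], probe[3]], num,
                   tolerance = 1e-5)
    }
  })
})

test_that("encoder training converges and separates trace identities", {
  ds <- module_fixture()$ds
  enc <- module_fixture()$enc
  lc <- enc$loss_curve
  expect_lt(utils::tail(lc, 1), lc[1])
  # identical traces map to nearly identical representations
  ser <- dataset_series(ds)[1:10, ]
  ser2 <- rbind(ser, ser[1, , drop = FALSE])
  reps <- scnca:::representations_from(enc$params, ser2)
  dup <- sqrt(sum((reps[11, ] - reps[1, ])^2))
  spread <- stats::median(as.matrix(stats::dist(reps[1:10, ])))
  expect_lt(dup, 1e-8 + 0.01 * spread)
  expect_error(train_encoder(ser[1, , drop = FALSE]), "at least 2")
})

test_that("representations carry more usable module signal than raw traces", {
  fx <- module_fixture()
  reps <- apply(fx$enc$representations, 2, rank)
  truth <- fx$ds$truth$module
  ser <- dataset_series(fx$ds)
  # supervised linear probe (LDA on leading PCs, repeated splits): the
  # representations must be at least as decodable as the raw series
  probe_acc <- function(X) {
    X <- scale(X)
    X <- X[, apply(X, 2, function(c) all(is.finite(c))), drop = FALSE]
    pcs <- stats::prcomp(X)$x[, 1:6, drop = FALSE]
    accs <- vapply(1:10, function(r) withr::with_seed(r, {
      tr <- sample(nrow(X), 32)
      ld <- MASS::lda(pcs[tr, ], grouping = truth[tr])
      mean(stats::predict(ld, pcs[-tr, ])$class == truth[-tr])
    }), numeric(1))
    mean(accs)
  }
  expect_gte(probe_acc(reps), probe_acc(ser) - 0.02)
  # unsupervised recovery is where the representations clearly win
  ari_reps <- mclust::adjustedRandIndex(
    cluster_subtypes(fx$enc$representations, K = 3, seed = 0)$labels[, 1],
    truth)
  km_raw <- withr::with_seed(7, stats::kmeans(ser, 3, nstart = 10)$cluster)
  ari_raw <- mclust::adjustedRandIndex(km_raw, truth)
  expect_gt(ari_reps, ari_raw)
})
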