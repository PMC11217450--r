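#' Generate bilaterally mirrored SCN neuron positions with concentric modules
#'
#' Places neurons uniformly inside two ellipsoidal nuclei mirrored about the
#' midline (x = 0), and assigns each neuron to one of `n_modules` concentric
#' spatial modules by banding the distance to a ventrolateral anchor point.
#' Modules therefore form ripple-like bands running from the ventrolateral
#' pole (module 1) to the dorsomedial pole (module `n_modules`). Mirrored
#' partners share their module id exactly; mirrored coordinates carry a small
#' Gaussian jitter (sigma = 5 um) so the symmetry is realistic rather than
#' exact.
#'
#' Axes convention: x mediolateral (midline at 0), y dorsoventral (ventral
#' negative), z rostrocaudal. Units are micrometers.
#'
#' @param config an [synth_config()] object (only `n_neurons`, `n_modules`
#'   and `seed` are used here).
#' @param mirror_jitter_sd SD (um) of the jitter applied to mirrored copies.
#' @return list with `positions` (matrix \[N x 3\]), `module` (integer
#'   vector of module ids in 1..n_modules), `side` (factor `"left"`/
#'   `"right"`), `pair` (index of each neuron's mirror partner), and
#'   `anchor` (the right-side ventrolateral anchor point).
#' @export
generate_geometry <- function(config, mirror_jitter_sd = 5) {
  stopifnot(inherits(config, "scn_synth_config"))
  n <- config$n_neurons
  k <- config$n_modules
  if (n < 2 * k) stop("invalid config: n_neurons must be at least 2 * n_modules")
  with_seed(config$seed + 101L, {
    semi <- c(130, 160, 100)           # ellipsoid semi-axes (um)
    center_r <- c(170, 0, 0)           # right nucleus center
    n_r <- ceiling(n / 2)
    # uniform sampling in an ellipsoid by rejection from the bounding box
    pts <- matrix(NA_real_, n_r, 3)
    got <- 0L
    while (got < n_r) {
      m <- 2L * (n_r - got) + 16L
      cand <- cbind(stats::runif(m, -1, 1), stats::runif(m, -1, 1),
                    stats::runif(m, -1, 1))
      keep <- rowSums(cand^2) <= 1
      cand <- cand[keep, , drop = FALSE]
      take <- min(nrow(cand), n_r - got)
      if (take > 0)
        pts[(got + 1):(got + take), ] <- cand[seq_len(take), , drop = FALSE]
      got <- got + take
    }
    pts <- sweep(pts, 2, semi, `*`)
    pts_r <- sweep(pts, 2, center_r, `+`)
    # ventrolateral anchor of the right nucleus: lateral and ventral pole
    anchor <- center_r + c(0.8 * semi[1], -0.8 * semi[2], 0)
    d <- sqrt(rowSums(sweep(pts_r, 2, anchor)^2))
    # "area": equal-width distance bands => band populations follow band
    # area; "equal": equal-frequency bands => equal module populations
    br <- if (identical(config$module_banding, "equal"))
      stats::quantile(d, seq(0, 1, length.out = k + 1), names = FALSE)
    else seq(min(d), max(d), length.out = k + 1)
    module_r <- pmin(pmax(findInterval(d, br, rightmost.closed = TRUE), 1L), k)
    # guarantee every module is populated (tiny n edge case)
    for (m in seq_len(k)) {
      if (!any(module_r == m)) {
        idx <- which.min(abs(d - (br[m] + br[m + 1]) / 2))
        module_r[idx] <- m
      }
    }
    n_l <- n - n_r
    mirror_idx <- seq_len(n_l)
    pts_l <- pts_r[mirror_idx, , drop = FALSE]
    pts_l[, 1] <- -pts_l[, 1]
    pts_l <- pts_l + matrix(stats::rnorm(3 * n_l, sd = mirror_jitter_sd),
                            n_l, 3)
    positions <- rbind(pts_r, pts_l)
    module <- c(module_r, module_r[mirror_idx])
    side <- c(rep("right", n_r), rep("left", n_l))
    pair <- c(ifelse(seq_len(n_r) <= n_l, n_r + seq_len(n_r), NA_integer_),
              mirror_idx)
    list(positions = positions, module = as.integer(module),
         side = factor(side, levels = c("left", "right")),
         pair = as.integer(pair), anchor = anchor)
  })
}
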