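## Phase-wave-of-hyperactivity detection on spatial intensity map series:
## Gaussian smoothing, per-frame mean normalization, second time
## derivative thresholding ("excited" pixels), and wavefront tracing.

#' Hourly intensity maps of a dataset
#'
#' Bins neurons on an x-y pixel grid and averages each session's mean
#' dF/F per cell, producing one spatial intensity image per hour.
#'
#' @param dataset an `scn_dataset`.
#' @param px grid side length in pixels.
#' @return array \[px x px x S\]; empty cells hold the global mean level.
#' @export
hourly_intensity_maps <- function(dataset, px = 48) {
  stopifnot(inherits(dataset, "scn_dataset"))
  d <- dim(dataset$fluorescence)
  xy <- dataset$positions[, 1:2, drop = FALSE]
  gx <- cut(xy[, 1], px, labels = FALSE)
  gy <- cut(xy[, 2], px, labels = FALSE)
  cell <- gx + (gy - 1L) * px
  out <- array(0, c(px, px, d[2]))
  for (s in seq_len(d[2])) {
    amp <- rowMeans(session_dff(dataset, s))
    m <- tapply(amp, cell, mean)
    img <- rep(mean(amp), px * px)
    img[as.integer(names(m))] <- m
    out[, , s] <- matrix(img, px, px)
  }
  out
}

#' Detect excited pixels in an image series
#'
#' Each frame is Gaussian-smoothed (sigma in pixels), normalized by its
#' mean pixel value, and differentiated twice in time with central
#' differences; pixels whose second derivative exceeds the threshold are
#' marked excited. The default threshold is the 97.5th percentile of the
#' second-derivative distribution.
#'
#' @param images array \[H x W x T\] with T >= 3.
#' @param sigma Gaussian smoothing sigma (pixels).
#' @param threshold absolute threshold on the second derivative; `NULL`
#'   uses the `quantile_p` percentile.
#' @param quantile_p percentile used when `threshold` is `NULL`.
#' @return `scn_excitation` list: `excited` (logical \[H x W x T\], all
#'   `FALSE` at the first/last frame), `d2` (second derivative),
#'   `threshold`, `normalized` (smoothed, mean-normalized frames).
#' @export
detect_excited <- function(images, sigma = 3.5, threshold = NULL,
                           quantile_p = 0.975) {
  stopifnot(length(dim(images)) == 3)
  d <- dim(images)
  if (d[3] < 3) stop("need at least 3 frames")
  sm <- array(0, d)
  for (t in seq_len(d[3])) {
    if (abs(mean(images[, , t])) < 1e-12)
      stop("zero-mean layer: cannot normalize frame ", t)
    fr <- EBImage::gblur(images[, , t], sigma = sigma)
    mu <- mean(fr)
    if (abs(mu) < 1e-12) stop("zero-mean layer: cannot normalize frame ", t)
    sm[, , t] <- fr / mu
  }
  d2 <- array(0, d)
  d2[, , 2:(d[3] - 1)] <- sm[, , 3:d[3]] - 2 * sm[, , 2:(d[3] - 1)] +
    sm[, , 1:(d[3] - 2)]
  if (is.null(threshold))
    threshold <- stats::quantile(d2[, , 2:(d[3] - 1)], quantile_p,
                                 names = FALSE)
  excited <- d2 > threshold
  excited[, , c(1, d[3])] <- FALSE
  res <- list(excited = excited, d2 = d2, threshold = threshold,
              normalized = sm)
  class(res) <- "scn_excitation"
  res
}

#' Trace the wavefront of an excitation map
#'
#' Collects the excited-pixel set of every frame, computes per-frame
#' centroids and boundary contours, and fits the centroid trajectory by
#' least squares to estimate propagation speed and direction. When the
#' centroid barely moves (simultaneous global excitation) the direction is
#' flagged undefined.
#'
#' @param excitation an `scn_excitation` (or logical array \[H x W x T\]).
#' @param min_pixels frames with fewer excited pixels are skipped.
#' @return list with `front` (data.frame: frame, n_pixels, cx, cy),
#'   `contours` (per-frame boundary pixel coordinates), `velocity`
#'   (vx, vy per frame), `speed` (pixels/frame), `direction` (unit
#'   vector, or NA), `undefined` (logical flag).
#' @export
trace_wavefront <- function(excitation, min_pixels = 1) {
  masks <- if (inherits(excitation, "scn_excitation")) excitation$excited
           else excitation
  d <- dim(masks)
  rows <- list(); contours <- list()
  for (t in seq_len(d[3])) {
    idx <- which(masks[, , t], arr.ind = TRUE)
    if (nrow(idx) < min_pixels) next
    rows[[length(rows) + 1]] <- data.frame(frame = t, n_pixels = nrow(idx),
                                           cx = mean(idx[, 1]),
                                           cy = mean(idx[, 2]))
    m <- masks[, , t]
    interior <- m
    interior[2:(d[1] - 1), 2:(d[2] - 1)] <-
      m[2:(d[1] - 1), 2:(d[2] - 1)] &
      m[1:(d[1] - 2), 2:(d[2] - 1)] & m[3:d[1], 2:(d[2] - 1)] &
      m[2:(d[1] - 1), 1:(d[2] - 2)] & m[2:(d[1] - 1), 3:d[2]]
    contours[[as.character(t)]] <- which(m & !interior, arr.ind = TRUE)
  }
  front <- do.call(rbind, rows)
  if (is.null(front) || nrow(front) < 2)
    stop("wavefront undefined: excited pixels in fewer than 2 frames")
  # the excitation outlines lead and trail the wave crest; frames where
  # only one lobe crosses threshold are off-track, so fit robustly
  rfit <- function(y) {
    f <- tryCatch(suppressWarnings(
                    MASS::rlm(y ~ front$frame, weights = front$n_pixels,
                              maxit = 50)),
                  error = function(e) stats::lm(y ~ front$frame,
                                                weights = front$n_pixels))
    unname(stats::coef(f)[2])
  }
  v <- c(vx = rfit(front$cx), vy = rfit(front$cy))
  speed <- sqrt(sum(v^2))
  spread <- stats::sd(front$frame)
  undefined <- speed < 1e-6 || spread < 1e-9
  direction <- if (undefined) c(NA_real_, NA_real_) else v / speed
  list(front = front, contours = contours, velocity = v, speed = speed,
       direction = direction, undefined = undefined)
}
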