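## Bespoke parts of the image-to-trace pipeline: background rule, ROI trace
## extraction, dF/F baselines, and the stand-in burst detector that replaces
## model-based spike inference while keeping the same attribute definitions
## (peak dF/F amplitude, FWHM duration).

#' Estimate the background fluorescence of an image frame
#'
#' The background is the mean of the lowest 10% of pixel intensities.
#'
#' @param frame numeric matrix or vector of pixel intensities.
#' @return scalar background estimate.
#' @export
estimate_background <- function(frame) {
  px <- as.numeric(frame)
  px <- px[!is.na(px)]
  if (length(px) < 10) stop("need at least 10 pixels to estimate background")
  k <- max(1L, floor(length(px) / 10))
  mean(sort(px, partial = k)[seq_len(k)])
}

# Rolling-percentile baseline: 20th percentile in a centered 60-s window.
rolling_baseline <- function(f, frame_rate, window_s = 60, p = 0.2) {
  n <- length(f)
  w <- max(3L, round(window_s * frame_rate))
  half <- w %/% 2
  out <- numeric(n)
  for (i in seq_len(n)) {
    lo <- max(1L, i - half); hi <- min(n, i + half)
    out[i] <- stats::quantile(f[lo:hi], p, names = FALSE, type = 7)
  }
  out
}

#' Extract background-subtracted ROI traces from an image stack
#'
#' For every ROI mask and frame computes F = mean(F_raw pixels) - F_bg,
#' where F_bg is the frame's lowest-decile background. dF/F uses the
#' supplied per-trace baseline `f0` when known, otherwise a rolling
#' 20th-percentile baseline over a 60-s window.
#'
#' @param stack array \[H x W x T\].
#' @param masks list of ROI pixel-index matrices (columns x, y).
#' @param frame_rate frames per second.
#' @param f0 optional numeric vector of known per-ROI baselines.
#' @return list of `scn_trace` objects with fields `F` (background-
#'   subtracted a.u.), `F0` (baseline), `dff`, `t` (s).
#' @export
extract_traces <- function(stack, masks, frame_rate, f0 = NULL) {
  stopifnot(length(dim(stack)) == 3)
  h <- dim(stack)[1]; w <- dim(stack)[2]; nT <- dim(stack)[3]
  bg <- vapply(seq_len(nT), function(t) estimate_background(stack[, , t]),
               numeric(1))
  lapply(seq_along(masks), function(i) {
    pix <- masks[[i]]
    if (nrow(pix) == 0) stop("empty ROI mask")
    if (any(pix[, 1] < 1 | pix[, 1] > h | pix[, 2] < 1 | pix[, 2] > w))
      stop("ROI mask outside image bounds")
    lin <- (pix[, 2] - 1L) * h + pix[, 1]
    m <- matrix(stack, h * w, nT)[lin, , drop = FALSE]
    f <- colMeans(m) - bg
    base <- if (!is.null(f0)) rep(f0[i], nT)
            else rolling_baseline(f, frame_rate)
    dff <- ifelse(base > 0, (f - base) / base, NA_real_)
    structure(list(F = f, F0 = base, dff = dff,
                   t = (seq_len(nT) - 1) / frame_rate),
              class = "scn_trace")
  })
}

# Local maxima of a numeric vector (strictly greater than one neighbor,
# >= the other, plateaus take the first index).
local_maxima <- function(x) {
  n <- length(x)
  if (n < 3) return(integer())
  which(x[2:(n - 1)] >= x[1:(n - 2)] & x[2:(n - 1)] > x[3:n]) + 1L
}

# Topographic prominence of peak at index i: height above the higher of
# the two key saddles toward the nearest higher terrain (or the edge).
peak_prominence <- function(x, i) {
  n <- length(x)
  left <- if (i == 1) x[1] else {
    j <- i - 1; lo <- x[i]
    while (j >= 1 && x[j] <= x[i]) { lo <- min(lo, x[j]); j <- j - 1 }
    if (j >= 1) lo else min(x[1:i])
  }
  right <- if (i == n) x[n] else {
    j <- i + 1; lo <- x[i]
    while (j <= n && x[j] <= x[i]) { lo <- min(lo, x[j]); j <- j + 1 }
    if (j <= n) lo else min(x[i:n])
  }
  x[i] - max(left, right)
}

# Interpolated crossing of `level` walking from peak index `i` in
# direction `dir` (-1 left, +1 right); returns fractional frame index.
half_crossing <- function(x, i, level, dir) {
  n <- length(x)
  j <- i
  while (j + dir >= 1 && j + dir <= n && x[j + dir] > level) j <- j + dir
  k <- j + dir
  if (k < 1 || k > n) return(NA_real_)
  # linear interpolation between frames j and k
  j + dir * (x[j] - level) / (x[j] - x[k])
}

#' Detect calcium bursts in a dF/F trace
#'
#' Stand-in burst detector: peaks are found on a moving-average smoothed
#' copy of the trace and filtered by topographic prominence; amplitude
#' (peak dF/F above the local base) and FWHM duration (half-maximum
#' crossings with linear interpolation) are then measured on the raw
#' trace. Negative-polarity deflections are detected symmetrically on the
#' sign-flipped trace and flagged.
#'
#' @param trace numeric dF/F vector or an `scn_trace` object.
#' @param frame_rate frames per second (ignored if `trace` is `scn_trace`).
#' @param prominence minimum peak prominence (dF/F units).
#' @param smooth_w moving-average width (frames) for peak finding.
#' @param detect_negative also search the flipped trace.
#' @param onset_frac fraction of amplitude above base defining burst onset.
#' @return data.frame of events sorted by onset: `onset_s`, `peak_time_s`,
#'   `amplitude`, `duration_s` (FWHM), `polarity` (+1/-1).
#' @export
detect_bursts <- function(trace, frame_rate = 0.67, prominence = 0.3,
                          smooth_w = 5, detect_negative = TRUE,
                          onset_frac = 0.1) {
  if (inherits(trace, "scn_trace")) {
    frame_rate <- 1 / diff(trace$t[1:2])
    trace <- trace$dff
  }
  if (all(is.na(trace))) stop("all-NaN trace")
  if (length(trace) < 16) stop("trace too short for burst detection")
  scan <- function(x, pol) {
    sm <- as.numeric(stats::filter(x, rep(1 / smooth_w, smooth_w),
                                   sides = 2))
    sm[is.na(sm)] <- x[is.na(sm)]
    cand <- local_maxima(sm)
    keep <- cand[vapply(cand, function(i) peak_prominence(sm, i),
                        numeric(1)) >= prominence]
    if (length(keep) == 0)
      return(data.frame(onset_s = numeric(), peak_time_s = numeric(),
                        amplitude = numeric(), duration_s = numeric(),
                        polarity = numeric()))
    rows <- lapply(keep, function(i) {
      # refine peak on the raw trace near the smoothed peak
      lo <- max(1L, i - smooth_w); hi <- min(length(x), i + smooth_w)
      ip <- lo - 1L + which.max(x[lo:hi])
      base <- x[ip] - peak_prominence(x, ip)
      amp <- x[ip] - base
      if (amp < prominence) return(NULL)
      half <- base + amp / 2
      l <- half_crossing(x, ip, half, -1L)
      r <- half_crossing(x, ip, half, +1L)
      if (is.na(l) || is.na(r)) return(NULL)
      on <- half_crossing(x, ip, base + onset_frac * amp, -1L)
      if (is.na(on)) on <- l
      data.frame(onset_s = (on - 1) / frame_rate,
                 peak_time_s = (ip - 1) / frame_rate,
                 amplitude = pol * amp,
                 duration_s = (r - l) / frame_rate,
                 polarity = pol)
    })
    do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  }
  ev <- scan(trace, +1)
  if (detect_negative) {
    neg <- scan(-trace, -1)
    if (!is.null(neg) && nrow(neg) > 0) ev <- rbind(ev, neg)
  }
  if (is.null(ev) || nrow(ev) == 0)
    return(data.frame(onset_s = numeric(), peak_time_s = numeric(),
                      amplitude = numeric(), duration_s = numeric(),
                      polarity = numeric()))
  ev$amplitude <- abs(ev$amplitude)
  ev <- ev[order(ev$onset_s), , drop = FALSE]
  rownames(ev) <- NULL
  ev
}

#' Write / read an image stack as multi-page TIFF
#'
#' Intensities are scaled to \[0, 1\] by `scale_max` on write and restored
#' on read.
#'
#' @param stack array \[H x W x T\].
#' @param path file path.
#' @param scale_max intensity mapped to white (default: stack maximum).
#' @return `write_stack_tiff` returns `scale_max` invisibly;
#'   `read_stack_tiff` the array \[H x W x T\].
#' @export
write_stack_tiff <- function(stack, path, scale_max = max(stack)) {
  pages <- lapply(seq_len(dim(stack)[3]), function(t)
    pmin(pmax(stack[, , t] / scale_max, 0), 1))
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(scale_max)
}

#' @rdname write_stack_tiff
#' @export
read_stack_tiff <- function(path, scale_max = 1) {
  pages <- tiff::readTIFF(path, all = TRUE)
  array(unlist(pages), c(dim(pages[[1]]), length(pages))) * scale_max
}
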