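#' @keywords internal
"_PACKAGE"

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' Wrap an angle into (-180, 180] degrees
#' @param x angle(s) in degrees.
#' @return angle(s) wrapped to the half-open interval (-180, 180].
#' @export
wrap_phase <- function(x) {
  w <- ((x + 180) %% 360) - 180
  w[w == -180] <- 180
  w
}

## Convert a logical per-sample mask into a table of half-open time intervals
## [start, end). `t` must be uniform; the interval end is the time just past
## the last TRUE sample.
runs_to_intervals <- function(mask, t) {
  mask[is.na(mask)] <- FALSE
  if (!any(mask)) {
    return(data.frame(start = numeric(0), end = numeric(0)))
  }
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  dt <- if (length(t) > 1) t[2] - t[1] else 0
  data.frame(start = t[starts[keep]], end = t[ends[keep]] + dt)
}

## Inverse of runs_to_intervals: TRUE where t falls in any [start, end).
intervals_to_mask <- function(intervals, t) {
  mask <- logical(length(t))
  if (is.null(intervals) || nrow(intervals) == 0) return(mask)
  for (i in seq_len(nrow(intervals))) {
    mask <- mask | (t >= intervals$start[i] & t < intervals$end[i])
  }
  mask
}

## Merge overlapping/adjacent intervals, optionally after padding both ends.
merge_intervals <- function(intervals, pad = 0) {
  if (is.null(intervals) || nrow(intervals) == 0) return(intervals)
  iv <- intervals[order(intervals$start), , drop = FALSE]
  iv$start <- iv$start - pad
  iv$end <- iv$end + pad
  out_s <- iv$start[1]
  out_e <- iv$end[1]
  if (nrow(iv) > 1) {
    for (i in 2:nrow(iv)) {
      k <- length(out_s)
      if (iv$start[i] <= out_e[k]) {
        out_e[k] <- max(out_e[k], iv$end[i])
      } else {
        out_s <- c(out_s, iv$start[i])
        out_e <- c(out_e, iv$end[i])
      }
    }
  }
  data.frame(start = out_s, end = out_e)
}

#' Low-pass differentiating filter for sampled eye-position signals
#'
#' Differentiates a uniformly sampled signal with a Savitzky-Golay polynomial
#' window, the standard way to obtain eye velocity from video-oculography
#' position traces without amplifying quantization steps and pixel noise.
#' Missing samples are bridged by linear interpolation before filtering and
#' restored to `NA` afterwards.
#'
#' @param x numeric signal (degrees).
#' @param sample_rate samples per second.
#' @param window odd filter length in samples (default 21 at 500 samples/s,
#'   i.e. a 42 ms window).
#' @param order polynomial order (default 3).
#' @return numeric vector of the same length: the signal's time derivative in
#'   units of `x` per second.
#' @export
sg_velocity <- function(x, sample_rate, window = 21L, order = 3L) {
  stopifnot(length(x) > window, window %% 2 == 1, order < window)
  nas <- is.na(x)
  xi <- x
  if (any(nas)) {
    ok <- which(!nas)
    if (length(ok) < 2) stop("signal has fewer than two finite samples")
    xi[nas] <- stats::approx(ok, x[ok], xout = which(nas), rule = 2)$y
  }
  v <- signal::sgolayfilt(xi, p = order, n = window, m = 1) * sample_rate
  v[nas] <- NA_real_
  v
}

## Weighted least-squares fit of y ~ A sin(theta) + B cos(theta) + C.
## Returns coefficients plus amplitude |Y| = sqrt(A^2 + B^2) and the phase of
## the equivalent sinusoid amp * sin(theta + phase) in degrees.
fit_sinusoid <- function(theta, y, w = NULL) {
  keep <- is.finite(theta) & is.finite(y)
  if (!is.null(w)) keep <- keep & is.finite(w) & w > 0
  theta <- theta[keep]
  y <- y[keep]
  if (length(y) < 4) stop("too few samples for sinusoidal regression")
  X <- cbind(s = sin(theta), c = cos(theta))
  fit <- if (is.null(w)) {
    stats::lm.fit(cbind(X, 1), y)
  } else {
    stats::lm.wfit(cbind(X, 1), y, w = w[keep])
  }
  cf <- fit$coefficients
  A <- unname(cf[1]); B <- unname(cf[2]); C <- unname(cf[3])
  list(A = A, B = B, C = C,
       amplitude = sqrt(A^2 + B^2),
       phase = rad2deg(atan2(B, A)))
}
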