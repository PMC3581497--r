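#' Estimate the pupil-to-rotation-center distance from a camera-yaw sweep
#'
#' When the oculography camera is yawed by a known angle about a vertical
#' axis through the recorded eye, the pupil image is displaced by
#' `Rp * sin(angle)`, where `Rp` is the effective distance from the pupil to
#' the eye's rotation center in camera position units. `estimate_rp` fits
#' that model by least squares (an intercept absorbs any reference offset)
#' and returns `Rp` with fit diagnostics.
#'
#' @param sweep `data.frame` with columns `camera_angle` (degrees) and
#'   `pupil_displacement` (camera units), e.g. from
#'   [simulate_calibration_sweep()].
#' @return an object of class `oculo_rp`: list with `value` (Rp), `offset`
#'   (fitted intercept), `residual_sd`, `r_squared`, `n`.
#' @examples
#' sweep <- simulate_calibration_sweep(1.2, c(-10, -5, 0, 5, 10))
#' estimate_rp(sweep)
#' @export
estimate_rp <- function(sweep) {
  stopifnot(is.data.frame(sweep),
            all(c("camera_angle", "pupil_displacement") %in% names(sweep)))
  sweep <- sweep[is.finite(sweep$camera_angle) &
                   is.finite(sweep$pupil_displacement), ]
  if (nrow(sweep) < 2 || length(unique(sweep$camera_angle)) < 2) {
    stop("degenerate calibration sweep: need at least two distinct camera angles")
  }
  s <- sin(deg2rad(sweep$camera_angle))
  fit <- stats::lm(sweep$pupil_displacement ~ s)
  slope <- unname(stats::coef(fit)[2])
  if (!is.finite(slope) || slope <= 0) {
    stop("fitted calibration slope is not positive; check the sign convention ",
         "of the pupil displacement channel (displacement should increase ",
         "with camera yaw angle)")
  }
  res <- stats::residuals(fit)
  ssr <- sum(res^2)
  sst <- sum((sweep$pupil_displacement - mean(sweep$pupil_displacement))^2)
  structure(list(value = slope,
                 offset = unname(stats::coef(fit)[1]),
                 residual_sd = if (nrow(sweep) > 2) {
                   sqrt(ssr / (nrow(sweep) - 2))
                 } else 0,
                 r_squared = if (sst > 0) 1 - ssr / sst else NA_real_,
                 n = nrow(sweep)),
            class = "oculo_rp")
}

#' @export
print.oculo_rp <- function(x, ...) {
  cat(sprintf("<oculo_rp> Rp = %.4g camera units/sin(deg) (n = %d, residual SD %.3g)\n",
              x$value, x$n, x$residual_sd))
  invisible(x)
}

#' Convert raw pupil positions to angular eye position
#'
#' Inverts the spherical camera model: vertical eye angle (head frame)
#' `v = asin((pupil_v - ref_v) / Rp)` and horizontal angle
#' `h = asin((pupil_h - ref_h) / (Rp * cos(v)))` -- the cos(v) factor is the
#' vertical-position correction of the horizontal angle, needed because a
#' raised or lowered eye forecloses part of the horizontal projection. The
#' head-mount pitch (`pitch_offset` degrees nose-down) is then added so the
#' vertical angle is expressed as elevation relative to the earth-horizontal
#' plane. When corneal-reflection channels are present they are subtracted
#' from the pupil channels first (removing camera-translation artifacts)
#' unless `use_cr = FALSE`.
#'
#' Samples whose asin argument reaches magnitude 1, or with missing pupil
#' data, are flagged invalid rather than clipped.
#'
#' @param rec an `oculo_record` (or any list with `$samples`,
#'   `$sample_rate`).
#' @param rp an `oculo_rp` from [estimate_rp()], or a positive number. If
#'   `NULL`, the record's embedded calibration (simulated records) is used.
#' @param reference named camera-unit reference position `c(h =, v =)`;
#'   defaults to the record's embedded calibration.
#' @param pitch_offset head-mount pitch, degrees nose-down.
#' @param use_cr subtract corneal-reflection channels before calibration.
#' @param correct_vertical apply the cos(v) correction to the horizontal
#'   angle (disable only to demonstrate the resulting downward bias of
#'   `|h|`).
#' @return an `oculo_trace`: list with `$samples`
#'   (`t`, `h`, `v`, `valid`), `$sample_rate`, `$spec`, `$truth`,
#'   `$rp`, `$pitch_offset`.
#' @export
to_angles <- function(rec, rp = NULL, reference = NULL, pitch_offset = NULL,
                      use_cr = TRUE, correct_vertical = TRUE) {
  stopifnot(!is.null(rec$samples), !is.null(rec$sample_rate))
  calib <- rec$calibration
  if (is.null(rp)) rp <- calib$rp
  if (inherits(rp, "oculo_rp")) rp <- rp$value
  if (is.null(rp) || !is.finite(rp) || rp <= 0) {
    stop("rp must be a positive finite calibration distance")
  }
  if (is.null(reference)) reference <- calib$reference %||% c(h = 0, v = 0)
  if (is.null(pitch_offset)) pitch_offset <- calib$pitch_offset %||% 20
  if (any(!is.finite(reference))) stop("reference offsets must be finite")
  s <- rec$samples
  ph <- s$pupil_h
  pv <- s$pupil_v
  if (use_cr && all(c("cr_h", "cr_v") %in% names(s))) {
    ph <- ph - s$cr_h
    pv <- pv - s$cr_v
  }
  av <- (pv - reference[["v"]]) / rp
  valid <- is.finite(av) & abs(av) < 1
  v_head <- rep(NA_real_, length(av))
  v_head[valid] <- asin(av[valid])
  denom <- if (correct_vertical) rp * cos(v_head) else rep(rp, length(av))
  ah <- (ph - reference[["h"]]) / denom
  valid <- valid & is.finite(ah) & abs(ah) < 1
  h <- rep(NA_real_, length(ah))
  h[valid] <- rad2deg(asin(ah[valid]))
  v <- rad2deg(v_head) + pitch_offset
  v[!valid] <- NA_real_
  h[!valid] <- NA_real_
  if (mean(!valid) > 0.5) {
    stop("calibration failure: more than half of the samples fall outside ",
         "the valid asin domain; check Rp and the reference offsets")
  }
  out <- data.frame(t = s$t, h = h, v = v, valid = valid)
  for (ch in c("table_position", "planetarium_velocity")) {
    if (ch %in% names(s)) out[[ch]] <- s[[ch]]
  }
  structure(list(samples = out,
                 sample_rate = rec$sample_rate, spec = rec$spec,
                 truth = rec$truth, rp = rp, pitch_offset = pitch_offset),
            class = "oculo_trace")
}

#' @export
print.oculo_trace <- function(x, ...) {
  cat(sprintf("<oculo_trace> %d samples at %g samples/s; %.1f%% valid\n",
              nrow(x$samples), x$sample_rate, 100 * mean(x$samples$valid)))
  invisible(x)
}
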