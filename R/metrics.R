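## Response measures: sinusoidal gain/phase, hemicycle gains, step gains and
## speed tuning, resting position, mean-velocity bias.
##
## All gains are computed on velocity. The "response" velocity follows the
## compensatory convention: for table (vestibular) stimuli it is the negated
## eye velocity so that a perfectly compensatory eye has gain 1 and phase 0;
## for planetarium (optokinetic) stimuli the eye follows the surround and the
## response is the eye velocity itself. Positive phase = eye leads stimulus.

## patched response and stimulus velocity vectors for a segmented trace
response_stim_velocity <- function(trace, raw = FALSE) {
  stopifnot(!is.null(trace$labels))
  s <- trace$samples
  eye <- if (trace$spec$axis == "yaw") {
    if (raw) s$vh_raw else s$vh
  } else {
    if (raw) s$vv_raw else s$vv
  }
  if (trace$spec$stimulator == "table") {
    ## compensatory drive: the eye follows the negated table velocity
    tp <- sg_velocity(s$table_position, trace$sample_rate)
    list(response = eye, stimulus = -tp)
  } else {
    list(response = eye, stimulus = s$planetarium_velocity)
  }
}

usable_mask <- function(trace, classes = c("slow", "fast_phase",
                                           "glissade_excluded")) {
  trace$labels$class %in% classes
}

#' Phase-binned cycle average of a sinusoidal response
#'
#' Folds the patched response and stimulus velocity records on the stimulus
#' period and averages across clean cycles. A cycle's contribution to a
#' phase bin is omitted when any of its samples in that bin is excluded
#' (dropout or deleted artifact); patched fast-phase samples contribute.
#'
#' @param trace a patched `oculo_trace` from [segment_record()] /
#'   [patch_intervals()].
#' @param stim the `stimulus_spec` (defaults to the trace's).
#' @param n_bins phase bins per stimulus period.
#' @param min_cycles minimum clean cycles required (default 3).
#' @return object of class `cycle_average`: `phase` (bin centers, cycles),
#'   `response`, `stimulus` (bin means, deg/s), `n` (per-bin cycle counts),
#'   `n_cycles`, `frequency`.
#' @export
average_cycles <- function(trace, stim = NULL, n_bins = 100, min_cycles = 3) {
  stopifnot(inherits(trace, "oculo_trace"), !is.null(trace$labels))
  if (is.null(stim)) stim <- trace$spec
  if (!identical(stim$mode, "sinusoid")) {
    stop("average_cycles applies to sinusoidal records")
  }
  vel <- response_stim_velocity(trace)
  t <- trace$samples$t
  f <- stim$frequency
  n_cyc_total <- floor(stim$record_duration * f)
  cyc <- floor(t * f)
  keep <- cyc < n_cyc_total & usable_mask(trace) &
    is.finite(vel$response) & is.finite(vel$stimulus)
  ph <- (t * f) %% 1
  bin <- pmin(n_bins, floor(ph * n_bins) + 1L)
  ## a (cycle, bin) cell contributes only if every sample of that cell is
  ## usable
  cell <- cyc * n_bins + bin
  all_cells <- tapply(keep, cell, all)
  good_cell <- names(all_cells)[all_cells]
  use <- keep & (as.character(cell) %in% good_cell)
  resp <- tapply(vel$response[use], bin[use], mean)
  stimv <- tapply(vel$stimulus[use], bin[use], mean)
  cnt_cells <- tapply(cyc[use], bin[use], function(z) length(unique(z)))
  bins <- as.integer(names(resp))
  n_per_bin <- integer(n_bins)
  n_per_bin[bins] <- as.integer(cnt_cells)
  n_cycles <- if (length(cnt_cells)) min(n_per_bin) else 0L
  if (n_cycles < min_cycles) {
    stop(sprintf("insufficient clean cycles: %d available, %d required",
                 n_cycles, min_cycles))
  }
  response <- stimulus <- rep(NA_real_, n_bins)
  response[bins] <- as.numeric(resp)
  stimulus[bins] <- as.numeric(stimv)
  structure(list(phase = (seq_len(n_bins) - 0.5) / n_bins,
                 response = response, stimulus = stimulus,
                 n = n_per_bin, n_cycles = n_cycles, frequency = f),
            class = "cycle_average")
}

#' @export
print.cycle_average <- function(x, ...) {
  cat(sprintf("<cycle_average> %d bins/period at %g Hz, %d clean cycles\n",
              length(x$phase), x$frequency, x$n_cycles))
  invisible(x)
}

#' Fundamental-frequency gain and phase by Fourier analysis
#'
#' Extracts the amplitude and phase at the stimulus frequency from the
#' cycle-averaged response and stimulus velocity (weighted sinusoidal
#' regression over the phase bins, weights = per-bin cycle counts). Gain is
#' the response/stimulus amplitude ratio; phase is response minus stimulus
#' in degrees, positive = eye leads, compensatory convention (a perfectly
#' compensatory response has gain 1, phase 0).
#'
#' @param avg a `cycle_average`.
#' @return object of class `gain_phase`: `gain`, `phase` (degrees, in
#'   (-180, 180]), `frequency`, `response_amplitude`,
#'   `stimulus_amplitude` (deg/s), `n_cycles`,
#'   `convention = "positive phase = eye leads stimulus"`.
#' @export
fourier_gain_phase <- function(avg) {
  stopifnot(inherits(avg, "cycle_average"))
  theta <- 2 * pi * avg$phase
  w <- avg$n
  fe <- fit_sinusoid(theta, avg$response, w)
  fs_ <- fit_sinusoid(theta, avg$stimulus, w)
  if (fs_$amplitude < 1e-9) {
    stop("stimulus fundamental amplitude is ~0; gain undefined")
  }
  structure(list(gain = fe$amplitude / fs_$amplitude,
                 phase = wrap_phase(fe$phase - fs_$phase),
                 frequency = avg$frequency,
                 response_amplitude = fe$amplitude,
                 stimulus_amplitude = fs_$amplitude,
                 n_cycles = avg$n_cycles,
                 convention = "positive phase = eye leads stimulus"),
            class = "gain_phase")
}

#' @export
print.gain_phase <- function(x, ...) {
  cat(sprintf("<gain_phase> gain %.3f, phase %.2f deg at %g Hz (%d cycles; %s)\n",
              x$gain, x$phase, x$frequency, x$n_cycles, x$convention))
  invisible(x)
}

#' Hemicycle gains by sinusoidal regression
#'
#' Directional gains for sinusoidal optokinetic records, computed in five
#' steps: (1) the trace is segmented and patched; (2) the stimulus velocity
#' is fit with a sinusoid and the record split into hemicycles by the sign
#' of the fitted stimulus velocity (positive = upward with respect to the
#' recorded eye); (3) ordinary least squares of the model
#' `Y(t) = A sin(2 pi f t) + B cos(2 pi f t) + C` is run separately on the
#' upward and downward hemicycles, for the eye and the stimulus;
#' (4) amplitudes are `|Y| = sqrt(A^2 + B^2)`; (5) each hemicycle gain is
#' the eye/stimulus amplitude ratio.
#'
#' @inheritParams average_cycles
#' @param min_fraction a hemicycle with fewer usable samples than this
#'   fraction of its nominal length is reported missing (`NA`).
#' @return object of class `hemicycle_gains`: `gain_up`, `gain_down`, and
#'   the per-hemicycle regression coefficients for eye and stimulus
#'   (`coefficients`, a data.frame).
#' @export
hemicycle_gains <- function(trace, stim = NULL, min_fraction = 0.25) {
  stopifnot(inherits(trace, "oculo_trace"), !is.null(trace$labels))
  if (is.null(stim)) stim <- trace$spec
  if (!identical(stim$mode, "sinusoid")) {
    stop("hemicycle_gains applies to sinusoidal records")
  }
  vel <- response_stim_velocity(trace)
  t <- trace$samples$t
  theta <- 2 * pi * stim$frequency * t
  ok <- usable_mask(trace) & is.finite(vel$response) & is.finite(vel$stimulus)
  stim_fit <- fit_sinusoid(theta[ok], vel$stimulus[ok])
  fitted_stim <- stim_fit$A * sin(theta) + stim_fit$B * cos(theta) +
    stim_fit$C
  half <- list(up = fitted_stim > 0, down = fitted_stim <= 0)
  coefs <- data.frame()
  gains <- c(up = NA_real_, down = NA_real_)
  for (side in names(half)) {
    sel <- ok & half[[side]]
    if (sum(sel) < min_fraction * sum(half[[side]])) next
    fe <- fit_sinusoid(theta[sel], vel$response[sel])
    fs_ <- fit_sinusoid(theta[sel], vel$stimulus[sel])
    gains[side] <- fe$amplitude / fs_$amplitude
    coefs <- rbind(coefs,
                   data.frame(hemicycle = side,
                              channel = c("eye", "stimulus"),
                              A = c(fe$A, fs_$A), B = c(fe$B, fs_$B),
                              C = c(fe$C, fs_$C),
                              amplitude = c(fe$amplitude, fs_$amplitude)))
  }
  structure(list(gain_up = gains[["up"]], gain_down = gains[["down"]],
                 coefficients = coefs, frequency = stim$frequency),
            class = "hemicycle_gains")
}

#' @export
print.hemicycle_gains <- function(x, ...) {
  cat(sprintf("<hemicycle_gains> up %.3f / down %.3f at %g Hz\n",
              x$gain_up, x$gain_down, x$frequency))
  invisible(x)
}

#' Gain of one constant-velocity step
#'
#' Mean slow-phase eye velocity over the step's slow-labeled samples,
#' divided by the planetarium velocity. Arrested, dropout, deleted,
#' fast-phase and glissade samples are all excluded: after patching, the
#' remaining slow-labeled samples carry the optokinetic following response
#' alone.
#'
#' @param trace a patched `oculo_trace` of a step record.
#' @param step one row of the step table (`speed`, `t_on`, `t_off`), e.g.
#'   from `attr(trace$labels, "steps")`.
#' @return list `gain`, `n` (samples used), `usable`, `reason`.
#' @export
step_gain <- function(trace, step) {
  stopifnot(inherits(trace, "oculo_trace"), !is.null(trace$labels))
  vel <- response_stim_velocity(trace)
  t <- trace$samples$t
  in_step <- t >= step$t_on & t < step$t_off
  sel <- in_step & trace$labels$class == "slow" & is.finite(vel$response)
  if (sum(sel) < 0.1 * sum(in_step)) {
    return(list(gain = NA_real_, n = 0L, usable = FALSE,
                reason = "step fully arrested or lost"))
  }
  list(gain = mean(vel$response[sel]) / step$speed, n = sum(sel),
       usable = TRUE, reason = NA_character_)
}

#' Speed-tuning curve from one or more step records
#'
#' Per-speed mean gain across all usable steps of the supplied records
#' (records must share the stimulus axis).
#'
#' @param traces a patched `oculo_trace` or list of them (step records).
#' @return object of class `speed_tuning`: `data.frame(speed, gain, n)`
#'   ordered by signed speed, with `n` the count of usable steps averaged.
#' @export
speed_tuning <- function(traces) {
  if (inherits(traces, "oculo_trace")) traces <- list(traces)
  rows <- list()
  for (trace in traces) {
    steps <- attr(trace$labels, "steps")
    if (is.null(steps)) stop("trace lacks step classification; run segment_record()")
    for (i in seq_len(nrow(steps))) {
      g <- step_gain(trace, steps[i, ])
      if (g$usable) {
        rows[[length(rows) + 1L]] <-
          data.frame(speed = steps$speed[i], gain = g$gain)
      }
    }
  }
  if (!length(rows)) stop("no usable steps in the supplied records")
  d <- do.call(rbind, rows)
  agg <- stats::aggregate(gain ~ speed, d, mean)
  agg$n <- stats::aggregate(gain ~ speed, d, length)$gain
  agg <- agg[order(agg$speed), ]
  rownames(agg) <- NULL
  structure(agg, class = c("speed_tuning", "data.frame"))
}

#' Point-wise difference of two speed-tuning curves (post minus pre)
#'
#' @param post,pre `speed_tuning` curves. Speeds present in only one curve
#'   are dropped with a warning; the difference is aligned on the shared
#'   speed set.
#' @return `data.frame(speed, delta, n_post, n_pre)`.
#' @export
delta_curve <- function(post, pre) {
  stopifnot(inherits(post, "speed_tuning"), inherits(pre, "speed_tuning"))
  shared <- intersect(post$speed, pre$speed)
  if (length(shared) < length(union(post$speed, pre$speed))) {
    warning("speed sets differ; difference reported on their intersection")
  }
  ip <- match(shared, post$speed)
  iq <- match(shared, pre$speed)
  out <- data.frame(speed = shared,
                    delta = post$gain[ip] - pre$gain[iq],
                    n_post = post$n[ip], n_pre = pre$n[iq])
  out[order(out$speed), ]
}

#' Resting eye position from a stationary record
#'
#' Averages eye position over the stable portions of a stationary record in
#' the light. Stable spans are those where the smoothed eye speed stays
#' below `stable_velocity` for at least `min_span`. Transient eccentric
#' positions -- a saccade away from the equilibrium region followed by a
#' return -- are excluded: a stable span far from the dominant level with
#' dominant-level spans both before and after it is dropped. If several
#' distant stable levels remain (no identifiable equilibrium), all stable
#' spans are averaged; if no stable span exists (pure drift), the whole
#' record's mean is used.
#'
#' @param trace an `oculo_trace` (stationary record), segmented or not.
#' @param cfg a [detector_config()] (for the differentiator and dropout
#'   handling).
#' @param stable_velocity maximum eye speed within a stable span, deg/s.
#' @param min_span minimum stable span duration, s.
#' @param eccentric_threshold distance (deg) from the dominant level beyond
#'   which a span counts as eccentric.
#' @return list `h`, `v` (degrees), `method` (`"stable_spans"` or
#'   `"whole_record_drift"`), `n_spans`.
#' @export
resting_position <- function(trace, cfg = detector_config(),
                             stable_velocity = 1.5, min_span = 0.5,
                             eccentric_threshold = 5) {
  stopifnot(inherits(trace, "oculo_trace"))
  if (is.null(trace$labels)) {
    labels <- detect_fast_phases(trace, cfg)
  } else {
    labels <- trace$labels
  }
  s <- trace$samples
  ok <- labels$class %in% c("slow") & is.finite(s$h) & is.finite(s$v)
  if (!any(ok)) {
    ok <- s$valid & is.finite(s$h) & is.finite(s$v)
    if (!any(ok)) stop("no usable samples for resting position")
  }
  fs <- trace$sample_rate
  vh <- sg_velocity(s$h, fs, cfg$sg_window, cfg$sg_order)
  vv <- sg_velocity(s$v, fs, cfg$sg_window, cfg$sg_order)
  ## stability is a sustained state: judge it on 0.2 s smoothed velocities
  k <- max(3L, round(0.2 * fs))
  if (k %% 2 == 0) k <- k + 1L
  smooth1 <- function(x) {
    y <- as.numeric(stats::filter(x, rep(1, k) / k, sides = 2))
    y[is.na(y)] <- x[is.na(y)]
    y
  }
  speed <- sqrt(smooth1(vh)^2 + smooth1(vv)^2)
  stable <- ok & !is.na(speed) & speed < stable_velocity
  r <- rle(as.vector(stable))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values & r$lengths >= round(min_span * fs))
  if (!length(keep)) {
    return(list(h = mean(s$h[ok]), v = mean(s$v[ok]),
                method = "whole_record_drift", n_spans = 0L))
  }
  spans <- data.frame(i0 = starts[keep], i1 = ends[keep])
  spans$dur <- (spans$i1 - spans$i0 + 1) / fs
  spans$h <- mapply(function(a, b) mean(s$h[a:b]), spans$i0, spans$i1)
  spans$v <- mapply(function(a, b) mean(s$v[a:b]), spans$i0, spans$i1)
  ## dominant level: duration-weighted position of the cluster holding the
  ## most total record time
  pos <- spans$v
  cl <- round(pos / eccentric_threshold)
  cl_dur <- tapply(spans$dur, cl, sum)
  dom_cl <- as.numeric(names(cl_dur)[which.max(cl_dur)])
  dom_mask <- cl == dom_cl
  dom_level <- sum(spans$v[dom_mask] * spans$dur[dom_mask]) /
    sum(spans$dur[dom_mask])
  eccentric <- abs(spans$v - dom_level) > eccentric_threshold
  transient <- logical(nrow(spans))
  for (i in which(eccentric)) {
    transient[i] <- any(dom_mask & spans$i1 < spans$i0[i]) &&
      any(dom_mask & spans$i0 > spans$i1[i])
  }
  use <- if (any(eccentric & !transient)) !transient else dom_mask
  idx <- unlist(mapply(function(a, b) a:b, spans$i0[use], spans$i1[use],
                       SIMPLIFY = FALSE))
  list(h = mean(s$h[idx]), v = mean(s$v[idx]),
       method = "stable_spans", n_spans = sum(use))
}

#' Mean slow-phase eye-velocity bias of a sinusoidal record
#'
#' The DC term of the patched slow-phase eye velocity on the stimulated
#' axis -- the constant-drift component superimposed on the sinusoidal
#' response, equal to the coefficient C of the sinusoidal regression
#' `Y(t) = A sin(2 pi f t) + B cos(2 pi f t) + C` over the full record.
#' Reported as actual eye velocity (deg/s), not in the compensatory
#' convention.
#'
#' @inheritParams average_cycles
#' @return list `bias` (deg/s), `A`, `B`, `C` (regression coefficients on
#'   the eye velocity), `n` (samples used).
#' @export
mean_velocity_bias <- function(trace, stim = NULL) {
  stopifnot(inherits(trace, "oculo_trace"), !is.null(trace$labels))
  if (is.null(stim)) stim <- trace$spec
  if (!identical(stim$mode, "sinusoid")) {
    stop("mean_velocity_bias applies to sinusoidal records")
  }
  s <- trace$samples
  eye <- if (stim$axis == "yaw") s$vh else s$vv
  ok <- usable_mask(trace) & is.finite(eye)
  if (!any(ok)) stop("no usable samples")
  theta <- 2 * pi * stim$frequency * s$t
  fit <- fit_sinusoid(theta[ok], eye[ok])
  list(bias = fit$C, A = fit$A, B = fit$B, C = fit$C, n = sum(ok))
}

#' One-call analysis of a simulated or calibrated sinusoidal record
#'
#' Convenience wrapper chaining [to_angles()], [segment_record()],
#' [average_cycles()] and [fourier_gain_phase()], optionally with
#' [hemicycle_gains()] and [mean_velocity_bias()].
#'
#' @param rec an `oculo_record` (raw) or `oculo_trace`.
#' @param cfg a [detector_config()].
#' @param hemicycles also compute hemicycle gains.
#' @param n_bins,min_cycles passed to [average_cycles()].
#' @param patch set `FALSE` to skip desaccading: fast-phase and glissade
#'   samples are treated as slow and the raw velocity is analyzed. Used to
#'   demonstrate the gain bias that patching removes; never for real
#'   measurements.
#' @param ... passed to [to_angles()].
#' @return list `gain`, `phase`, `n_cycles`, `mean_velocity`, and (when
#'   requested) `gain_up`, `gain_down`.
#' @export
analyze_sinusoidal_record <- function(rec, cfg = detector_config(),
                                      hemicycles = FALSE, n_bins = 100,
                                      min_cycles = 3, patch = TRUE, ...) {
  trace <- segment_record(rec, cfg, ...)
  if (!patch) {
    trace$samples$vh <- trace$samples$vh_raw
    trace$samples$vv <- trace$samples$vv_raw
    sac <- trace$labels$class %in% c("fast_phase", "glissade_excluded")
    trace$labels$class[sac] <- "slow"
  }
  gp <- fourier_gain_phase(average_cycles(trace, n_bins = n_bins,
                                          min_cycles = min_cycles))
  out <- list(gain = gp$gain, phase = gp$phase, n_cycles = gp$n_cycles,
              mean_velocity = mean_velocity_bias(trace)$bias)
  if (hemicycles) {
    hc <- hemicycle_gains(trace)
    out$gain_up <- hc$gain_up
    out$gain_down <- hc$gain_down
  }
  out
}

#' One-call analysis of a constant-velocity step record
#'
#' @inheritParams analyze_sinusoidal_record
#' @return a `speed_tuning` curve for the record.
#' @export
analyze_step_record <- function(rec, cfg = detector_config(), ...) {
  speed_tuning(segment_record(rec, cfg, ...))
}
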