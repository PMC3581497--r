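#' Detection thresholds for nystagmus segmentation
#'
#' Tunable parameters of the fast-phase / arrest / dropout labeling stage.
#' All durations in seconds, velocities in deg/s.
#'
#' @param velocity_threshold absolute velocity floor for fast-phase
#'   detection, deg/s. The effective threshold is
#'   `max(velocity_threshold, expected peak slow-phase speed + peak_margin)`.
#' @param peak_margin additive margin (deg/s) over the stimulus' expected
#'   peak slow-phase speed. An additive margin rather than a multiple keeps
#'   the threshold below the filtered peak velocity of small (~1.5 deg)
#'   resetting fast phases even for fast stimuli.
#' @param detect_window short differentiator length (odd, samples) used for
#'   detection only; the brief window preserves saccadic peak velocities
#'   that the longer slow-phase differentiator attenuates.
#' @param min_fast_duration shortest supra-threshold run accepted as a fast
#'   phase.
#' @param post_fast_exclusion window after each fast phase excluded as a
#'   potential post-saccadic glissade (the first few tens of milliseconds).
#' @param arrest_velocity_fraction a behavioral arrest is a span where
#'   `|eye velocity| < arrest_velocity_fraction * |stimulus speed|`.
#' @param arrest_min_duration minimum arrest span.
#' @param sg_window,sg_order Savitzky-Golay differentiator length (odd,
#'   samples) and polynomial order.
#' @param dropout_guard guard margin added around invalid samples.
#' @return object of class `detector_config`.
#' @export
detector_config <- function(velocity_threshold = 40, peak_margin = 25,
                            min_fast_duration = 0.012,
                            post_fast_exclusion = 0.04,
                            arrest_velocity_fraction = 0.2,
                            arrest_min_duration = 0.3,
                            sg_window = 31L, sg_order = 3L,
                            detect_window = 9L,
                            dropout_guard = 0.01) {
  vals <- c(velocity_threshold, peak_margin, min_fast_duration,
            post_fast_exclusion, arrest_velocity_fraction,
            arrest_min_duration, sg_window, sg_order, detect_window,
            dropout_guard)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all detector parameters must be positive")
  }
  structure(list(velocity_threshold = velocity_threshold,
                 peak_margin = peak_margin,
                 min_fast_duration = min_fast_duration,
                 post_fast_exclusion = post_fast_exclusion,
                 arrest_velocity_fraction = arrest_velocity_fraction,
                 arrest_min_duration = arrest_min_duration,
                 sg_window = as.integer(sg_window),
                 sg_order = as.integer(sg_order),
                 detect_window = as.integer(detect_window),
                 dropout_guard = dropout_guard),
            class = "detector_config")
}

SEGMENT_CLASSES <- c("slow", "fast_phase", "glissade_excluded", "arrest",
                     "dropout", "deleted_artifact")

new_labels <- function(trace) {
  structure(list(t = trace$samples$t, sample_rate = trace$sample_rate,
                 class = rep("slow", nrow(trace$samples))),
            class = "segment_labels")
}

#' @export
print.segment_labels <- function(x, ...) {
  tab <- table(factor(x$class, levels = SEGMENT_CLASSES))
  cat("<segment_labels>", length(x$class), "samples:",
      paste(sprintf("%s %.1f%%", names(tab), 100 * tab / length(x$class)),
            collapse = ", "), "\n")
  invisible(x)
}

#' Interval table of a segmentation class
#'
#' @param labels a `segment_labels` object.
#' @param class one of `"slow"`, `"fast_phase"`, `"glissade_excluded"`,
#'   `"arrest"`, `"dropout"`, `"deleted_artifact"`; `NULL` returns all
#'   classes.
#' @return `data.frame(class, start, end)` with half-open `[start, end)`
#'   intervals in seconds, sorted and disjoint within each class.
#' @export
label_intervals <- function(labels, class = NULL) {
  stopifnot(inherits(labels, "segment_labels"))
  classes <- if (is.null(class)) SEGMENT_CLASSES else class
  out <- lapply(classes, function(cl) {
    iv <- runs_to_intervals(labels$class == cl, labels$t)
    if (nrow(iv)) cbind(class = cl, iv) else NULL
  })
  out <- do.call(rbind, out)
  if (is.null(out)) data.frame(class = character(0), start = numeric(0),
                               end = numeric(0)) else out
}

## set class on masked samples; never downgrades dropout/deleted samples
set_class <- function(labels, mask, class,
                      protect = c("dropout", "deleted_artifact")) {
  mask <- mask & !(labels$class %in% setdiff(protect, class))
  labels$class[mask] <- class
  labels
}

#' Label pupil-tracking dropouts
#'
#' Marks invalid calibrated samples (lost video, asin-domain violations)
#' plus a guard margin as `dropout`; contiguous runs are merged. Dropout
#' samples are excluded from all downstream measures, never patched.
#'
#' @param trace an `oculo_trace` from [to_angles()].
#' @param cfg a [detector_config()].
#' @param labels optional existing `segment_labels` to update.
#' @return `segment_labels`.
#' @export
find_dropouts <- function(trace, cfg = detector_config(), labels = NULL) {
  stopifnot(inherits(trace, "oculo_trace"))
  if (is.null(labels)) labels <- new_labels(trace)
  bad <- !trace$samples$valid
  if (any(bad)) {
    iv <- merge_intervals(runs_to_intervals(bad, labels$t),
                          pad = cfg$dropout_guard)
    bad <- intervals_to_mask(iv, labels$t)
  }
  set_class(labels, bad, "dropout", protect = character(0))
}

## axis-appropriate response position channel
response_position <- function(trace) {
  if (trace$spec$axis == "yaw") trace$samples$h else trace$samples$v
}

#' Detect resetting fast phases
#'
#' Finds intervals where the smoothed absolute eye velocity on the
#' stimulated axis exceeds `max(velocity_threshold, k_peak * expected peak
#' slow-phase speed)`. Each supra-threshold run is grown outward to the
#' flanking velocity minima (zero-acceleration samples) plus the
#' differentiator half-window, and a `post_fast_exclusion` glissade window
#' is labeled after it.
#'
#' @inheritParams find_dropouts
#' @param stim the `stimulus_spec` (defaults to the trace's); sets the
#'   expected slow-phase velocity ceiling.
#' @return `segment_labels` with `fast_phase` and `glissade_excluded`
#'   intervals; the realized per-interval direction is attached as
#'   `attr(, "fast_phases")`.
#' @export
detect_fast_phases <- function(trace, cfg = detector_config(), stim = NULL,
                               labels = NULL) {
  stopifnot(inherits(trace, "oculo_trace"))
  if (is.null(stim)) stim <- trace$spec
  if (is.null(labels)) labels <- find_dropouts(trace, cfg)
  n <- length(labels$t)
  fs <- trace$sample_rate
  peak <- if (identical(stim$mode, "stationary")) 0 else peak_slow_speed(stim)
  if (cfg$velocity_threshold < peak) {
    stop(sprintf(paste0("velocity_threshold (%g deg/s) is below the expected ",
                        "peak slow-phase speed (%g deg/s); fast-phase ",
                        "detection would label slow phases"),
                 cfg$velocity_threshold, peak))
  }
  thr <- max(cfg$velocity_threshold, peak + cfg$peak_margin)
  vel <- sg_velocity(response_position(trace), fs,
                     window = cfg$detect_window,
                     order = min(cfg$sg_order, cfg$detect_window - 2L))
  av <- abs(vel)
  av[is.na(av)] <- 0
  hot <- av > thr
  r <- rle(hot)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values &
                  r$lengths >= max(1L, round(cfg$min_fast_duration * fs)))
  pad <- (cfg$sg_window - 1L) %/% 2L + 2L
  gl_n <- round(cfg$post_fast_exclusion * fs)
  ## smoothed |velocity| for following the monotone post-saccadic decay
  ## (glissade) through sample noise; growth capped at 200 ms
  sm <- as.numeric(stats::filter(av, rep(1, 9) / 9, sides = 2))
  sm[is.na(sm)] <- av[is.na(sm)]
  max_grow <- round(0.2 * fs)
  fp_mask <- logical(n)
  gl_mask <- logical(n)
  info <- data.frame(start = numeric(0), end = numeric(0),
                     direction = numeric(0))
  for (k in keep) {
    i0 <- starts[k]; i1 <- ends[k]
    while (i0 > 1L && av[i0 - 1L] < av[i0]) i0 <- i0 - 1L
    g0 <- i1
    while (i1 < n && i1 - g0 < max_grow && sm[min(n, i1 + 1L)] <= sm[i1]) {
      i1 <- i1 + 1L
    }
    dir <- sign(vel[starts[k]:ends[k]][which.max(av[starts[k]:ends[k]])])
    i0 <- max(1L, i0 - pad)
    i1 <- min(n, i1 + pad)
    fp_mask[i0:i1] <- TRUE
    gl_mask[min(n, i1 + 1L):min(n, i1 + gl_n)] <- TRUE
    info <- rbind(info, data.frame(start = labels$t[i0],
                                   end = labels$t[i1] + 1 / fs,
                                   direction = dir))
  }
  gl_mask <- gl_mask & !fp_mask
  labels <- set_class(labels, fp_mask, "fast_phase")
  labels <- set_class(labels, gl_mask, "glissade_excluded",
                      protect = c("dropout", "deleted_artifact", "fast_phase"))
  attr(labels, "fast_phases") <- info
  labels
}

#' Classify constant-velocity step epochs: arrests and usable slow phase
#'
#' Within each constant-velocity step, spans where the smoothed absolute eye
#' velocity stays below `arrest_velocity_fraction * |stimulus speed|` for at
#' least `arrest_min_duration` are labeled behavioral arrests (the animal
#' has stopped making resetting fast phases and the eye has halted
#' eccentrically); they are excluded from gain. Remaining in-step samples
#' keep their existing class.
#'
#' @inheritParams detect_fast_phases
#' @param labels `segment_labels` that already carry dropout and fast-phase
#'   classes (from [detect_fast_phases()]).
#' @return `segment_labels` with `arrest` spans; a per-step usability table
#'   (`attr(, "steps")`: `speed`, `t_on`, `t_off`, `n_slow`, `usable`).
#' @export
classify_step_epochs <- function(trace, labels, cfg = detector_config(),
                                 stim = NULL) {
  stopifnot(inherits(trace, "oculo_trace"), inherits(labels, "segment_labels"))
  if (is.null(stim)) stim <- trace$spec
  if (stim$mode != "velocity_steps") {
    stop("classify_step_epochs applies to constant-velocity step records")
  }
  fs <- trace$sample_rate
  t <- labels$t
  vel <- sg_velocity(response_position(trace), fs,
                     window = cfg$sg_window, order = cfg$sg_order)
  ## arrests are a sustained low-velocity state: judge them on a 0.2 s
  ## moving average so sample noise cannot break up (or fake) a span
  k <- max(3L, round(0.2 * fs))
  if (k %% 2 == 0) k <- k + 1L
  vs <- as.numeric(stats::filter(vel, rep(1, k) / k, sides = 2))
  vs[is.na(vs)] <- vel[is.na(vs)]
  sched <- step_schedule(stim)
  min_n <- max(1L, round(cfg$arrest_min_duration * fs))
  sched$n_slow <- 0L
  sched$usable <- FALSE
  avs <- abs(vs)
  for (i in seq_len(nrow(sched))) {
    in_step <- t >= sched$t_on[i] & t < sched$t_off[i]
    step_idx <- which(in_step)
    eligible <- in_step & labels$class %in% c("slow", "glissade_excluded") &
      !is.na(vs)
    ## expected slow-phase speed for this step, estimated robustly from the
    ## step itself (the true gain is unknown; the stimulus speed would
    ## overstate it at high speeds, where optokinetic gain is low)
    expected <- max(2, stats::median(avs[eligible]))
    quiet <- eligible & avs < cfg$arrest_velocity_fraction * expected
    r <- rle(quiet)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    lo <- if (length(step_idx)) min(step_idx) else 1L
    hi <- if (length(step_idx)) max(step_idx) else 0L
    arrest_mask <- logical(length(t))
    grow_cap <- round(0.5 * fs)
    for (k in which(r$values & r$lengths >= min_n)) {
      i0 <- starts[k]; i1 <- ends[k]
      ## include the deceleration into, and reacceleration out of, the halt:
      ## extend while the eye is still below its cruise speed for this step
      j0 <- i0
      while (i0 > lo && i0 > j0 - grow_cap && !is.na(vs[i0 - 1L]) &&
             avs[i0 - 1L] < 0.8 * expected) {
        i0 <- i0 - 1L
      }
      j1 <- i1
      while (i1 < hi && i1 < j1 + grow_cap && !is.na(vs[i1 + 1L]) &&
             avs[i1 + 1L] < 0.8 * expected) {
        i1 <- i1 + 1L
      }
      arrest_mask[i0:i1] <- TRUE
    }
    if (any(arrest_mask)) {
      labels <- set_class(labels, arrest_mask, "arrest",
                          protect = c("dropout", "deleted_artifact"))
    }
    sched$n_slow[i] <- sum(in_step & labels$class == "slow")
    sched$usable[i] <- sched$n_slow[i] >= 0.1 * sum(in_step)
  }
  attr(labels, "steps") <- sched
  labels
}

#' Patch fast phases and glissade windows by linear interpolation
#'
#' Removes saccadic content from the slow-phase velocity traces: within each
#' `fast_phase`/`glissade_excluded` interval, the eye-velocity samples are
#' replaced by the straight line joining the last preceding and first
#' following slow-phase velocity samples. This is the velocity-domain form
#' of joining the surrounding slow-phase data across the removed fast phase
#' (patching positions literally would retain the saccadic displacement as
#' a spurious velocity transient). Dropout and arrest samples are excluded,
#' not patched; intervals touching a record edge or with no slow-phase
#' neighbor are flagged `deleted_artifact` instead of being extrapolated.
#'
#' @inheritParams classify_step_epochs
#' @return the input `oculo_trace` with added `$samples` columns `vh`, `vv`
#'   (patched velocities, deg/s), `vh_raw`, `vv_raw` (unpatched), and the
#'   labels attached as `$labels`. Slow-labeled samples are never altered.
#' @export
patch_intervals <- function(trace, labels, cfg = detector_config()) {
  stopifnot(inherits(trace, "oculo_trace"), inherits(labels, "segment_labels"))
  fs <- trace$sample_rate
  n <- nrow(trace$samples)
  vh <- sg_velocity(trace$samples$h, fs, cfg$sg_window, cfg$sg_order)
  vv <- sg_velocity(trace$samples$v, fs, cfg$sg_window, cfg$sg_order)
  trace$samples$vh_raw <- vh
  trace$samples$vv_raw <- vv
  to_patch <- labels$class %in% c("fast_phase", "glissade_excluded")
  r <- rle(to_patch)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  ## anchor each patch on the mean over a few contiguous slow samples so a
  ## single noisy endpoint does not tilt the whole interpolated span
  anchor <- function(vel, idx, dir) {
    run <- idx
    while (length(run) < 5L) {
      nxt <- run[length(run)] + dir
      if (nxt < 1L || nxt > n || labels$class[nxt] != "slow" ||
          !is.finite(vel[nxt])) break
      run <- c(run, nxt)
    }
    mean(vel[run])
  }
  for (k in which(r$values)) {
    i0 <- starts[k]; i1 <- ends[k]
    a <- i0 - 1L
    b <- i1 + 1L
    while (a >= 1L && labels$class[a] != "slow") a <- a - 1L
    while (b <= n && labels$class[b] != "slow") b <- b + 1L
    if (a < 1L || b > n || !is.finite(vh[a]) || !is.finite(vh[b])) {
      labels$class[i0:i1] <- "deleted_artifact"
      next
    }
    w <- (seq(i0, i1) - a) / (b - a)
    vh[i0:i1] <- anchor(vh, a, -1L) * (1 - w) + anchor(vh, b, 1L) * w
    vv[i0:i1] <- anchor(vv, a, -1L) * (1 - w) + anchor(vv, b, 1L) * w
  }
  excluded <- labels$class %in% c("dropout", "deleted_artifact")
  vh[excluded] <- NA_real_
  vv[excluded] <- NA_real_
  trace$samples$vh <- vh
  trace$samples$vv <- vv
  trace$labels <- labels
  trace
}

#' Run the full segmentation chain on a record or calibrated trace
#'
#' Calibrates (if given a raw record), labels dropouts, detects fast phases,
#' classifies step epochs for constant-velocity records, and patches. The
#' returned trace is ready for the response-metric functions.
#'
#' @param x an `oculo_record` or `oculo_trace`.
#' @param cfg a [detector_config()].
#' @param ... passed to [to_angles()] when `x` is a raw record.
#' @return a patched `oculo_trace` with `$labels`.
#' @export
segment_record <- function(x, cfg = detector_config(), ...) {
  trace <- if (inherits(x, "oculo_trace")) x else to_angles(x, ...)
  labels <- find_dropouts(trace, cfg)
  labels <- detect_fast_phases(trace, cfg, labels = labels)
  if (identical(trace$spec$mode, "velocity_steps")) {
    labels <- classify_step_epochs(trace, labels, cfg)
  }
  patch_intervals(trace, labels, cfg)
}
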