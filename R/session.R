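## Session-level orchestration: pre -> treatment -> post phases, per-measure
## deltas (post minus pre), cohort t-tests, and the dose-response regression
## for intrafloccular injection series.

#' Simulate one pre/post recording session
#'
#' Generates matched pre- and post-treatment records for a single animal.
#' The session's baseline gain is the cohort baseline plus a
#' session-to-session random offset; the post-phase gain adds the
#' within-session habituation (a property of the animal/session) and, for
#' treated sessions, the treatment effect. Resting-position sessions use
#' stationary records with the analogous decomposition on vertical
#' position.
#'
#' @param animal,cohort,treatment session metadata. `cohort` is one of
#'   `"young_mutant"`, `"old_mutant"`, `"control"`; `treatment` one of
#'   `"saline"`, `"drug_systemic"`, `"drug_intrafloccular"`, `"sham"`.
#' @param stimulus a sinusoidal [stimulus_spec()] for gain sessions
#'   (default 0.8 Hz +/-4.8 deg rotation in light); ignored when
#'   `measure = "resting_v"`.
#' @param measure `"gain"` or `"resting_v"`.
#' @param baseline mean pre-treatment value of the measure across sessions
#'   (gain, or degrees for resting position).
#' @param session_sd between-session SD of the baseline.
#' @param habituation within-session change of the measure, post minus pre
#'   (e.g. -0.06 gain units).
#' @param habituation_sd between-session SD of the within-session change
#'   (the dominant source of spread in post-minus-pre deltas).
#' @param effect treatment effect added to the post phase.
#' @param injection_volume pL/injection for intrafloccular sessions
#'   (`NA` otherwise).
#' @param n_records records per phase.
#' @param record_duration record length, s.
#' @param seed integer session seed.
#' @param truth_args extra arguments merged into the per-record
#'   [sim_truth()] (noise, fast-phase rate, ...).
#' @return an `oculo_session`: list with `meta` and per-phase record lists
#'   `pre`, `post`.
#' @export
simulate_session <- function(animal = "m1", cohort = "young_mutant",
                             treatment = "saline",
                             stimulus = NULL, measure = c("gain", "resting_v"),
                             baseline = if (measure == "gain") 0.6 else 15,
                             session_sd = if (measure == "gain") 0.05 else 2.5,
                             habituation = -0.06,
                             habituation_sd = if (measure == "gain") 0.05 else 2.5,
                             effect = 0,
                             injection_volume = NA_real_,
                             n_records = 1, record_duration = NULL,
                             seed = 1L, truth_args = list()) {
  measure <- match.arg(measure)
  set.seed(as.integer(seed))
  base <- baseline + stats::rnorm(1, 0, session_sd)
  pre_val <- base
  post_val <- base + habituation + stats::rnorm(1, 0, habituation_sd) + effect
  make_truth <- function(value, rec_seed) {
    args <- truth_args
    args$seed <- rec_seed
    if (measure == "gain") {
      args$gain <- max(0, value)
    } else {
      args$resting_v <- value
    }
    do.call(sim_truth, args)
  }
  gen <- function(value, phase_tag) {
    lapply(seq_len(n_records), function(i) {
      rec_seed <- (seed * 1000L + i * 2L +
                     if (phase_tag == "post") 1L else 0L) %% .Machine$integer.max
      tr <- make_truth(value, rec_seed)
      if (measure == "gain") {
        sp <- stimulus %||% stimulus_spec("yaw", "sinusoid", "table",
                                          frequency = 0.8, amplitude = 4.8)
        if (!is.null(record_duration)) sp$record_duration <- record_duration
        simulate_sinusoidal_record(sp, tr)
      } else {
        simulate_stationary_record(record_duration %||% 20, tr)
      }
    })
  }
  structure(list(meta = list(animal = animal, cohort = cohort,
                             treatment = treatment,
                             injection_volume = injection_volume,
                             measure = measure, seed = seed,
                             truth = list(pre = pre_val, post = post_val,
                                          habituation = habituation,
                                          effect = effect)),
                 pre = gen(pre_val, "pre"),
                 post = gen(post_val, "post")),
            class = "oculo_session")
}

COHORTS <- c("young_mutant", "old_mutant", "control")
TREATMENTS <- c("saline", "drug_systemic", "drug_intrafloccular", "sham")

#' Analyze a session: per-phase measures and post-minus-pre deltas
#'
#' Runs the response-metric pipeline on every record of each phase,
#' averages within phase, and assembles the treatment-related change as
#' post-treatment minus pre-treatment. Phases with no analyzable records
#' yield `NA` with the gap made explicit rather than an error.
#'
#' @param session an `oculo_session` from [simulate_session()] (or a list
#'   with the same shape built from real records).
#' @param cfg a [detector_config()].
#' @return a one-row-per-measure `data.frame`: `animal`, `cohort`,
#'   `treatment`, `injection_volume`, `measure`, `pre`, `post`, `delta`,
#'   `n_pre`, `n_post`.
#' @export
run_session <- function(session, cfg = detector_config()) {
  meta <- session$meta
  analyze_phase <- function(records) {
    vals <- vapply(records, function(rec) {
      out <- tryCatch({
        if (identical(rec$spec$mode, "stationary")) {
          resting_position(to_angles(rec), cfg)$v
        } else if (identical(rec$spec$mode, "sinusoid")) {
          analyze_sinusoidal_record(rec, cfg)$gain
        } else {
          NA_real_
        }
      }, error = function(e) NA_real_)
      as.numeric(out)
    }, numeric(1))
    vals[is.finite(vals)]
  }
  pre <- analyze_phase(session$pre)
  post <- analyze_phase(session$post)
  pre_m <- if (length(pre)) mean(pre) else NA_real_
  post_m <- if (length(post)) mean(post) else NA_real_
  data.frame(animal = meta$animal, cohort = meta$cohort,
             treatment = meta$treatment,
             injection_volume = meta$injection_volume,
             measure = meta$measure,
             pre = pre_m, post = post_m, delta = post_m - pre_m,
             n_pre = length(pre), n_post = length(post))
}

#' Two-sample t statistic from group summaries
#'
#' The textbook pooled-variance two-sample t statistic computed from group
#' means, SDs and sizes, with the two-tailed p-value on
#' `n1 + n2 - 2` degrees of freedom.
#'
#' @param m1,sd1,n1,m2,sd2,n2 group summaries.
#' @return list `t`, `df`, `p`, `degenerate` (TRUE when both SDs are 0).
#' @export
t_from_summary <- function(m1, sd1, n1, m2, sd2, n2) {
  stopifnot(n1 >= 2, n2 >= 2)
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / df
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  if (se == 0) {
    d <- m1 - m2
    return(list(t = if (d == 0) 0 else sign(d) * Inf, df = df,
                p = if (d == 0) 1 else 0, degenerate = TRUE))
  }
  tt <- (m1 - m2) / se
  list(t = tt, df = df, p = 2 * stats::pt(-abs(tt), df), degenerate = FALSE)
}

#' Compare a measure between groups or between pre and post
#'
#' Unpaired: two-tailed pooled-variance t-test of the per-session deltas
#' (or any value column) between two groups, recomputed exactly from the
#' group summaries. Paired: two-tailed paired t-test of post vs. pre within
#' sessions. Degenerate variance (identical values) is reported, not a
#' crash: identical groups give `t = 0, p = 1`; a constant nonzero
#' difference is flagged `degenerate`.
#'
#' @param results stacked [run_session()] output.
#' @param measure measure name to compare.
#' @param grouping column splitting the sessions into two groups for the
#'   unpaired test (default `"treatment"`).
#' @param test `"unpaired"` or `"paired"`.
#' @param value column tested in the unpaired case (default `"delta"`).
#' @param by_animal average sessions within each animal before testing
#'   (each animal typically contributes two sessions per arm, which are not
#'   strictly independent). Default `FALSE`: each session is one
#'   observation, matching the reported per-arm n's.
#' @return object of class `cohort_comparison`: group means, SDs and n, the
#'   t statistic, df, two-tailed p, test type, and the `degenerate` flag.
#' @export
compare_groups <- function(results, measure = NULL,
                           grouping = "treatment",
                           test = c("unpaired", "paired"),
                           value = "delta", by_animal = FALSE) {
  test <- match.arg(test)
  if (!is.null(measure)) results <- results[results$measure == measure, ]
  if (by_animal && test == "unpaired") {
    by <- list(animal = results$animal, group = results[[grouping]])
    agg <- stats::aggregate(results[[value]], by = by, FUN = mean)
    results <- data.frame(animal = agg$animal, group = agg$group,
                          value = agg$x)
    names(results)[2:3] <- c(grouping, value)
  }
  if (test == "paired") {
    d <- results$post - results$pre
    d <- d[is.finite(d)]
    n <- length(d)
    if (n < 2) stop("paired test needs at least two complete sessions")
    sdd <- stats::sd(d)
    if (sdd == 0) {
      out <- list(t = if (mean(d) == 0) 0 else sign(mean(d)) * Inf,
                  df = n - 1, p = if (mean(d) == 0) 1 else 0,
                  degenerate = TRUE)
    } else {
      tt <- mean(d) / (sdd / sqrt(n))
      out <- list(t = tt, df = n - 1, p = 2 * stats::pt(-abs(tt), n - 1),
                  degenerate = FALSE)
    }
    groups <- data.frame(group = c("pre", "post"),
                         mean = c(mean(results$pre, na.rm = TRUE),
                                  mean(results$post, na.rm = TRUE)),
                         sd = c(stats::sd(results$pre),
                                stats::sd(results$post)),
                         n = n)
  } else {
    g <- results[[grouping]]
    lv <- unique(g)
    if (length(lv) != 2) {
      stop("unpaired comparison needs exactly two groups in '", grouping, "'")
    }
    x1 <- results[[value]][g == lv[1]]
    x2 <- results[[value]][g == lv[2]]
    x1 <- x1[is.finite(x1)]
    x2 <- x2[is.finite(x2)]
    if (length(x1) < 2 || length(x2) < 2) {
      stop("need at least two sessions per group")
    }
    out <- t_from_summary(mean(x1), stats::sd(x1), length(x1),
                          mean(x2), stats::sd(x2), length(x2))
    groups <- data.frame(group = as.character(lv),
                         mean = c(mean(x1), mean(x2)),
                         sd = c(stats::sd(x1), stats::sd(x2)),
                         n = c(length(x1), length(x2)))
  }
  structure(list(measure = measure %||% "value", groups = groups,
                 t = out$t, df = out$df, p = out$p, test = test,
                 degenerate = out$degenerate),
            class = "cohort_comparison")
}

#' @export
print.cohort_comparison <- function(x, ...) {
  cat(sprintf("<cohort_comparison> %s (%s, two-tailed): t(%g) = %.3f, p = %.4g\n",
              x$measure, x$test, x$df, x$t, x$p))
  for (i in seq_len(nrow(x$groups))) {
    cat(sprintf("  %s: %.4g +/- %.3g (n = %d)\n", x$groups$group[i],
                x$groups$mean[i], x$groups$sd[i], x$groups$n[i]))
  }
  if (x$degenerate) cat("  (degenerate variance)\n")
  invisible(x)
}

#' Dose-response regression of a measure's change on injection volume
#'
#' Ordinary least squares of the per-session delta against the ejected
#' volume per injection, with the saline/sham reference band (mean +/- 2
#' SD of the control sessions' deltas) computed alongside.
#'
#' @param results stacked [run_session()] rows of the injection sessions
#'   (must carry `injection_volume`).
#' @param measure measure to regress (default: the only one present).
#' @param controls optional stacked [run_session()] rows of the designated
#'   control (e.g. systemic saline) sessions for the reference band.
#' @return object of class `dose_response`: `slope`, `intercept`,
#'   `r_squared`, `p` (slope's two-tailed p), `se_slope`, `n`, and
#'   `reference_band` (`mean`, `lower`, `upper`, `n`) or `NULL`.
#' @export
dose_response <- function(results, measure = NULL, controls = NULL) {
  if (!is.null(measure)) results <- results[results$measure == measure, ]
  keep <- is.finite(results$delta) & is.finite(results$injection_volume)
  results <- results[keep, ]
  if (nrow(results) < 3) stop("dose-response regression needs >= 3 sessions with volumes")
  if (length(unique(results$injection_volume)) < 2) {
    stop("degenerate regression: all injection volumes are equal")
  }
  fit <- stats::lm(delta ~ injection_volume, data = results)
  sm <- summary(fit)
  band <- NULL
  if (!is.null(controls)) {
    if (!is.null(measure)) controls <- controls[controls$measure == measure, ]
    d <- controls$delta[is.finite(controls$delta)]
    band <- list(mean = mean(d), lower = mean(d) - 2 * stats::sd(d),
                 upper = mean(d) + 2 * stats::sd(d), n = length(d))
  }
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = sm$r.squared,
                 p = sm$coefficients[2, 4],
                 se_slope = sm$coefficients[2, 2],
                 n = nrow(results),
                 reference_band = band),
            class = "dose_response")
}

#' @export
print.dose_response <- function(x, ...) {
  cat(sprintf("<dose_response> slope %.4g per pL (SE %.3g), r^2 = %.3f, p = %.4g, n = %d\n",
              x$slope, x$se_slope, x$r_squared, x$p, x$n))
  if (!is.null(x$reference_band)) {
    cat(sprintf("  control band: %.3g [%.3g, %.3g] (mean +/- 2 SD, n = %d)\n",
                x$reference_band$mean, x$reference_band$lower,
                x$reference_band$upper, x$reference_band$n))
  }
  invisible(x)
}

#' Simulate an intrafloccular injection series
#'
#' A set of sessions with lognormally distributed ejection volumes (median
#' ~300 pL, clipped to 0.4-1100 pL) whose post-minus-pre change in resting
#' vertical eye position follows `baseline_delta + slope * volume` plus
#' session noise. Used to validate [dose_response()] against known truth.
#'
#' @param n_sessions number of sessions.
#' @param slope true deg per pL effect of the injection (0 = null series).
#' @param baseline_delta session change common to all volumes, degrees.
#' @param session_sd between-session SD of both the baseline position and
#'   the delta noise, degrees.
#' @param seed integer seed.
#' @param record_duration stationary record length, s.
#' @param truth_args extra [sim_truth()] arguments.
#' @return list of `oculo_session` objects.
#' @export
simulate_injection_series <- function(n_sessions = 40, slope = 0,
                                      baseline_delta = -1,
                                      session_sd = 2.5, seed = 1L,
                                      record_duration = 20,
                                      truth_args = list()) {
  set.seed(as.integer(seed))
  vols <- pmin(1100, pmax(0.4, stats::rlnorm(n_sessions, log(300), 1.2)))
  session_seeds <- sample.int(1e6, n_sessions)
  lapply(seq_len(n_sessions), function(i) {
    simulate_session(animal = sprintf("m%02d", i), cohort = "young_mutant",
                     treatment = "drug_intrafloccular",
                     measure = "resting_v",
                     baseline = 15, session_sd = session_sd,
                     habituation = baseline_delta + slope * vols[i],
                     effect = 0, injection_volume = vols[i],
                     record_duration = record_duration,
                     seed = session_seeds[i], truth_args = truth_args)
  })
}
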