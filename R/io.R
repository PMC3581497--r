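## Delimited-text persistence: one TSV per record (one row per sample,
## header naming channel roles) with a YAML sidecar holding the stimulus
## specification and, for simulated records, the ground truth; segmentation
## labels as a BED-like interval table.

iv_to_list <- function(iv) {
  if (is.null(iv) || nrow(iv) == 0) return(list())
  lapply(seq_len(nrow(iv)), function(i) as.list(iv[i, ]))
}

iv_from_list <- function(x) {
  if (is.null(x) || length(x) == 0) {
    return(data.frame(start = numeric(0), end = numeric(0)))
  }
  do.call(rbind, lapply(x, function(e) as.data.frame(e)))
}

#' Write an oculography record to delimited text with a YAML sidecar
#'
#' The samples go to `<path>` as tab-separated text; the stimulus
#' specification, calibration and (if present) ground truth go to
#' `<path>.yaml`. Bulky per-sample truth vectors (true slow-phase velocity)
#' are not serialized.
#'
#' @param rec an `oculo_record`.
#' @param path output file path (the sidecar adds `.yaml`).
#' @return `path`, invisibly.
#' @export
write_record <- function(rec, path) {
  stopifnot(inherits(rec, "oculo_record"))
  utils::write.table(rec$samples, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  truth <- rec$truth
  if (!is.null(truth)) {
    truth <- unclass(truth)
    truth$slow_velocity <- NULL
    truth$stimulus_velocity <- NULL
    for (nm in c("fast_phase_intervals", "glissade_intervals",
                 "arrest_intervals", "dropout_intervals",
                 "excursion_intervals", "step_schedule")) {
      if (!is.null(truth[[nm]]) && is.data.frame(truth[[nm]])) {
        truth[[nm]] <- iv_to_list(truth[[nm]])
      }
    }
    truth <- truth[!vapply(truth, is.null, logical(1))]
    truth <- truth[!vapply(truth, is.function, logical(1))]
  }
  spec <- unclass(rec$spec)
  spec <- spec[!vapply(spec, is.null, logical(1))]
  side <- list(sample_rate = rec$sample_rate, spec = spec,
               calibration = lapply(rec$calibration, function(z) {
                 if (length(z) > 1) as.list(z) else z
               }),
               truth = truth)
  yaml::write_yaml(side, paste0(path, ".yaml"))
  invisible(path)
}

#' Read an oculography record written by [write_record()]
#'
#' @param path the sample-table path (expects `<path>.yaml` beside it).
#' @return an `oculo_record`; the truth element is `NULL` when the sidecar
#'   carries none (real data).
#' @export
read_record <- function(path) {
  samples <- utils::read.table(path, header = TRUE, sep = "\t")
  side <- yaml::read_yaml(paste0(path, ".yaml"))
  spec <- structure(side$spec, class = "stimulus_spec")
  truth <- side$truth
  if (!is.null(truth)) {
    for (nm in c("fast_phase_intervals", "glissade_intervals",
                 "arrest_intervals", "dropout_intervals",
                 "excursion_intervals", "step_schedule")) {
      if (!is.null(truth[[nm]])) truth[[nm]] <- iv_from_list(truth[[nm]])
    }
    if (!is.null(truth$fast_phase_times)) {
      truth$fast_phase_times <- unlist(truth$fast_phase_times)
    }
    class(truth) <- "sim_truth"
  }
  calib <- side$calibration
  if (!is.null(calib$reference)) calib$reference <- unlist(calib$reference)
  structure(list(samples = samples, sample_rate = side$sample_rate,
                 spec = spec, truth = truth, calibration = calib),
            class = "oculo_record")
}

#' Write segmentation labels as a BED-like interval table
#'
#' @param labels a `segment_labels` object.
#' @param path output path (tab-separated: `record_id`, `start`, `end`,
#'   `class`).
#' @param record_id identifier written in the first column.
#' @return `path`, invisibly.
#' @export
write_labels <- function(labels, path, record_id = "record") {
  iv <- label_intervals(labels)
  out <- data.frame(record_id = record_id, start = iv$start, end = iv$end,
                    class = iv$class)
  utils::write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a session manifest
#'
#' A YAML file describing a session set: animals, cohorts, treatments,
#' per-phase record files, injection volumes, and explicit exclusions (with
#' reasons). Returned as-is for [run_session()]-style orchestration of real
#' recordings.
#'
#' @param path YAML manifest path.
#' @return the parsed manifest list.
#' @export
read_session_manifest <- function(path) {
  yaml::read_yaml(path)
}
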