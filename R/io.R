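#' Read and write trial records
#'
#' Trial records travel as plain CSV with one row per trial and the columns
#' produced by [run_session()] and [generate_session()]: `subject_id`,
#' `block`, `condition`, `trial_index`, `coherence_signed` (negative =
#' left), `direction`, `choice`, `responded` (0/1), `decision_time_s`,
#' `prestim_rate_chosen_hz`, `prestim_rate_unchosen_hz`, `previous_choice`,
#' plus any analysis columns such as `correct` or `valid`.
#'
#' @param records a trial-record data frame.
#' @param path file path.
#' @return `read_trial_records()` returns the data frame;
#'   `write_trial_records()` returns `path` invisibly.
#' @export
write_trial_records <- function(records, path) {
  write.csv(records, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trial_records
#' @export
read_trial_records <- function(path) {
  rec <- read.csv(path, stringsAsFactors = FALSE)
  needed <- c("subject_id", "condition", "coherence_signed", "choice",
              "responded", "decision_time_s", "previous_choice")
  missing <- setdiff(needed, names(rec))
  if (length(missing))
    stop("trial-record file is missing columns: ",
         paste(missing, collapse = ", "), call. = FALSE)
  rec
}

#' Write a rate trace as CSV
#'
#' Two-column (plus label) tabular format: `time_ms`, `rate_hz`,
#' `population`.
#'
#' @param trace data frame with `time_ms` and `rate_hz` (and optionally
#'   `population`), e.g. from [population_rate_trace()].
#' @param path file path.
#' @export
write_rate_trace <- function(trace, path) {
  stopifnot(all(c("time_ms", "rate_hz") %in% names(trace)))
  write.csv(trace, path, row.names = FALSE)
  invisible(path)
}

#' Write spike events as two-column text
#'
#' Plain whitespace-separated `neuron_id time_ms` lines.
#'
#' @param spike_neuron integer neuron ids.
#' @param spike_time_ms spike times (ms).
#' @param path file path.
#' @export
write_spikes <- function(spike_neuron, spike_time_ms, path) {
  stopifnot(length(spike_neuron) == length(spike_time_ms))
  utils::write.table(data.frame(neuron_id = spike_neuron,
                                time_ms = spike_time_ms),
                     path, row.names = FALSE, col.names = TRUE, quote = FALSE)
  invisible(path)
}
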