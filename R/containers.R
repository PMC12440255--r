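#' Channel timeseries container
#'
#' Holds multichannel optical data as a channels x timepoints matrix together
#' with its sampling rate, start time, channel table and signal kind.
#'
#' @param data Numeric matrix, channels in rows, timepoints in columns.
#' @param rate_hz Sampling rate in Hz (> 0).
#' @param t0_s Time of the first sample in seconds.
#' @param channel_table Data frame describing the rows (typically the
#'   `channels` table of a [default_probe()] layout, one row per data row).
#' @param kind One of `"intensity"`, `"od"` (optical density) or `"hb"`
#'   (hemoglobin concentration, uM). For `"hb"` data the channel table must
#'   carry a `chromophore` column with values `"HbO"`/`"HbR"`.
#' @return An object of class `channel_timeseries`.
#' @export
channel_timeseries <- function(data, rate_hz, t0_s = 0, channel_table = NULL,
                               kind = c("od", "intensity", "hb")) {
  kind <- match.arg(kind)
  data <- as.matrix(data)
  if (!is.numeric(data) || any(!is.finite(data)))
    stop_arg("data must be a finite numeric matrix")
  if (!is.numeric(rate_hz) || rate_hz <= 0) stop_arg("rate_hz must be > 0")
  if (!is.null(channel_table) && nrow(channel_table) != nrow(data))
    stop_arg("channel_table must have one row per data row")
  structure(list(data = data, rate_hz = rate_hz, t0_s = t0_s,
                 channel_table = channel_table, kind = kind),
            class = "channel_timeseries")
}

#' @export
print.channel_timeseries <- function(x, ...) {
  cat(sprintf("<channel_timeseries> %s: %d channels x %d samples @ %.3g Hz (t0 = %.2f s)\n",
              x$kind, nrow(x$data), ncol(x$data), x$rate_hz, x$t0_s))
  invisible(x)
}

#' Sample times of a channel timeseries
#' @param ts A `channel_timeseries`.
#' @return Numeric vector of sample times in seconds.
#' @export
ts_times <- function(ts) ts$t0_s + (seq_len(ncol(ts$data)) - 1L) / ts$rate_hz

# replace the data matrix, keeping metadata
ts_with_data <- function(ts, data, rate_hz = ts$rate_hz, t0_s = ts$t0_s,
                         kind = ts$kind, channel_table = ts$channel_table) {
  channel_timeseries(data, rate_hz, t0_s, channel_table, kind)
}

#' Trial schedule accessors
#'
#' `schedule_trial_windows()` returns, per trial, the gaze analysis window
#' running from auditory cue onset to the end of the expected stimulus
#' presentation (cue duration + stimulus duration, 2.55 s by default).
#' `schedule_event_end()` returns the end time of the last event.
#'
#' @param schedule A `trial_schedule` from [generate_trial_schedule()].
#' @return For `schedule_trial_windows()`, a data frame with `trial`, `type`,
#'   `start_s`, `end_s`.
#' @export
schedule_trial_windows <- function(schedule) {
  tr <- schedule$trials
  data.frame(trial = seq_len(nrow(tr)), type = tr$type,
             start_s = tr$cue_onset_s,
             end_s = tr$cue_onset_s + schedule$cue_dur_s + schedule$stim_dur_s)
}

#' @rdname schedule_trial_windows
#' @export
schedule_event_end <- function(schedule) {
  max(schedule$trials$stim_onset_s) + schedule$stim_dur_s
}
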