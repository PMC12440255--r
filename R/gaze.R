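#' Per-trial dwell-time ratio (DTR)
#'
#' For each trial, the DTR is the valid gaze time inside the area of interest
#' divided by the total valid tracking time within the trial window (auditory
#' cue onset to the end of the expected stimulus presentation window).
#' Samples are attributed to the window by their timestamp over the half-open
#' interval `[start, end)`; invalid samples are excluded from both numerator
#' and denominator, and a trial with no valid samples gets a missing DTR
#' (not zero).
#'
#' @param gaze A `gaze_recording` (see [generate_gaze()] or
#'   [read_gaze_csv()]).
#' @param schedule A `trial_schedule`.
#' @return Object of class `dtr_series`: data frame with `trial`, `type`,
#'   `dtr`, `valid_time_s`, `start_s`, `end_s`.
#' @export
compute_dtr <- function(gaze, schedule) {
  s <- gaze$samples
  win <- schedule_trial_windows(schedule)
  if (min(s$time_s) > min(win$start_s) || max(s$time_s) < max(win$end_s) - 1e-9)
    warning("gaze recording does not fully cover the schedule's trial windows")
  aoi <- gaze$aoi
  in_aoi <- s$x_px >= aoi[1] & s$x_px <= aoi[3] &
            s$y_px >= aoi[2] & s$y_px <= aoi[4]
  dt <- 1 / infer_rate(s$time_s)
  out <- win
  out$dtr <- NA_real_
  out$valid_time_s <- 0
  for (i in seq_len(nrow(win))) {
    idx <- s$time_s >= win$start_s[i] & s$time_s < win$end_s[i] & s$valid
    nv <- sum(idx)
    out$valid_time_s[i] <- nv * dt
    if (nv > 0) out$dtr[i] <- sum(in_aoi[idx]) / nv
  }
  structure(out[, c("trial", "type", "dtr", "valid_time_s", "start_s", "end_s")],
            class = c("dtr_series", "data.frame"))
}

infer_rate <- function(times) {
  d <- diff(sort(times))
  d <- d[d > 0]
  if (!length(d)) return(1)
  1 / stats::median(d)
}

#' Scale DTR values for use as a parametric modulator
#'
#' Fixed affine map from the theoretical \[0, 1\] DTR domain onto
#' `[lo, hi]` (default 0.1 to 1), applied before convolution with the
#' canonical HRF. A fixed map (rather than per-subject min-max) keeps the
#' modulator comparable across subjects and is deterministic for constant
#' series. Missing values stay missing.
#'
#' @param dtr A `dtr_series` or numeric vector of DTR values in \[0, 1\].
#' @param lo,hi Target range (default 0.1, 1); `lo < hi` required.
#' @return Numeric vector of scaled values.
#' @examples
#' scale_dtr(c(0, 0.5, 1)) # 0.10 0.55 1.00
#' @export
scale_dtr <- function(dtr, lo = 0.1, hi = 1) {
  if (lo >= hi) stop_arg("lo must be < hi")
  x <- if (inherits(dtr, "dtr_series")) dtr$dtr else dtr
  if (any(x < -1e-12 | x > 1 + 1e-12, na.rm = TRUE))
    stop_arg("DTR values must lie in [0, 1]")
  lo + (hi - lo) * x
}

#' Subject inclusion rule
#'
#' A subject is included when the number of trials with a non-missing DTR is
#' at least `min_per_type` (default 3) for every trial type.
#'
#' @param dtr A `dtr_series` aligned to `schedule`.
#' @param schedule The matching `trial_schedule`.
#' @param min_per_type Minimum usable trials per type (default 3).
#' @return List with `include` (logical) and `counts` (named integer vector
#'   of usable trials per type).
#' @export
subject_inclusion <- function(dtr, schedule, min_per_type = 3) {
  if (nrow(dtr) != nrow(schedule$trials))
    stop_arg("dtr series and schedule are not aligned")
  types <- c("expected", "unexpected")
  counts <- vapply(types, function(ty)
    sum(dtr$type == ty & !is.na(dtr$dtr)), integer(1))
  list(include = all(counts >= min_per_type), counts = counts)
}

#' Read / write gaze recordings as CSV
#'
#' Columns: `time_s`, `x_px`, `y_px`, `valid` (0/1).
#'
#' @param path File path.
#' @param gaze A `gaze_recording`.
#' @param screen_px Display size for the reader (default 1920 x 1080, with
#'   the AOI spanning the full display).
#' @return `read_gaze_csv()` returns a `gaze_recording`;
#'   `write_gaze_csv()` returns `path` invisibly.
#' @export
read_gaze_csv <- function(path, screen_px = c(1920, 1080)) {
  d <- utils::read.csv(path)
  need <- c("time_s", "x_px", "y_px", "valid")
  if (!all(need %in% names(d)))
    stop_arg("gaze CSV must have columns ", paste(need, collapse = ", "))
  structure(list(samples = data.frame(time_s = d$time_s, x_px = d$x_px,
                                      y_px = d$y_px, valid = as.logical(d$valid)),
                 screen_px = screen_px,
                 aoi = c(0, 0, screen_px[1], screen_px[2]),
                 dtr_true = NULL),
            class = "gaze_recording")
}

#' @rdname read_gaze_csv
#' @export
write_gaze_csv <- function(gaze, path) {
  s <- gaze$samples
  s$valid <- as.integer(s$valid)
  utils::write.csv(s, path, row.names = FALSE)
  invisible(path)
}
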