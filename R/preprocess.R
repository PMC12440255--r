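#' Detect motion artifacts in optical-density data
#'
#' Sliding-window detector: for each channel, any window of `t_motion_s`
#' seconds whose peak-to-peak excursion exceeds `amp_thresh` OD, or exceeds
#' `std_thresh` times the channel's standard deviation of sample-to-sample
#' differences, is flagged; flagged windows are dilated by `t_mask_s` on each
#' side and merged.
#'
#' @param ts A `channel_timeseries` of kind `"od"`.
#' @param t_motion_s Detection window length in seconds (default 1).
#' @param t_mask_s Dilation of flagged windows in seconds (default 1).
#' @param std_thresh Multiplier on the channel-wise SD of first differences
#'   (default 15).
#' @param amp_thresh Absolute peak-to-peak OD threshold (default 0.4).
#' @return Object of class `motion_mask`: list with `segments` (per channel,
#'   a data frame of merged `start_s`, `end_s`), `rate_hz`, `n_samples`,
#'   `t0_s`.
#' @export
detect_motion <- function(ts, t_motion_s = 1, t_mask_s = 1,
                          std_thresh = 15, amp_thresh = 0.4) {
  if (ts$kind != "od") stop_arg("detect_motion expects optical-density data")
  fs <- ts$rate_hz
  w <- max(2L, round(t_motion_s * fs))
  if (round(t_motion_s * fs) < 2L)
    stop_arg("t_motion_s spans fewer than 2 samples at this rate")
  n <- ncol(ts$data)
  dil <- round(t_mask_s * fs)
  segs <- vector("list", nrow(ts$data))
  for (c_i in seq_len(nrow(ts$data))) {
    x <- ts$data[c_i, ]
    sd_diff <- stats::sd(diff(x))
    ptp <- rolling_ptp(x, w)                       # windows starting at 1..n-w+1
    hit <- ptp > amp_thresh | ptp > std_thresh * sd_diff
    flag <- logical(n)
    if (any(hit)) {
      starts <- which(hit)
      for (s0 in starts) flag[max(1L, s0 - dil):min(n, s0 + w - 1L + dil)] <- TRUE
    }
    segs[[c_i]] <- logical_to_segments(flag, fs, ts$t0_s)
  }
  structure(list(segments = segs, rate_hz = fs, n_samples = n, t0_s = ts$t0_s),
            class = "motion_mask")
}

logical_to_segments <- function(flag, fs, t0) {
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(start_s = t0 + (starts[keep] - 1L) / fs,
             end_s = t0 + (ends[keep] - 1L) / fs)
}

# logical vector of masked samples for one channel
mask_flags <- function(mask, channel) {
  flag <- logical(mask$n_samples)
  seg <- mask$segments[[channel]]
  if (is.null(seg) || !nrow(seg)) return(flag)
  tt <- mask$t0_s + (seq_len(mask$n_samples) - 1L) / mask$rate_hz
  for (i in seq_len(nrow(seg)))
    flag[tt >= seg$start_s[i] - 1e-9 & tt <= seg$end_s[i] + 1e-9] <- TRUE
  flag
}

#' Prune channels by separation and coefficient of variation
#'
#' A channel is rejected when its source-detector separation exceeds
#' `max_sep_mm` (default 60 mm) or when its intensity coefficient of
#' variation over motion-artifact-free samples exceeds `cv_max` percent
#' (default 8%). Optical-density input is mapped back to relative intensity
#' as `exp(-OD)` for the CV computation.
#'
#' @param ts A `channel_timeseries` of kind `"intensity"` or `"od"`.
#' @param probe Optional `probe_layout`; defaults to `ts$channel_table`.
#' @param max_sep_mm Maximum source-detector distance (default 60).
#' @param cv_max Maximum CV in percent (default 8).
#' @param mask Optional `motion_mask` from [detect_motion()]; CV is computed
#'   over unmasked samples only. A channel with no artifact-free samples is
#'   rejected with reason `"uncomputable CV"`.
#' @return Data frame: `channel`, `keep`, `cv_pct`, `sd_distance_mm`,
#'   `reason` (`""` when kept).
#' @export
prune_channels <- function(ts, probe = NULL, max_sep_mm = 60, cv_max = 8,
                           mask = NULL) {
  chan <- if (!is.null(probe)) probe$channels else ts$channel_table
  if (is.null(chan$sd_distance_mm)) stop_arg("channel table lacks sd_distance_mm")
  inten <- switch(ts$kind,
                  intensity = ts$data,
                  od = exp(-ts$data),
                  stop_arg("CV pruning needs intensity or od data"))
  out <- data.frame(channel = seq_len(nrow(ts$data)),
                    keep = TRUE, cv_pct = NA_real_,
                    sd_distance_mm = chan$sd_distance_mm, reason = "")
  for (c_i in seq_len(nrow(ts$data))) {
    ok <- if (is.null(mask)) rep(TRUE, ncol(ts$data)) else !mask_flags(mask, c_i)
    if (!any(ok)) {
      out$keep[c_i] <- FALSE; out$reason[c_i] <- "uncomputable CV"
    } else {
      x <- inten[c_i, ok]
      cv <- 100 * stats::sd(x) / mean(x)
      out$cv_pct[c_i] <- cv
      if (!is.finite(cv)) { out$keep[c_i] <- FALSE; out$reason[c_i] <- "uncomputable CV" }
      else if (cv > cv_max) { out$keep[c_i] <- FALSE; out$reason[c_i] <- "CV" }
    }
    if (out$sd_distance_mm[c_i] > max_sep_mm) {
      out$keep[c_i] <- FALSE
      out$reason[c_i] <- trimws(paste(out$reason[c_i], "separation"))
    }
  }
  out
}

#' Spline correction of masked motion segments
#'
#' Within each masked segment a smoothing spline is fitted (penalty written
#' as in the MATLAB `csaps` convention: parameter `p` close to 1 follows the
#' data closely) and subtracted; the segment is then re-leveled so its mean
#' matches the preceding clean data, and following data are level-aligned to
#' preserve continuity so that persistent baseline steps inside the mask are
#' repaired. Segments shorter than 4 samples receive a mean-shift correction
#' only.
#'
#' @param ts A `channel_timeseries` of kind `"od"`.
#' @param mask A `motion_mask`.
#' @param p Smoothing parameter in (0, 1) (default 0.99).
#' @return Corrected `channel_timeseries`.
#' @export
correct_spline <- function(ts, mask, p = 0.99) {
  if (ts$kind != "od") stop_arg("correct_spline expects optical-density data")
  if (p <= 0 || p >= 1) stop_arg("p must be in (0, 1)")
  fs <- ts$rate_hz
  lev_w <- max(1L, round(2 * fs))   # window for level estimation (~2 s)
  dat <- ts$data
  for (c_i in seq_len(nrow(dat))) {
    flag <- mask_flags(mask, c_i)
    if (!any(flag)) next
    x <- dat[c_i, ]
    r <- rle(flag)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    level <- NULL   # running level: mean of tail of previously processed data
    for (k in seq_along(r$values)) {
      idx <- starts[k]:ends[k]
      seg <- x[idx]
      if (r$values[k]) {            # artifact segment
        base <- if (length(seg) >= 4) {
          # csaps-convention penalty on unit-spaced samples; smooth.spline
          # rescales x to [0, 1], which scales the roughness integral by
          # range^3
          lam <- max(1e-12, (1 - p) / p / (length(seg) - 1)^3)
          sp <- stats::smooth.spline(seq_along(seg), seg, lambda = lam,
                                     cv = FALSE)
          stats::predict(sp, seq_along(seg))$y
        } else rep(mean(seg), length(seg))
        resid <- seg - base
        ref <- level %||% mean(seg[seq_len(min(lev_w, length(seg)))])
        x[idx] <- resid - mean(resid) + ref
      } else if (!is.null(level)) { # clean segment after an artifact: re-align
        head_m <- mean(seg[seq_len(min(lev_w, length(seg)))])
        x[idx] <- seg - head_m + level
      }
      level <- mean(x[idx][max(1L, length(idx) - lev_w + 1L):length(idx)])
    }
    dat[c_i, ] <- x
  }
  ts_with_data(ts, dat)
}

#' Zero-phase FIR band-pass filter
#'
#' Designs a linear-phase (Hamming-window) FIR band-pass filter and applies
#' it forward-backward for zero phase, preserving the latency of bin-indexed
#' FIR averages downstream. The default band 0.01 to 0.5 Hz removes slow
#' drifts and cardiac pulsation. The filter order required for >= 20 dB
#' stopband attenuation at `f_lo / 2` grows as the low cut-off shrinks; if
#' the recording is too short to support it, the function errors naming the
#' minimum length unless `strict = FALSE`, in which case the longest
#' realizable filter is used with a warning.
#'
#' @param ts A `channel_timeseries`.
#' @param f_lo,f_hi Band edges in Hz, `f_lo < f_hi < rate/2`.
#' @param order Optional FIR order (even); computed from the band edges when
#'   `NULL`.
#' @param strict Error (default) vs warn when the recording cannot support
#'   the required order.
#' @return Filtered `channel_timeseries`.
#' @export
bandpass <- function(ts, f_lo = 0.01, f_hi = 0.5, order = NULL, strict = TRUE) {
  fs <- ts$rate_hz
  if (!(f_lo < f_hi && f_hi < fs / 2))
    stop_arg("need f_lo < f_hi < rate/2")
  n <- ncol(ts$data)
  if (is.null(order)) {
    # Hamming transition width ~3.3/N (normalized); stopband edge must reach
    # f_lo/2 below and 2*f_hi above.
    tw <- min(f_lo, 2 * f_hi) # full transition width budget (Hz)
    order <- 2L * ceiling(3.3 * fs / tw / 2)
    min_len <- 3L * order + 1L
    if (n < min_len) {
      msg <- sprintf(paste0(
        "recording too short for a %g-%g Hz band-pass at %g Hz: ",
        "need >= %d samples (%.0f s), got %d"),
        f_lo, f_hi, fs, min_len, min_len / fs, n)
      if (strict) stop_arg(msg)
      warning(msg, "; using reduced filter order")
      order <- max(8L, 2L * floor((n - 2L) / 6))
    }
  }
  h <- signal::fir1(order, c(f_lo, f_hi) * 2 / fs, type = "pass")
  dat <- t(apply(ts$data, 1L, function(x) signal::filtfilt(as.numeric(h), 1, x)))
  ts_with_data(ts, dat)
}

# filtfilt magnitude response of the band-pass design at given frequencies
bandpass_response <- function(order, f_lo, f_hi, fs, freqs_hz) {
  h <- signal::fir1(order, c(f_lo, f_hi) * 2 / fs, type = "pass")
  H <- vapply(freqs_hz, function(f) {
    z <- exp(-1i * 2 * pi * f / fs * (seq_along(h) - 1))
    Mod(sum(h * z))^2          # forward-backward: magnitude squared
  }, numeric(1))
  H
}

#' Modified Beer-Lambert conversion to hemoglobin concentrations
#'
#' For every source-detector pair with both wavelengths present (and kept,
#' if `keep` is given), solves
#' `dOD(lambda) = [eps_HbO(lambda) dHbO + eps_HbR(lambda) dHbR] * d_mm * DPF`
#' per timepoint for `(dHbO, dHbR)` in uM. Pairs missing a wavelength are
#' dropped and recorded in the `dropped_pairs` attribute.
#'
#' @param ts A `channel_timeseries` of kind `"od"` with a channel table
#'   carrying `source_id`, `detector_id`, `wavelength_nm`, `sd_distance_mm`.
#' @param dpf Differential pathlength factor, identical at both wavelengths
#'   (default 5.1, an infant-appropriate value).
#' @param extinction 2 x 2 extinction matrix (rows = wavelengths in the order
#'   they appear, columns HbO/HbR) in mm^-1 uM^-1; defaults to
#'   [extinction_coefficients()] at the table's wavelengths.
#' @param keep Optional logical vector (length = channels) of channels to use.
#' @return A `channel_timeseries` of kind `"hb"` with two rows (HbO, HbR) per
#'   retained pair; concentrations in uM.
#' @export
mbll <- function(ts, dpf = 5.1, extinction = NULL, keep = NULL) {
  if (ts$kind != "od") stop_arg("mbll expects optical-density data")
  ch <- ts$channel_table
  if (is.null(ch)) stop_arg("mbll needs a channel table")
  wls <- sort(unique(ch$wavelength_nm))
  if (length(wls) != 2L) stop_arg("mbll needs exactly two wavelengths, got ",
                                  length(wls))
  E <- extinction %||% extinction_coefficients(wls)
  if (abs(det(E)) < 1e-12 * max(abs(E))^2)
    stop_arg("extinction matrix is singular; check wavelength choice")
  keep <- keep %||% rep(TRUE, nrow(ch))
  pair_id <- interaction(ch$source_id, ch$detector_id, drop = TRUE)
  out_rows <- list(); out_tab <- list(); dropped <- character()
  for (p in levels(pair_id)) {
    idx <- which(pair_id == p & keep)
    w_here <- ch$wavelength_nm[idx]
    if (!all(wls %in% w_here)) { dropped <- c(dropped, p); next }
    i1 <- idx[match(wls[1], w_here)]; i2 <- idx[match(wls[2], w_here)]
    d_mm <- ch$sd_distance_mm[i1]
    A <- E * d_mm * dpf
    hb <- solve(A, rbind(ts$data[i1, ], ts$data[i2, ]))
    out_rows[[length(out_rows) + 1L]] <- hb
    out_tab[[length(out_tab) + 1L]] <- data.frame(
      source_id = ch$source_id[i1], detector_id = ch$detector_id[i1],
      chromophore = c("HbO", "HbR"), sd_distance_mm = d_mm)
  }
  if (!length(out_rows)) stop_arg("no source-detector pair has both wavelengths")
  res <- channel_timeseries(do.call(rbind, out_rows), ts$rate_hz, ts$t0_s,
                            do.call(rbind, out_tab), "hb")
  attr(res, "dropped_pairs") <- dropped
  res
}

# forward map: hb (2k x n, alternating HbO/HbR rows per pair) -> od
# convenience for round-trip testing
mbll_forward <- function(hb_ts, dpf = 5.1, extinction = NULL,
                         wavelengths_nm = c(735, 850)) {
  ch <- hb_ts$channel_table
  E <- extinction %||% extinction_coefficients(wavelengths_nm)
  pairs <- unique(ch[, c("source_id", "detector_id", "sd_distance_mm")])
  rows <- list(); tab <- list()
  for (i in seq_len(nrow(pairs))) {
    sel <- ch$source_id == pairs$source_id[i] & ch$detector_id == pairs$detector_id[i]
    hbo <- hb_ts$data[which(sel & ch$chromophore == "HbO"), ]
    hbr <- hb_ts$data[which(sel & ch$chromophore == "HbR"), ]
    A <- E * pairs$sd_distance_mm[i] * dpf
    od <- A %*% rbind(hbo, hbr)
    rows[[i]] <- od
    tab[[i]] <- data.frame(source_id = pairs$source_id[i],
                           detector_id = pairs$detector_id[i],
                           wavelength_nm = wavelengths_nm,
                           sd_distance_mm = pairs$sd_distance_mm[i])
  }
  channel_timeseries(do.call(rbind, rows), hb_ts$rate_hz, hb_ts$t0_s,
                     do.call(rbind, tab), "od")
}

#' Trim and resample a recording
#'
#' Crops the time axis to `[first cue onset - 2 s, last event end + 3 s]` and
#' resamples to `target_hz` (default 4 Hz) with an anti-aliasing low-pass
#' filter followed by spline interpolation onto the new grid.
#'
#' @param ts A `channel_timeseries`.
#' @param target_hz Target rate, `<= ts$rate_hz` (default 4).
#' @param schedule The session's `trial_schedule`.
#' @return Trimmed, resampled `channel_timeseries` with updated `t0_s`.
#' @export
resample_trim <- function(ts, target_hz = 4, schedule) {
  if (target_hz > ts$rate_hz) stop_arg("target_hz must be <= the current rate")
  tt <- ts_times(ts)
  t_start <- min(schedule$trials$cue_onset_s) - 2
  t_end <- schedule_event_end(schedule) + 3
  if (t_start < min(tt) - 1e-9 || t_end > max(tt) + 1e-9)
    stop_arg("schedule (plus trim margins) extends outside the recording span")
  keep <- tt >= t_start - 1e-9 & tt <= t_end + 1e-9
  dat <- ts$data[, keep, drop = FALSE]
  tt <- tt[keep]
  if (target_hz == ts$rate_hz)
    return(ts_with_data(ts, dat, t0_s = tt[1]))
  # anti-alias below the new Nyquist, then interpolate
  ord <- min(64L, 2L * floor((ncol(dat) - 2L) / 6))
  h <- signal::fir1(ord, 0.9 * target_hz / ts$rate_hz, type = "low")
  new_t <- seq(tt[1], tt[length(tt)], by = 1 / target_hz)
  out <- matrix(0, nrow(dat), length(new_t))
  for (c_i in seq_len(nrow(dat))) {
    xf <- signal::filtfilt(as.numeric(h), 1, dat[c_i, ])
    out[c_i, ] <- stats::spline(tt, xf, xout = new_t)$y
  }
  ts_with_data(ts, out, rate_hz = target_hz, t0_s = new_t[1])
}

#' Epoching and block averages
#'
#' Cuts 9-s epochs (default window -2 to +7 s around stimulus onset),
#' subtracts the mean of the 2-s pre-onset baseline per epoch and channel,
#' and averages epochs within condition. Epochs extending past the recording
#' are dropped with a warning.
#'
#' @param ts A `channel_timeseries` (typically kind `"hb"`).
#' @param schedule A `trial_schedule`.
#' @param window Epoch window in seconds relative to onset (default
#'   `c(-2, 7)`).
#' @param baseline Baseline interval in seconds relative to onset (default
#'   `c(-2, 0)`).
#' @return Object of class `epoch_set`: list with `epochs` (per condition, a
#'   trials x channels x time array), `means` (per condition, channels x
#'   time), `times_s` (relative time axis), `window`, `baseline`,
#'   `channel_table`, `dropped` (count).
#' @export
block_average <- function(ts, schedule, window = c(-2, 7), baseline = c(-2, 0)) {
  fs <- ts$rate_hz
  rel_idx <- seq(round(window[1] * fs), round(window[2] * fs) - 1L)
  times_rel <- rel_idx / fs
  bl <- times_rel >= baseline[1] - 1e-9 & times_rel < baseline[2] - 1e-9
  n <- ncol(ts$data)
  onsets <- round((schedule$trials$stim_onset_s - ts$t0_s) * fs) + 1L
  conds <- c("expected", "unexpected")
  epochs <- list(); dropped <- 0L
  for (cond in conds) {
    tr_idx <- which(schedule$trials$type == cond)
    mats <- list()
    for (i in tr_idx) {
      idx <- onsets[i] + rel_idx
      if (min(idx) < 1L || max(idx) > n) { dropped <- dropped + 1L; next }
      ep <- ts$data[, idx, drop = FALSE]
      ep <- ep - rowMeans(ep[, bl, drop = FALSE])
      mats[[length(mats) + 1L]] <- ep
    }
    arr <- array(NA_real_, c(length(mats), nrow(ts$data), length(rel_idx)))
    for (k in seq_along(mats)) arr[k, , ] <- mats[[k]]
    epochs[[cond]] <- arr
  }
  if (dropped > 0L) warning(dropped, " epoch(s) extended past the recording and were dropped")
  means <- lapply(epochs, function(a)
    if (dim(a)[1] == 0L) matrix(NA_real_, dim(a)[2], dim(a)[3])
    else apply(a, c(2, 3), mean))
  structure(list(epochs = epochs, means = means, times_s = times_rel,
                 window = window, baseline = baseline,
                 channel_table = ts$channel_table, dropped = dropped),
            class = "epoch_set")
}
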