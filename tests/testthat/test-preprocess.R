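test_that("motion detection flags threshold crossings with mask dilation", {
  fs <- 4.6; n <- 1200
  expect_equal(nrow(detect_motion(od_ts(rep(0.1, n)))$segments[[1]]), 0)
  set.seed(1)
  x <- rnorm(n, 0, 0.005); x[600:n] <- x[600:n] + 0.5
  m <- detect_motion(od_ts(x))          # defaults (1, 1, 15, 0.4)
  seg <- m$segments[[1]]
  t_step <- 599 / fs
  expect_equal(nrow(seg), 1)
  expect_lte(seg$start_s, t_step - 0.9)  # dilated ~1 s before
  expect_gte(seg$end_s, t_step + 0.9)
  expect_error(detect_motion(od_ts(x), t_motion_s = 0.1), "2 samples")
  expect_error(detect_motion(channel_timeseries(matrix(x, 1), fs, 0, NULL, "hb")),
               "optical-density")
})

test_that("channel pruning applies separation and CV rules", {
  tab <- data.frame(source_id = 1, detector_id = 1:3, wavelength_nm = 735,
                    sd_distance_mm = c(30, 65, 30))
  set.seed(2)
  inten <- rbind(rep(1, 500),                       # CV 0, 30 mm -> keep
                 rep(1, 500),                       # 65 mm -> separation
                 1 + rnorm(500, 0, 0.1))            # CV ~10% -> CV reject
  ts <- channel_timeseries(inten, 4.6, 0, tab, "intensity")
  pr <- prune_channels(ts)
  expect_equal(pr$keep, c(TRUE, FALSE, FALSE))
  expect_match(pr$reason[2], "separation")
  expect_match(pr$reason[3], "CV")
  expect_equal(pr$cv_pct[3], 10, tolerance = 1)
  # channel fully masked -> uncomputable CV
  od <- channel_timeseries(rbind(c(rep(0, 250), rep(0.6, 250))), 4.6, 0,
                           tab[1, ], "od")
  mask <- structure(list(segments = list(data.frame(start_s = 0, end_s = 499 / 4.6)),
                         rate_hz = 4.6, n_samples = 500, t0_s = 0),
                    class = "motion_mask")
  pr2 <- prune_channels(od, mask = mask)
  expect_false(pr2$keep[1])
  expect_match(pr2$reason[1], "uncomputable")
})

test_that("spline correction repairs baseline steps inside the mask", {
  fs <- 4.6; n <- 1200
  set.seed(3)
  x <- rnorm(n, 0, 0.005); x[600:n] <- x[600:n] + 0.3
  ts <- od_ts(x)
  m <- detect_motion(ts)
  expect_identical(correct_spline(ts, detect_motion(od_ts(rep(0, n))))$data,
                   ts$data)   # empty mask -> identity
  cor1 <- correct_spline(ts, m, p = 0.99)
  resid_step <- mean(cor1$data[1, 650:n]) - mean(cor1$data[1, 1:550])
  expect_lt(abs(resid_step), 0.1 * 0.3)
  expect_error(correct_spline(ts, m, p = 1.2), "p must")
})

test_that("wavelet correction suppresses spikes and preserves slow signal", {
  fs <- 4.6; n <- 1200; tt <- (0:(n - 1)) / fs
  # benign data with huge fences: numerically exact pass-through
  set.seed(4)
  w0 <- od_ts(rnorm(1024, 0, 0.01))
  expect_lt(max(abs(correct_wavelet(w0, 10)$data - w0$data)), 1e-8)
  slow <- 0.1 * sin(2 * pi * 0.05 * tt)
  spike <- numeric(n); spike[500] <- 0.3
  ts <- od_ts(slow + spike + rnorm(n, 0, 0.002))
  out <- correct_wavelet(ts, 0.8)
  expect_lt(abs(out$data[1, 500] - slow[500]), 0.25 * 0.3)
  amp <- unname(coef(lm(out$data[1, ] ~ 0 + sin(2 * pi * 0.05 * tt))))
  expect_equal(amp, 0.1, tolerance = 0.2 * 0.1)
  expect_warning(correct_wavelet(od_ts(rnorm(2))), "pass")
})

test_that("TDDR leaves trends alone and removes slow large excursions", {
  fs <- 4; n <- 1200
  lin <- od_ts(0.01 * (0:(n - 1)) / fs, fs)
  expect_equal(correct_tddr(lin)$data, lin$data)
  expect_equal(correct_tddr(od_ts(rep(0.2, n), fs))$data,
               matrix(0.2, 1, n))
  set.seed(5)
  base <- rnorm(n, 0, 0.01)
  idx <- 500:515                           # 4-s, 10-sigma square excursion
  x <- base; x[idx] <- x[idx] + 0.1
  out <- correct_tddr(od_ts(x, fs))
  resid <- out$data[1, ] - base
  level <- median(resid[c(1:400, 700:n)])
  center <- mean(resid[506:509])
  expect_lt(abs(center - level), 0.1 * 0.1)   # >= 90% removed at center
  # persistent baseline step is repaired
  x2 <- base; x2[600:n] <- x2[600:n] + 0.3
  out2 <- correct_tddr(od_ts(x2, fs))
  expect_lt(abs(mean(out2$data[1, 700:n]) - mean(out2$data[1, 1:500])), 0.03)
})

test_that("band-pass filter meets its gain contract and length rule", {
  fs <- 4.6
  # frequency response of the default 0.01-0.5 Hz design (filtfilt magnitude)
  ord <- 2 * ceiling(3.3 * fs / 0.01 / 2)
  H <- nidot:::bandpass_response(ord, 0.01, 0.5, fs, c(0.001, 0.005, 0.1, 1.0))
  expect_lt(H[1], 0.01)                    # 0.001 Hz drift: >> 20 dB down
  expect_lt(H[2], 0.01)                    # f_lo / 2: >= 20 dB down
  expect_gt(H[3], 0.95); expect_lt(H[3], 1.05)   # 0.1 Hz passband
  expect_lt(H[4], 0.01)                    # 2 * f_hi: >= 20 dB down
  # filtering a long 0.1 Hz probe preserves amplitude
  np <- 3 * ord + 100; tp <- (0:(np - 1)) / fs
  sfil <- bandpass(od_ts(sin(2 * pi * 0.1 * tp)))
  mid <- (np %/% 4):(3 * np %/% 4)
  expect_equal(sqrt(2 * mean(sfil$data[1, mid]^2)), 1, tolerance = 0.05)
  # too-short recording errors naming the minimum length
  expect_error(bandpass(od_ts(rnorm(500))), "need >= ")
  expect_warning(bandpass(od_ts(rnorm(500)), strict = FALSE), "reduced")
  expect_error(bandpass(od_ts(rnorm(500)), f_lo = 0.5, f_hi = 3), "rate/2")
})

test_that("MBLL inverts the forward model and is linear", {
  probe <- default_probe(n_tiles = 1)
  sch <- generate_trial_schedule(6, 0.8, seed = 6)
  tr <- subject_truth()
  chd <- generate_channel_data(sch, tr, probe, noiseless_cfg(), seed = 7)
  hb <- mbll(chd$ts)
  od_back <- nidot:::mbll_forward(hb)
  k1 <- with(chd$ts$channel_table, paste(source_id, detector_id, wavelength_nm))
  k2 <- with(od_back$channel_table, paste(source_id, detector_id, wavelength_nm))
  expect_lt(max(abs(od_back$data[match(k1, k2), ] - chd$ts$data)), 1e-10)
  # zero OD -> zero Hb
  z <- mbll(channel_timeseries(matrix(0, nrow(probe$channels), 10), 4.6, 0,
                               probe$channels, "od"))
  expect_true(all(z$data == 0))
  # linearity
  chd2 <- generate_channel_data(sch, subject_truth(beta_expected = 0.1,
                                                   beta_unexpected = 0.2),
                                probe, noiseless_cfg(), seed = 7)
  lhs <- mbll(channel_timeseries(2 * chd$ts$data + 3 * chd2$ts$data, 4.6, 0,
                                 probe$channels, "od"))
  expect_lt(max(abs(lhs$data - (2 * mbll(chd$ts)$data + 3 * mbll(chd2$ts)$data))),
            1e-10)
  # a pair missing one wavelength is dropped and reported
  keep <- rep(TRUE, nrow(probe$channels))
  keep[which(probe$channels$wavelength_nm == 850)[1]] <- FALSE
  hb_k <- mbll(chd$ts, keep = keep)
  expect_equal(length(attr(hb_k, "dropped_pairs")), 1)
  expect_error(mbll(chd$ts, extinction = matrix(1, 2, 2)), "singular")
})

test_that("trim and resample preserve in-band content and update the clock", {
  fs <- 4.6
  sch <- generate_trial_schedule(20, 0.8, seed = 8)
  ns <- ceiling((sch$session_end_s + 2) * fs)
  tt <- (0:(ns - 1)) / fs
  ts <- od_ts(sin(2 * pi * 0.1 * tt))
  r <- resample_trim(ts, 4, sch)
  expect_equal(r$rate_hz, 4)
  expect_lt(abs(r$t0_s - (min(sch$trials$cue_onset_s) - 2)), 1 / fs)
  expect_equal(sqrt(2 * mean(r$data[1, ]^2)), 1, tolerance = 0.02)
  # target = source rate: trim only
  r2 <- resample_trim(ts, fs, sch)
  expect_equal(r2$rate_hz, fs)
  expect_lte(max(ts_times(r2)), schedule_event_end(sch) + 3 + 1e-9)
  short <- od_ts(rnorm(50))
  expect_error(resample_trim(short, 4, sch), "outside the recording")
})

test_that("block averaging subtracts baselines over 9-s epochs", {
  fs <- 4
  sch <- generate_trial_schedule(8, 0.8, seed = 9)
  n <- ceiling((sch$session_end_s + 10) * fs)
  # constant signal -> all-zero epochs
  const <- channel_timeseries(matrix(5, 2, n), fs, 0,
                              data.frame(chromophore = c("HbO", "HbR")), "hb")
  ep <- block_average(const, sch)
  expect_equal(ep$times_s[1], -2)
  expect_equal(length(ep$times_s), 9 * fs)
  expect_true(all(abs(unlist(ep$epochs)) < 1e-12))
  # planted response is recovered exactly without noise on a sparse
  # schedule (no overlap between neighbouring responses)
  sch_sp <- generate_trial_schedule(8, 0.8, seed = 9,
                                    baseline_range_s = c(30, 32))
  tr <- subject_truth(attention_coupling = 1)
  amp <- beta_amplitudes(tr, sch_sp, rep(1, 8))
  roi <- simulate_roi_trace(sch_sp, amp, fs, noise_sd = 0, seed = 1)
  ep2 <- block_average(roi, sch_sp)
  h <- canonical_hrf(ep2$times_s)
  for (cond in c("expected", "unexpected")) {
    b <- if (cond == "expected") 0.4 else 0.7
    if (dim(ep2$epochs[[cond]])[1] > 0)
      expect_lt(max(abs(ep2$means[[cond]][1, ] - b * h)), 1e-10)
  }
  # epochs running past the recording end are dropped with a warning
  n_cut <- round((max(sch_sp$trials$stim_onset_s) + 3) * fs)
  shorted <- channel_timeseries(roi$data[, 1:n_cut, drop = FALSE],
                                fs, 0, roi$channel_table, "hb")
  expect_warning(block_average(shorted, sch_sp), "dropped")
})
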