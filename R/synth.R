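#' Generate a trial schedule for the prediction-error paradigm
#'
#' Events follow the paradigm structure: a 750-ms auditory cue, then a
#' 1800-ms visual stimulus window in which the expected cartoon appears with
#' probability `p_expected` ("expected" trials) or is omitted ("unexpected"
#' trials), separated by jittered baselines drawn uniformly from
#' `baseline_range_s`.
#'
#' @param n_trials Number of trials (>= 1).
#' @param p_expected Probability of an expected trial, in (0, 1].
#' @param seed Optional integer seed; the same seed yields an identical
#'   schedule and the caller's RNG stream is left untouched.
#' @param cue_dur_s Auditory cue duration in seconds (default 0.75).
#' @param stim_dur_s Stimulus window duration in seconds (default 1.8).
#' @param baseline_range_s Length-2 vector, inter-trial baseline range in
#'   seconds (default `c(3, 5)`).
#' @return Object of class `trial_schedule`: list with a `trials` data frame
#'   (`cue_onset_s`, `stim_onset_s`, `type`), the durations, and
#'   `session_end_s`.
#' @examples
#' sch <- generate_trial_schedule(27, 0.8, seed = 1)
#' table(sch$trials$type)
#' @export
generate_trial_schedule <- function(n_trials, p_expected = 0.8, seed = NULL,
                                    cue_dur_s = 0.75, stim_dur_s = 1.8,
                                    baseline_range_s = c(3, 5)) {
  if (!is.numeric(n_trials) || length(n_trials) != 1L || n_trials < 1)
    stop_arg("n_trials must be a positive count")
  n_trials <- as.integer(n_trials)
  if (p_expected <= 0 || p_expected > 1)
    stop_arg("p_expected must be in (0, 1]")
  if (length(baseline_range_s) != 2L || baseline_range_s[1] > baseline_range_s[2])
    stop_arg("baseline_range_s must be (lo, hi) with lo <= hi")
  with_seed(seed, {
    gaps <- stats::runif(n_trials + 1L, baseline_range_s[1], baseline_range_s[2])
    type <- ifelse(stats::runif(n_trials) < p_expected, "expected", "unexpected")
    trial_len <- cue_dur_s + stim_dur_s
    cue_onset <- cumsum(gaps[seq_len(n_trials)]) + (seq_len(n_trials) - 1L) * trial_len
    trials <- data.frame(cue_onset_s = cue_onset,
                         stim_onset_s = cue_onset + cue_dur_s,
                         type = type)
    structure(list(trials = trials, cue_dur_s = cue_dur_s,
                   stim_dur_s = stim_dur_s,
                   baseline_range_s = baseline_range_s,
                   session_end_s = max(trials$stim_onset_s) + stim_dur_s +
                     gaps[n_trials + 1L]),
              class = "trial_schedule")
  })
}

#' @export
print.trial_schedule <- function(x, ...) {
  cat(sprintf("<trial_schedule> %d trials (%d expected / %d unexpected), %.1f s session\n",
              nrow(x$trials), sum(x$trials$type == "expected"),
              sum(x$trials$type == "unexpected"), x$session_end_s))
  invisible(x)
}

#' Default per-subject ground truth
#'
#' Bundles the planted quantities for one simulated subject. Response
#' amplitudes are in uM HbO; the engagement (dwell-time-ratio, DTR) model is
#' `dtr = engagement_intercept + condition_gaze_effect * unexpected +
#' habituation_slope * (trial - 1) + noise`, clamped to \[0, 1\]. Trial
#' amplitude couples to engagement as
#' `beta_condition * (attention_coupling + (1 - attention_coupling) * dtr)`.
#'
#' Defaults mirror the study conditions: a -0.10 condition effect on DTR, a
#' -0.014/trial habituation slope, STAI-range anxiety scores, and infant-scale
#' HbO amplitudes.
#'
#' @param beta_expected,beta_unexpected Planted response amplitudes (uM HbO).
#' @param trait_anxiety,state_anxiety STAI scores in \[20, 80\].
#' @param engagement_intercept Baseline DTR level.
#' @param condition_gaze_effect Additive DTR shift on unexpected trials.
#' @param habituation_slope DTR change per trial.
#' @param attention_coupling Coupling parameter `a` in \[0, 1\]; `a = 1`
#'   removes any dependence of the response on engagement.
#' @param dtr_sd Trial-to-trial DTR noise SD.
#' @return A list of class `ground_truth`.
#' @export
subject_truth <- function(beta_expected = 0.4, beta_unexpected = 0.7,
                          trait_anxiety = 36, state_anxiety = 35,
                          engagement_intercept = 0.68,
                          condition_gaze_effect = -0.10,
                          habituation_slope = -0.014,
                          attention_coupling = 0.5, dtr_sd = 0.18) {
  stopifnot(attention_coupling >= 0, attention_coupling <= 1)
  if (trait_anxiety < 20 || trait_anxiety > 80 || state_anxiety < 20 || state_anxiety > 80)
    stop_arg("STAI scores must lie in [20, 80]")
  structure(as.list(environment()), class = "ground_truth")
}

#' Planted per-trial DTR values for a schedule
#'
#' @param truth A `ground_truth` from [subject_truth()].
#' @param schedule A `trial_schedule`.
#' @param seed Optional seed.
#' @return Numeric vector of true DTR values in \[0, 1\], one per trial.
#' @export
trial_dtr_truth <- function(truth, schedule, seed = NULL) {
  tr <- schedule$trials
  with_seed(seed, {
    mu <- truth$engagement_intercept +
      truth$condition_gaze_effect * (tr$type == "unexpected") +
      truth$habituation_slope * (seq_len(nrow(tr)) - 1L)
    pmin(1, pmax(0, mu + stats::rnorm(nrow(tr), 0, truth$dtr_sd)))
  })
}

# Planted per-trial HbO amplitude (uM) under the attention coupling model.
trial_amplitudes <- function(truth, schedule, dtr_true) {
  beta <- ifelse(schedule$trials$type == "unexpected",
                 truth$beta_unexpected, truth$beta_expected)
  a <- truth$attention_coupling
  beta * (a + (1 - a) * dtr_true)
}

#' Generate synthetic gaze samples for a schedule
#'
#' Emulates a 100-Hz eye-tracker: within each trial's analysis window the
#' probability that a sample falls inside the area of interest (AOI) equals
#' the trial's true DTR, so the realized in-AOI fraction computed by
#' [compute_dtr()] is an unbiased estimate of `dtr_true`. Samples are dropped
#' (flagged invalid) at rate `loss_rate`, emulating tracker signal loss.
#'
#' @param schedule A `trial_schedule`.
#' @param truth A `ground_truth` or a list carrying a numeric `dtr_true`
#'   vector (one value per trial). When a `ground_truth` is given, per-trial
#'   DTR values are drawn via [trial_dtr_truth()].
#' @param sample_rate_hz Gaze sampling rate (default 100 Hz).
#' @param loss_rate Probability in \[0, 1) that a sample is invalid.
#' @param seed Optional seed.
#' @param screen_px Display size in pixels (default 1920 x 1080).
#' @return Object of class `gaze_recording`: list with a `samples` data frame
#'   (`time_s`, `x_px`, `y_px`, `valid`), `screen_px`, `aoi` (full display
#'   rectangle `c(x0, y0, x1, y1)`), and the per-trial `dtr_true` used.
#' @export
generate_gaze <- function(schedule, truth, sample_rate_hz = 100,
                          loss_rate = 0.05, seed = NULL,
                          screen_px = c(1920, 1080)) {
  if (nrow(schedule$trials) == 0L) stop_arg("schedule has no trials")
  if (sample_rate_hz <= 0) stop_arg("sample_rate_hz must be > 0")
  if (loss_rate < 0 || loss_rate >= 1) stop_arg("loss_rate must be in [0, 1)")
  with_seed(seed, {
    dtr_true <- if (!is.null(truth$dtr_true)) truth$dtr_true
                else trial_dtr_truth(truth, schedule)
    if (length(dtr_true) != nrow(schedule$trials))
      stop_arg("dtr_true must have one value per trial")
    tt <- seq(0, schedule$session_end_s, by = 1 / sample_rate_hz)
    n <- length(tt)
    win <- schedule_trial_windows(schedule)
    p_in <- rep(0.5, n)  # between trials: irrelevant to DTR, wanders on/off
    for (i in seq_len(nrow(win))) {
      idx <- tt >= win$start_s[i] & tt < win$end_s[i]
      p_in[idx] <- dtr_true[i]
    }
    in_aoi <- stats::runif(n) < p_in
    x <- ifelse(in_aoi, stats::runif(n, 0, screen_px[1]), -100)
    y <- ifelse(in_aoi, stats::runif(n, 0, screen_px[2]), -100)
    valid <- stats::runif(n) >= loss_rate
    structure(list(samples = data.frame(time_s = tt, x_px = x, y_px = y,
                                        valid = valid),
                   screen_px = screen_px,
                   aoi = c(0, 0, screen_px[1], screen_px[2]),
                   dtr_true = dtr_true),
              class = "gaze_recording")
  })
}

#' Extinction coefficients for HbO and HbR
#'
#' Molar extinction coefficients from the Gratzer/Prahl compilation at the
#' default operating wavelengths, converted to natural-log units of
#' mm^-1 uM^-1 as used by the forward model and the modified Beer-Lambert
#' inversion.
#'
#' @param wavelengths_nm Wavelengths to look up (subset of 735, 850 unless a
#'   custom `table` is supplied).
#' @param table Optional custom data frame with columns `wavelength_nm`,
#'   `hbo`, `hbr` in cm^-1 M^-1 (base-10 convention).
#' @return Matrix with rows per wavelength and columns `HbO`, `HbR`, in
#'   mm^-1 uM^-1 (natural log).
#' @export
extinction_coefficients <- function(wavelengths_nm = c(735, 850), table = NULL) {
  base <- table %||% data.frame(
    wavelength_nm = c(735, 850),
    hbo = c(404.0, 1058.0),    # cm^-1 / M, base-10
    hbr = c(1075.4, 691.3))
  idx <- match(wavelengths_nm, base$wavelength_nm)
  if (any(is.na(idx)))
    stop_arg("no extinction values for wavelength(s) ",
             paste(wavelengths_nm[is.na(idx)], collapse = ", "),
             "; supply a custom table")
  conv <- log(10) * 1e-7  # cm^-1/M (base-10) -> mm^-1/uM (natural log)
  out <- cbind(HbO = base$hbo[idx], HbR = base$hbr[idx]) * conv
  rownames(out) <- as.character(wavelengths_nm)
  out
}

#' Default noise and artifact configuration for the optical generator
#'
#' Amplitudes are in optical-density units. The cardiac component sits at
#' 2.0 Hz, below the 2.3-Hz Nyquist frequency of the 4.6-Hz acquisition.
#'
#' @param ... Named overrides of the default fields.
#' @return Named list of generator noise parameters.
#' @export
default_noise_cfg <- function(...) {
  cfg <- list(white_sd = 0.010, ar1_phi = 0.4, ar1_sd = 0.010,
              drift_amp = 0.020, drift_freq_hz = 0.002,
              cardiac_amp = 0.005, cardiac_freq_hz = 2.0,
              spike_rate_per_min = 0.5, spike_amp = 0.25,
              shift_rate_per_min = 0.2, shift_amp = 0.15,
              dpf = 5.1, hbr_ratio = -1/3)
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) stop_arg("unknown noise_cfg field(s): ",
                                paste(unknown, collapse = ", "))
  utils::modifyList(cfg, over)
}

#' Generate two-wavelength optical-density channel data
#'
#' Forward-simulates a session: each trial adds an HbO response of amplitude
#' `beta_condition * (a + (1 - a) * dtr_true)` (and `hbr_ratio` times that in
#' HbR) convolved with the canonical infant HRF, mapped to optical density at
#' both wavelengths through the same extinction matrix the modified
#' Beer-Lambert inversion uses, plus drift, cardiac, AR(1) and white noise,
#' and randomly planted spike and baseline-shift artifacts.
#'
#' @param schedule A `trial_schedule`.
#' @param truth A `ground_truth` (see [subject_truth()]); per-trial DTR values
#'   are drawn via [trial_dtr_truth()] unless `truth$dtr_true` is present.
#' @param probe A `probe_layout`; every channel's wavelength must have
#'   extinction values.
#' @param noise_cfg See [default_noise_cfg()].
#' @param seed Optional seed.
#' @param rate_hz Acquisition rate (default 4.6 Hz).
#' @param channel_gain Optional per-channel multiplicative gain on the planted
#'   response (default 1 for all channels), usable to create a spatial
#'   activation profile.
#' @return List with `ts` (a `channel_timeseries`, kind `"od"`) and `truth`
#'   (the input truth echoed back with `dtr_true`, per-trial `amplitude_uM`,
#'   and an `artifacts` data frame `channel`, `time_s`, `kind`, `amplitude`).
#' @export
generate_channel_data <- function(schedule, truth, probe,
                                  noise_cfg = default_noise_cfg(),
                                  seed = NULL, rate_hz = 4.6,
                                  channel_gain = NULL) {
  ext <- extinction_coefficients(unique(probe$channels$wavelength_nm))
  with_seed(seed, {
    dtr_true <- truth$dtr_true %||% trial_dtr_truth(truth, schedule)
    amp <- trial_amplitudes(truth, schedule, dtr_true)
    n <- ceiling(schedule$session_end_s * rate_hz) + 1L  # cover session_end
    onset_idx <- pmax(1L, round(schedule$trials$stim_onset_s * rate_hz) + 1L)
    hbo <- convolve_events(n, rate_hz, onset_idx, amp)
    hbr <- noise_cfg$hbr_ratio * hbo
    ch <- probe$channels
    nc <- nrow(ch)
    gain <- channel_gain %||% rep(1, nc)
    eps <- ext[as.character(ch$wavelength_nm), , drop = FALSE]
    scale <- (eps[, "HbO"] + eps[, "HbR"] * noise_cfg$hbr_ratio) *
      ch$sd_distance_mm * noise_cfg$dpf * gain
    dat <- outer(scale, hbo)   # channels x time signal component
    tt <- (seq_len(n) - 1L) / rate_hz
    artifacts <- list()
    dur_min <- n / rate_hz / 60
    for (c_i in seq_len(nc)) {
      noise <- stats::rnorm(n, 0, noise_cfg$white_sd)
      if (noise_cfg$ar1_sd > 0)
        noise <- noise + as.numeric(stats::arima.sim(
          list(ar = noise_cfg$ar1_phi), n,
          sd = noise_cfg$ar1_sd * sqrt(1 - noise_cfg$ar1_phi^2)))
      noise <- noise +
        noise_cfg$drift_amp * sin(2 * pi * noise_cfg$drift_freq_hz * tt +
                                    stats::runif(1, 0, 2 * pi)) +
        noise_cfg$cardiac_amp * sin(2 * pi * noise_cfg$cardiac_freq_hz * tt +
                                      stats::runif(1, 0, 2 * pi))
      n_spk <- stats::rpois(1, noise_cfg$spike_rate_per_min * dur_min)
      if (n_spk > 0) {
        for (s_i in seq_len(n_spk)) {
          at <- sample.int(n, 1)
          a0 <- noise_cfg$spike_amp * sample(c(-1, 1), 1) * stats::runif(1, 0.5, 1.5)
          idx <- at:min(n, at + ceiling(rate_hz))
          noise[idx] <- noise[idx] + a0 * exp(-(idx - at) / (0.3 * rate_hz))
          artifacts[[length(artifacts) + 1L]] <-
            data.frame(channel = c_i, time_s = tt[at], kind = "spike", amplitude = a0)
        }
      }
      n_shf <- stats::rpois(1, noise_cfg$shift_rate_per_min * dur_min)
      if (n_shf > 0) {
        for (s_i in seq_len(n_shf)) {
          at <- sample.int(n, 1)
          a0 <- noise_cfg$shift_amp * sample(c(-1, 1), 1) * stats::runif(1, 0.5, 1.5)
          noise[at:n] <- noise[at:n] + a0
          artifacts[[length(artifacts) + 1L]] <-
            data.frame(channel = c_i, time_s = tt[at], kind = "baseline_shift",
                       amplitude = a0)
        }
      }
      dat[c_i, ] <- dat[c_i, ] + noise
    }
    echo <- truth
    echo$dtr_true <- dtr_true
    echo$amplitude_uM <- amp
    echo$artifacts <- if (length(artifacts)) do.call(rbind, artifacts)
                      else data.frame(channel = integer(), time_s = numeric(),
                                      kind = character(), amplitude = numeric())
    list(ts = channel_timeseries(dat, rate_hz, 0, ch, "od"), truth = echo)
  })
}

#' Simulate a region-of-interest hemoglobin trace
#'
#' Fast single-series path used for GLM calibration studies: plants
#' per-trial HbO amplitudes convolved with the canonical HRF on an AR(1)
#' noise background, directly in concentration units.
#'
#' @param schedule A `trial_schedule`.
#' @param amplitudes Per-trial response amplitudes (uM).
#' @param rate_hz Sampling rate of the simulated trace (default 4 Hz).
#' @param ar_phi,noise_sd AR(1) coefficient and marginal SD of the noise.
#' @param seed Optional seed.
#' @return A single-channel `channel_timeseries` of kind `"hb"`.
#' @export
simulate_roi_trace <- function(schedule, amplitudes, rate_hz = 4,
                               ar_phi = 0.4, noise_sd = 0.5, seed = NULL) {
  with_seed(seed, {
    n <- ceiling((schedule_event_end(schedule) + 15) * rate_hz)
    onset_idx <- pmax(1L, round(schedule$trials$stim_onset_s * rate_hz) + 1L)
    y <- convolve_events(n, rate_hz, onset_idx, amplitudes)
    if (noise_sd > 0) {
      eps <- if (abs(ar_phi) > 0)
        as.numeric(stats::arima.sim(list(ar = ar_phi), n,
                                    sd = noise_sd * sqrt(1 - ar_phi^2)))
      else stats::rnorm(n, 0, noise_sd)
      y <- y + eps
    }
    channel_timeseries(matrix(y, 1), rate_hz, 0,
                       data.frame(chromophore = "HbO"), "hb")
  })
}

#' Generate a synthetic cohort
#'
#' Draws per-subject planted parameters: STAI trait/state anxiety
#' (truncated-normal within the 20-80 STAI range), expected-condition
#' amplitudes, and unexpected-condition amplitudes coupled to trait anxiety
#' as `beta_unexpected_i = b0 + b1 * trait_i + eps_i`. State anxiety is
#' generated uncoupled from the response. A subset of subjects (default 25 of
#' 31) is flagged as having maternal anxiety scores available, emulating the
#' respondent rule of the anxiety analyses.
#'
#' @param n_subjects Number of subjects (default 31).
#' @param anxiety_cfg Named list of generator parameters; see
#'   [default_anxiety_cfg()].
#' @param coupling_b1 Trait-anxiety slope `b1` on the unexpected amplitude,
#'   in uM per STAI point (default 0.01).
#' @param seed Optional seed.
#' @param n_anxiety Number of subjects with maternal scores available
#'   (default `min(25, n_subjects)`).
#' @return Object of class `cohort`: list with a `subjects` data frame and
#'   the configuration used. `subjects` columns include `subject`,
#'   `trait_anxiety`, `state_anxiety`, `clinical` (trait > 40),
#'   `mother_completed`, `beta_expected`, `beta_unexpected`,
#'   `engagement_intercept`, `habituation_slope`, `condition_gaze_effect`.
#' @export
generate_cohort <- function(n_subjects = 31, anxiety_cfg = default_anxiety_cfg(),
                            coupling_b1 = 0.01, seed = NULL,
                            n_anxiety = min(25L, n_subjects)) {
  if (n_subjects < 2) stop_arg("n_subjects must be >= 2")
  cfg <- anxiety_cfg
  if (cfg$trait_sd == 0 && coupling_b1 != 0)
    warning("trait anxiety has zero variance; planted coupling b1 is unidentifiable")
  with_seed(seed, {
    rtrunc <- function(n, mean, sd) {
      x <- stats::rnorm(n, mean, sd)
      while (any(bad <- x < 20 | x > 80)) x[bad] <- stats::rnorm(sum(bad), mean, sd)
      x
    }
    trait <- rtrunc(n_subjects, cfg$trait_mean, cfg$trait_sd)
    state <- rtrunc(n_subjects, cfg$state_mean, cfg$state_sd)
    # shared per-subject responsiveness: amplitudes correlate across
    # conditions within an infant, which is what the group-stage random
    # intercept absorbs
    u <- stats::rnorm(n_subjects, 0, cfg$subject_sd)
    beta_u <- cfg$beta0_unexpected + coupling_b1 * trait + u +
      stats::rnorm(n_subjects, 0, cfg$beta_sd)
    beta_e <- u + stats::rnorm(n_subjects, cfg$beta_expected_mean,
                               cfg$beta_expected_sd)
    subjects <- data.frame(
      subject = seq_len(n_subjects),
      trait_anxiety = trait, state_anxiety = state,
      clinical = trait > cfg$clinical_cutoff,
      mother_completed = seq_len(n_subjects) <= n_anxiety,
      beta_expected = beta_e, beta_unexpected = beta_u,
      engagement_intercept = pmin(0.98, pmax(0.05,
        stats::rnorm(n_subjects, cfg$engagement_mean, cfg$engagement_sd))),
      habituation_slope = cfg$habituation_slope,
      condition_gaze_effect = cfg$condition_gaze_effect)
    structure(list(subjects = subjects, anxiety_cfg = cfg,
                   coupling_b1 = coupling_b1,
                   attention_coupling = cfg$attention_coupling,
                   dtr_sd = cfg$dtr_sd),
              class = "cohort")
  })
}

#' Default cohort-level generator configuration
#'
#' @param ... Named overrides.
#' @return Named list: STAI means/SDs, clinical cutoff, amplitude
#'   distribution, engagement distribution, habituation slope, condition DTR
#'   effect, attention coupling and DTR noise.
#' @export
default_anxiety_cfg <- function(...) {
  cfg <- list(trait_mean = 36, trait_sd = 9, state_mean = 35, state_sd = 9,
              clinical_cutoff = 40,
              beta0_unexpected = 0.3, beta_sd = 0.12, subject_sd = 0.1,
              beta_expected_mean = 0.4, beta_expected_sd = 0.08,
              engagement_mean = 0.68, engagement_sd = 0.22,
              habituation_slope = -0.014, condition_gaze_effect = -0.10,
              attention_coupling = 0.5, dtr_sd = 0.18)
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) stop_arg("unknown anxiety_cfg field(s): ",
                                paste(unknown, collapse = ", "))
  utils::modifyList(cfg, over)
}

#' Ground truth for one cohort subject
#'
#' @param cohort A `cohort` from [generate_cohort()].
#' @param subject Subject index.
#' @return A `ground_truth` list for use with the per-subject generators.
#' @export
cohort_subject_truth <- function(cohort, subject) {
  s <- cohort$subjects[cohort$subjects$subject == subject, ]
  if (nrow(s) != 1L) stop_arg("unknown subject ", subject)
  subject_truth(beta_expected = s$beta_expected,
                beta_unexpected = s$beta_unexpected,
                trait_anxiety = s$trait_anxiety, state_anxiety = s$state_anxiety,
                engagement_intercept = s$engagement_intercept,
                condition_gaze_effect = s$condition_gaze_effect,
                habituation_slope = s$habituation_slope,
                attention_coupling = cohort$attention_coupling,
                dtr_sd = cohort$dtr_sd)
}
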