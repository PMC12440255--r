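# Shared simulation helpers for the test suite. Fixtures are generated in
# code; no data files are read.

noiseless_cfg <- function(...) {
  default_noise_cfg(white_sd = 0, ar1_sd = 0, drift_amp = 0, cardiac_amp = 0,
                    spike_rate_per_min = 0, shift_rate_per_min = 0, ...)
}

# schedule guaranteed to satisfy the >= 3 trials/type inclusion rule
included_schedule <- function(n_trials, p_expected, seed) {
  k <- 0
  repeat {
    sch <- generate_trial_schedule(n_trials, p_expected, seed = seed + k)
    tb <- table(sch$trials$type)
    if (length(tb) == 2 && min(tb) >= 3) return(sch)
    k <- k + 100000
  }
}

# single-channel od timeseries from a plain vector
od_ts <- function(x, rate_hz = 4.6) {
  channel_timeseries(matrix(x, 1), rate_hz, 0, NULL, "od")
}

# one replicate of the engagement-confound (mechanism) study: returns the
# U-E contrast with and without the DTR modulator plus the closed-form
# attention-referenced planted contrast for the realized trials.
mechanism_rep <- function(seed, a = 0.4, beta_e = 0.4, beta_u = 0.7) {
  sch <- included_schedule(27, 0.8, seed)
  tr <- subject_truth(beta_expected = beta_e, beta_unexpected = beta_u,
                      attention_coupling = a)
  dtr <- trial_dtr_truth(tr, sch, seed = seed + 500000)
  amp <- beta_amplitudes(tr, sch, dtr)
  roi <- simulate_roi_trace(sch, amp, 4, ar_phi = 0.4, noise_sd = 0.5,
                            seed = seed + 1000000)
  n <- ncol(roi$data)
  y <- roi$data[1, ]
  s <- scale_dtr(dtr)
  f_with <- suppressWarnings(ar_irls_fit(
    y, suppressWarnings(build_design(sch, s, "canonical", 4, n_time = n))))
  f_without <- suppressWarnings(ar_irls_fit(
    y, suppressWarnings(build_design(sch, NULL, "canonical", 4, n_time = n))))
  type <- sch$trials$type
  sE <- s[type == "expected"]; sU <- s[type == "unexpected"]
  w <- length(sE) * var(sE) / (length(sE) * var(sE) + length(sU) * var(sU))
  s_tilde <- w * mean(sU) + (1 - w) * mean(sE)
  target <- (beta_u - beta_e) * (a + (1 - a) * (s_tilde - 0.1) / 0.9)
  c(with_mod = contrast(f_with, c(unexpected = 1, expected = -1))$estimate,
    without_mod = contrast(f_without, c(unexpected = 1, expected = -1))$estimate,
    target = target)
}

beta_amplitudes <- function(truth, schedule, dtr_true) {
  beta <- ifelse(schedule$trials$type == "unexpected",
                 truth$beta_unexpected, truth$beta_expected)
  beta * (truth$attention_coupling + (1 - truth$attention_coupling) * dtr_true)
}

# subject x condition beta table for the anxiety models (subject-level fast
# path: cohort betas plus GLM-scale measurement noise)
anxiety_table <- function(seed, b1, n_subjects = 25, meas_sd = 0.12) {
  ch <- generate_cohort(n_subjects, default_anxiety_cfg(), coupling_b1 = b1,
                        seed = seed, n_anxiety = n_subjects)
  s <- ch$subjects
  with_seed_local(seed + 1, {
    data.frame(subject = rep(s$subject, 2),
               condition = rep(c("expected", "unexpected"), each = n_subjects),
               beta = c(s$beta_expected, s$beta_unexpected) +
                 rnorm(2 * n_subjects, 0, meas_sd),
               trait_anxiety = rep(s$trait_anxiety, 2),
               state_anxiety = rep(s$state_anxiety, 2),
               clinical = rep(s$clinical, 2))
  })
}

with_seed_local <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}

# unexpected-condition trait slope (estimate, p) from the interaction model
anxiety_slope <- function(tab) {
  f <- suppressMessages(fit_anxiety_interaction(tab))
  row <- f$coefficients[grepl("unexpected:", f$coefficients$term), ]
  c(estimate = row$estimate, p = row$p)
}
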