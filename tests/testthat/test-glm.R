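test_that("canonical HRF peaks at 4 s with unit height", {
  tt <- seq(0, 20, 0.01)
  h <- canonical_hrf(tt)
  expect_equal(h[1], 0)
  expect_equal(tt[which.max(h)], 4)
  expect_equal(max(h), 1)
  expect_true(all(h >= 0))
  expect_error(canonical_hrf(1, peak_s = -1), "peak_s")
})

test_that("design matrices have the documented column structure", {
  sch <- included_schedule(27, 0.8, seed = 1)
  s <- scale_dtr(runif(27))
  ds <- suppressWarnings(build_design(sch, s, "fir", rate_hz = 4))
  expect_equal(ncol(ds$X), 2 * 28 + 1 + 2)   # 59
  expect_equal(sum(grepl("^expected_bin", ds$names)), 28)
  expect_equal(sum(ds$names == "dtr_mod"), 1)
  expect_equal(nrow(ds$bin_map), 56)
  # canonical: one column per condition
  dc <- suppressWarnings(build_design(sch, s, "canonical", rate_hz = 4))
  expect_equal(ncol(dc$X), 5)
  # trials with missing DTR are excluded from all event regressors
  s2 <- s; s2[3] <- NA
  ds2 <- suppressWarnings(build_design(sch, s2, "fir", rate_hz = 4))
  expect_equal(length(ds2$usable_trials), 26)
  # dropping one early trial removes exactly its 28 bin impulses
  expect_equal(sum(ds$X[, 1:56]) - sum(ds2$X[, 1:56]), 28)
  expect_error(build_design(sch, rep(NA_real_, 27), "fir"), "no usable trials")
  # constant scaled DTR makes the modulator collinear with the condition
  # canonical columns: condition-number warning expected
  expect_warning(build_design(sch, rep(0.82, 27), "canonical", rate_hz = 4),
                 "collinear")
  expect_true(identical(suppressWarnings(build_design(sch, s, "fir", 4))$X,
                        ds$X))             # deterministic
})

test_that("AR-IRLS reduces to OLS with identity weights and order zero", {
  set.seed(2)
  for (case in 1:100) {
    n <- 60 + sample(40, 1)
    p <- sample(3:6, 1)
    X <- cbind(1, matrix(rnorm(n * (p - 1)), n))
    colnames(X) <- paste0("c", seq_len(p))
    y <- X %*% rnorm(p) + rnorm(n)
    fit <- ar_irls_fit(as.numeric(y), X, max_ar_order = 0, tukey_c = Inf)
    expect_lt(max(abs(fit$beta - qr.coef(qr(X), y))), 1e-6)
    expect_equal(fit$ar_order, 0L)
  }
})

test_that("Yule-Walker AR estimation recovers planted coefficients", {
  set.seed(3)
  x <- as.numeric(arima.sim(list(ar = 0.6), 2000))
  sel <- nidot:::select_ar(x, 8)
  expect_gte(sel$order, 1L)
  expect_equal(sel$phi[1], 0.6, tolerance = 0.1)
  # robust variant is immune to planted spikes
  xs <- x + rbinom(2000, 1, 0.05) * sample(c(-1, 1), 2000, TRUE) * 10
  selr <- nidot:::select_ar_robust(xs, 8)
  expect_equal(selr$phi[1], 0.6, tolerance = 0.1)
})

test_that("singular designs are rejected naming the collinear columns", {
  X <- cbind(a = rep(1, 50), b = rnorm(50))
  X <- cbind(X, c = X[, "b"])
  expect_error(ar_irls_fit(rnorm(50), X, max_ar_order = 0), "collinear")
  expect_error(ar_irls_fit(rnorm(10), matrix(rnorm(90), 10, 9)), "timepoints")
})

test_that("bin window convention maps the 12-24 label to 3-6 s at 4 Hz", {
  bw <- fir_bin_window(12, 24, 4)
  expect_equal(bw$window_s, c(3, 6))
  expect_equal(bw$bins, 13:24)
  lit <- fir_bin_window(12, 24, 4, convention = "literal")
  expect_equal(lit$window_s, c(2.75, 6))
  expect_equal(lit$bins, 12:24)
})

test_that("bin averaging and contrasts propagate estimates and covariance", {
  sch <- included_schedule(27, 0.8, seed = 4)
  tr <- subject_truth(attention_coupling = 1)   # amplitudes = planted betas
  dtr <- trial_dtr_truth(tr, sch, seed = 5)
  amp <- beta_amplitudes(tr, sch, dtr)
  roi <- simulate_roi_trace(sch, amp, 4, noise_sd = 0, seed = 6)
  n <- ncol(roi$data)
  ds <- suppressWarnings(build_design(sch, scale_dtr(dtr), "fir", 4,
                                      n_bins = 96, n_time = n))
  fit <- ar_irls_fit(roi$data[1, ], ds, max_ar_order = 0, tukey_c = Inf)
  bs <- average_bins(fit, 12, 24)
  lag_t <- (fir_bin_window(12, 24, 4)$bins - 1) / 4
  pred <- c(0.4, 0.7) * mean(canonical_hrf(lag_t))
  expect_equal(bs$summary$estimate, pred, tolerance = 1e-8)
  ct <- contrast(bs, c(unexpected = 1, expected = -1), "U - E")
  expect_equal(ct$estimate, pred[2] - pred[1], tolerance = 1e-8)
  # equal betas -> zero contrast, zero t
  ct0 <- contrast(structure(list(summary = data.frame(
    condition = c("expected", "unexpected"), estimate = c(1, 1),
    se = c(0.1, 0.1)), cov = diag(2) * 0.01, dof = 100,
    window_s = c(3, 6)), class = "beta_summary"),
    c(unexpected = 1, expected = -1))
  expect_equal(ct0$estimate, 0)
  expect_equal(ct0$t, 0)
  expect_error(average_bins(suppressWarnings(ar_irls_fit(
    roi$data[1, ],
    suppressWarnings(build_design(sch, scale_dtr(dtr), "canonical", 4,
                                  n_time = n)))), 12, 24), "FIR")
  expect_error(contrast(bs, c(bogus = 1)), "named by condition")
})

test_that("BH step-up matches a brute-force oracle and p.adjust", {
  brute_bh <- function(p, m) {
    ord <- order(p); n <- length(p)
    adj <- numeric(n)
    for (i in seq_len(n)) adj[i] <- min(1, min(p[ord][i:n] * m / (i:n)))
    out <- numeric(n); out[ord] <- adj; out
  }
  p <- c(0.001, 0.01, 0.02, 0.03, 0.5)
  r <- fdr_bh(p, 0.05)
  expect_equal(r$p_adjusted, c(0.005, 0.025, 1 / 30, 0.0375, 0.5))
  expect_equal(sum(r$reject), 4)
  expect_equal(r$p_adjusted, p.adjust(p, "BH"))
  set.seed(7)
  for (case in 1:50) {
    p <- runif(sample(2:20, 1))^sample(1:3, 1)
    m <- length(p) + sample(0:5, 1)
    r <- fdr_bh(p, 0.05, m = m)
    expect_equal(r$p_adjusted, brute_bh(p, m))
    expect_true(all(r$p_adjusted >= p - 1e-12))
    expect_true(all(diff(r$p_adjusted[order(p)]) >= -1e-12))  # monotone
  }
  expect_equal(fdr_bh(rep(1, 4))$reject, rep(FALSE, 4))
  expect_equal(length(fdr_bh(numeric(0))$p_adjusted), 0)
  expect_error(fdr_bh(c(0.5, 1.2)), "\\[0, 1\\]")
})
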