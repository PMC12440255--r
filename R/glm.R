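#' Build a GLM design matrix for the event-related paradigm
#'
#' Two basis choices per condition plus a single engagement modulator:
#' * `"fir"`: `n_bins` (default 28) unit-impulse regressors per condition at
#'   post-onset lags `0 .. n_bins - 1` samples, estimating the response shape
#'   bin by bin;
#' * `"canonical"`: one regressor per condition, onset impulses convolved
#'   with the canonical infant HRF ([canonical_hrf()], 4-s peak).
#'
#' The parametric modulator is a single column — onset impulses with height
#' equal to the scaled dwell-time ratio, convolved with the canonical HRF —
#' applied across all trials irrespective of condition and not
#' orthogonalized against the condition regressors. An intercept and a
#' linear drift are appended. Trials with missing DTR are excluded from all
#' event regressors. A warning is raised when the FIR span exceeds the
#' shortest inter-trial spacing (overlap is handled by linear superposition)
#' and when the design is near-collinear (condition number > 1e6).
#'
#' @param schedule A `trial_schedule`.
#' @param dtr_scaled Scaled DTR per trial (see [scale_dtr()]); `NA` drops the
#'   trial. Use `NULL` to omit the modulator column.
#' @param basis `"fir"` or `"canonical"`.
#' @param rate_hz Sampling rate of the data to be modelled (default 4).
#' @param n_bins FIR bins per condition (default 28).
#' @param t0_s Time of the first data sample (default 0).
#' @param n_time Number of data samples; default covers the schedule plus
#'   15 s.
#' @param hrf_peak_s Canonical HRF time-to-peak (default 4 s).
#' @return Object of class `design_matrix`: list with `X`, `names`,
#'   `bin_map` (FIR only; data frame `condition`, `bin`, `column`),
#'   `rate_hz`, `basis`, `usable_trials`.
#' @export
build_design <- function(schedule, dtr_scaled = NULL,
                         basis = c("fir", "canonical"), rate_hz = 4,
                         n_bins = 28, t0_s = 0, n_time = NULL,
                         hrf_peak_s = 4) {
  basis <- match.arg(basis)
  tr <- schedule$trials
  has_mod <- !is.null(dtr_scaled)
  if (has_mod && length(dtr_scaled) != nrow(tr))
    stop_arg("dtr_scaled must have one value per trial")
  usable <- if (has_mod) which(!is.na(dtr_scaled)) else seq_len(nrow(tr))
  if (!length(usable)) stop_arg("no usable trials (all DTR values missing)")
  n <- n_time %||% ceiling((schedule_event_end(schedule) + 15 - t0_s) * rate_hz)
  onset_idx <- round((tr$stim_onset_s[usable] - t0_s) * rate_hz) + 1L
  if (any(onset_idx < 1L | onset_idx > n))
    stop_arg("some trial onsets fall outside the modelled time span")
  type <- tr$type[usable]
  conds <- c("expected", "unexpected")
  cols <- list(); names_out <- character(); bin_map <- NULL
  if (basis == "fir") {
    if (min(diff(sort(tr$stim_onset_s))) < n_bins / rate_hz)
      warning("FIR span (", n_bins / rate_hz,
              " s) exceeds the shortest inter-trial spacing; ",
              "overlapping responses are modelled by linear superposition")
    bm <- list()
    for (cond in conds) {
      oi <- onset_idx[type == cond]
      for (b in seq_len(n_bins)) {
        x <- numeric(n)
        idx <- oi + (b - 1L)
        idx <- idx[idx <= n]
        x[idx] <- 1
        cols[[length(cols) + 1L]] <- x
        names_out <- c(names_out, sprintf("%s_bin%02d", cond, b))
        bm[[length(bm) + 1L]] <- data.frame(condition = cond, bin = b,
                                            column = length(cols))
      }
    }
    bin_map <- do.call(rbind, bm)
  } else {
    for (cond in conds) {
      oi <- onset_idx[type == cond]
      cols[[length(cols) + 1L]] <- convolve_events(n, rate_hz, oi,
                                                   rep(1, length(oi)),
                                                   peak_s = hrf_peak_s)
      names_out <- c(names_out, cond)
    }
  }
  if (has_mod) {
    cols[[length(cols) + 1L]] <- convolve_events(n, rate_hz, onset_idx,
                                                 dtr_scaled[usable],
                                                 peak_s = hrf_peak_s)
    names_out <- c(names_out, "dtr_mod")
  }
  cols[[length(cols) + 1L]] <- rep(1, n)
  cols[[length(cols) + 1L]] <- seq_len(n) / n - 0.5
  names_out <- c(names_out, "intercept", "drift")
  X <- do.call(cbind, cols)
  colnames(X) <- names_out
  nz <- colSums(X != 0) > 0
  if (any(!nz)) stop_arg("all-zero design column(s): ",
                         paste(names_out[!nz], collapse = ", "))
  kap <- kappa(X, exact = FALSE)
  if (is.finite(kap) && kap > 1e6)
    warning(sprintf("design matrix is near-collinear (condition number %.3g)", kap))
  structure(list(X = X, names = names_out, bin_map = bin_map,
                 rate_hz = rate_hz, basis = basis, usable_trials = usable,
                 n_bins = if (basis == "fir") n_bins else NULL),
            class = "design_matrix")
}

# Levinson-Durbin over autocovariances: innovation variances for AR orders
# 0..p_max and the coefficient vector for a requested order. `valid` marks
# samples to use (outlier spikes excluded pairwise so they do not whitewash
# the autocorrelation structure).
levinson_ar <- function(x, p_max, valid = NULL) {
  n <- length(x)
  if (is.null(valid)) {
    acv <- as.numeric(stats::acf(x, lag.max = p_max, type = "covariance",
                                 plot = FALSE, demean = TRUE)$acf)
  } else {
    xc <- x - mean(x[valid])
    acv <- vapply(0:p_max, function(k) {
      i <- seq_len(n - k)
      ok <- valid[i] & valid[i + k]
      if (!any(ok)) return(0)
      mean(xc[i][ok] * xc[i + k][ok])
    }, numeric(1))
  }
  sig <- numeric(p_max + 1L)
  sig[1] <- acv[1]
  phis <- vector("list", p_max + 1L)
  phis[[1]] <- numeric(0)
  phi <- numeric(0)
  for (p in seq_len(p_max)) {
    if (sig[p] <= 0) { sig[(p + 1L):(p_max + 1L)] <- sig[p]; phis[(p + 1L):(p_max + 1L)] <- list(phi); break }
    k <- (acv[p + 1] - sum(phi * acv[p:2][seq_len(p - 1)])) / sig[p]
    if (p == 1L) k <- acv[2] / sig[1]
    k <- max(-0.99, min(0.99, k))   # guard: pairwise acv need not be PSD
    phi_new <- c(phi - k * rev(phi), k)
    sig[p + 1L] <- sig[p] * (1 - k^2)
    phis[[p + 1L]] <- phi_new
    phi <- phi_new
  }
  list(sigma2 = sig, phis = phis, n = n)
}

# BIC-optimal Yule-Walker AR fit
select_ar <- function(x, p_max, valid = NULL) {
  p_max <- min(p_max, length(x) - 2L)
  if (p_max < 1L) return(list(order = 0L, phi = numeric(0)))
  lev <- levinson_ar(x, p_max, valid)
  n <- lev$n
  bic <- n * log(pmax(lev$sigma2, 1e-300)) + (0:p_max) * log(n)
  p <- which.min(bic) - 1L
  list(order = p, phi = if (p > 0) lev$phis[[p + 1L]] else numeric(0))
}

# Robust AR estimation in two passes: (1) Yule-Walker with BIC order choice
# on amplitude-trimmed samples; (2) spikes are re-detected in the whitened
# (innovation) domain, where additive outliers stand out against the
# compressed noise, and the AR is re-estimated with only those positions
# excluded, so genuine process tails are kept and the spike dilution of the
# autocorrelation is minimized. Plain Yule-Walker when tukey_c is infinite.
select_ar_robust <- function(x, p_max, tukey_c = 4.685) {
  if (!is.finite(tukey_c)) return(select_ar(x, p_max))
  med <- stats::median(x)
  s <- 1.4826 * stats::median(abs(x - med))
  valid <- if (s > 0) abs(x - med) <= 3 * s else NULL
  sel <- select_ar(x, p_max, valid)
  if (sel$order > 0L) {
    e <- ar_whiten(x - med, c(1, -sel$phi))
    se_ <- 1.4826 * stats::median(abs(e - stats::median(e)))
    if (se_ > 0) {
      det <- which(abs(e - stats::median(e)) > 3.5 * se_) + sel$order
      valid2 <- rep(TRUE, length(x))
      for (d in det)
        valid2[max(1L, d - sel$order):min(length(x), d + sel$order)] <- FALSE
      sel2 <- select_ar(x, p_max, valid2)
      if (sel2$order > 0L) sel <- sel2
    }
  }
  sel
}

# apply the whitening filter a = (1, -phi_1, ..., -phi_q) and drop warm-up
ar_whiten <- function(x, a) {
  if (length(a) <= 1L) return(x)
  as.numeric(stats::filter(x, a, method = "convolution",
                           sides = 1))[-seq_len(length(a) - 1L)]
}


#' AR-prewhitened iteratively reweighted least squares GLM fit
#'
#' The robust autoregressive fitting scheme used for channel and ROI
#' timeseries: iterate (robust Tukey-bisquare fit on the whitened model;
#' AR order selection by BIC over `0..max_ar_order` on the residuals via
#' Yule-Walker; AR whitening of both data and design) until the coefficient
#' vector changes by less than `tol` (relative) or `max_iter` iterations.
#' `tukey_c = Inf` disables reweighting (identity weights), reducing the fit
#' to prewhitened ordinary least squares; with `max_ar_order = 0` as well it
#' is exactly the normal-equations solution.
#'
#' @param Y Numeric data vector (timepoints).
#' @param X A `design_matrix` or plain numeric matrix.
#' @param max_ar_order Maximum AR order for BIC selection (default
#'   `ceiling(4 * rate_hz)` for a `design_matrix`, otherwise 8).
#' @param tukey_c Bisquare tuning constant (default 4.685, 95% Gaussian
#'   efficiency); `Inf` for identity weights.
#' @param tol,max_iter Outer-loop convergence controls (defaults 1e-4, 20).
#' @return Object of class `glm_fit`: list with `beta`, `se`, `cov`,
#'   `ar_order`, `ar_coeffs`, `weights` (timepoint robust weights on the
#'   whitened scale), `dof`, `residuals` (original scale), `converged`,
#'   `design` (the input design, if a `design_matrix`).
#' @export
ar_irls_fit <- function(Y, X, max_ar_order = NULL, tukey_c = 4.685,
                        tol = 1e-4, max_iter = 20L) {
  design <- NULL
  if (inherits(X, "design_matrix")) {
    design <- X
    max_ar_order <- max_ar_order %||% ceiling(4 * X$rate_hz)
    X <- X$X
  }
  max_ar_order <- max_ar_order %||% 8L
  X <- as.matrix(X)
  n <- length(Y); p <- ncol(X)
  if (nrow(X) != n) stop_arg("Y and X must have the same number of timepoints")
  if (n <= p + max_ar_order)
    stop_arg("need more timepoints than regressors plus the AR order")
  qrX <- qr(X)
  if (qrX$rank < p) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1L):p]]
    stop_arg("singular design; collinear column(s): ", paste(bad, collapse = ", "))
  }
  beta <- qr.coef(qrX, Y)
  converged <- FALSE
  phi <- numeric(0); ar_order <- 0L
  w <- rep(1, n); Yw <- Y; Xw <- X
  for (it in seq_len(max_iter)) {
    if (it <= 3L) {  # AR structure stabilizes early; freeze it afterwards
      r_raw <- Y - as.numeric(X %*% beta)
      sel <- select_ar_robust(r_raw, max_ar_order, tukey_c)
      ar_order <- sel$order; phi <- sel$phi
    }
    a <- c(1, -phi)
    Yw <- ar_whiten(Y, a)
    Xw <- if (ar_order > 0L) apply(X, 2L, ar_whiten, a = a) else X
    rob <- irls_tukey(Yw, Xw, tukey_c)
    delta <- max(abs(rob$beta - beta)) / max(1e-8, max(abs(beta)))
    beta <- rob$beta; w <- rob$w
    if (delta < tol && it > 3L) { converged <- TRUE; break }
  }
  if (!converged)
    warning("AR-IRLS did not converge in ", max_iter, " iterations; returning last iterate")
  nw <- length(Yw)
  rw <- Yw - as.numeric(Xw %*% beta)
  if (is.finite(tukey_c)) {
    # robust M-estimator variance from the whitened weighted normal
    # equations (Huber-style correction by the mean psi-derivative)
    s <- 1.4826 * stats::median(abs(rw))
    if (s < 1e-12) s <- sqrt(sum(rw^2) / max(1, nw - p)) + 1e-300
    u <- rw / s
    psi <- ifelse(abs(u) < tukey_c, u * (1 - (u / tukey_c)^2)^2, 0)
    dpsi <- ifelse(abs(u) < tukey_c,
                   (1 - (u / tukey_c)^2) * (1 - 5 * (u / tukey_c)^2), 0)
    m1 <- mean(dpsi)
    s2 <- s^2 * sum(psi^2) / (nw - p) / m1^2
    covb <- s2 * solve(crossprod(Xw))
  } else {
    s2 <- sum(rw^2) / (nw - p)
    covb <- s2 * solve(crossprod(Xw * sqrt(w)))
  }
  structure(list(beta = beta, se = sqrt(diag(covb)), cov = covb,
                 ar_order = ar_order, ar_coeffs = phi, weights = w,
                 dof = nw - p, residuals = Y - as.numeric(X %*% beta),
                 converged = converged, design = design,
                 names = colnames(X)),
            class = "glm_fit")
}

# inner robust loop (Tukey bisquare, MAD scale); bisquare is non-convex so a
# sensible beta_init matters under heavy contamination
irls_tukey <- function(Yw, Xw, tukey_c, max_iter = 30L, tol = 1e-6,
                       beta_init = NULL) {
  qrX <- qr(Xw)
  beta <- beta_init %||% qr.coef(qrX, Yw)
  n <- length(Yw)
  if (!is.finite(tukey_c)) return(list(beta = beta, w = rep(1, n)))
  w <- rep(1, n)
  for (it in seq_len(max_iter)) {
    r <- Yw - as.numeric(Xw %*% beta)
    s <- 1.4826 * stats::median(abs(r))
    if (s < 1e-12) return(list(beta = beta, w = rep(1, n)))
    u <- r / (tukey_c * s)
    w_new <- ifelse(abs(u) < 1, (1 - u^2)^2, 0)
    beta_new <- tryCatch(
      qr.coef(qr(Xw * sqrt(w_new)), Yw * sqrt(w_new)),
      error = function(e) beta)
    done <- max(abs(beta_new - beta)) / max(1e-8, max(abs(beta))) < tol
    beta <- beta_new; w <- w_new
    if (done) break
  }
  list(beta = beta, w = w)
}

#' FIR bin-to-time mapping
#'
#' Bin `b` covers `[(b - 1) / rate, b / rate)` seconds post-onset. Under the
#' default `"onset-label"` convention the summary window labelled
#' `bins 12-24 (3-6 s)` resolves to internal bins 13 to 24, i.e. the window
#' `[bin_lo / rate, bin_hi / rate)` — a 3.00-s start at 4 Hz; the
#' `"literal"` convention uses bins `bin_lo .. bin_hi` directly
#' (`[2.75, 6)` s at 4 Hz).
#'
#' @param bin_lo,bin_hi Bin labels of the averaging window.
#' @param rate_hz Sampling rate.
#' @param convention `"onset-label"` (default) or `"literal"`.
#' @return List with `bins` (internal bin indices) and `window_s`
#'   (start/end seconds post-onset).
#' @export
fir_bin_window <- function(bin_lo = 12, bin_hi = 24, rate_hz = 4,
                           convention = c("onset-label", "literal")) {
  convention <- match.arg(convention)
  bins <- if (convention == "onset-label") seq(bin_lo + 1L, bin_hi)
          else seq(bin_lo, bin_hi)
  list(bins = bins,
       window_s = c((min(bins) - 1L) / rate_hz, max(bins) / rate_hz),
       convention = convention)
}

#' Average FIR betas over the response-peak window
#'
#' Arithmetic mean of the FIR bin betas per condition over the window
#' labelled `bin_lo` to `bin_hi` (defaults 12 and 24, the 3-6-s post-onset
#' infant response peak; see [fir_bin_window()] for the label convention),
#' with the variance propagated through the corresponding covariance block.
#'
#' @param fit A `glm_fit` from a FIR design.
#' @param bin_lo,bin_hi Window labels (defaults 12, 24).
#' @param convention Bin label convention, see [fir_bin_window()].
#' @return Object of class `beta_summary`: list with `summary` (data frame
#'   `condition`, `estimate`, `se`), `cov` (2 x 2 across conditions),
#'   `dof`, `window_s`.
#' @export
average_bins <- function(fit, bin_lo = 12, bin_hi = 24,
                         convention = c("onset-label", "literal")) {
  if (is.null(fit$design) || fit$design$basis != "fir")
    stop_arg("average_bins requires a fit from an FIR design")
  bw <- fir_bin_window(bin_lo, bin_hi, fit$design$rate_hz, convention)
  if (max(bw$bins) > fit$design$n_bins || min(bw$bins) < 1L)
    stop_arg("averaging window outside 1..", fit$design$n_bins)
  bm <- fit$design$bin_map
  conds <- c("expected", "unexpected")
  k <- length(bw$bins)
  idx <- lapply(conds, function(cond)
    bm$column[bm$condition == cond & bm$bin %in% bw$bins])
  est <- vapply(idx, function(i) mean(fit$beta[i]), numeric(1))
  covb <- matrix(0, 2, 2, dimnames = list(conds, conds))
  for (i in 1:2) for (j in 1:2)
    covb[i, j] <- sum(fit$cov[idx[[i]], idx[[j]]]) / k^2
  structure(list(summary = data.frame(condition = conds, estimate = est,
                                      se = sqrt(diag(covb))),
                 cov = covb, dof = fit$dof, window_s = bw$window_s),
            class = "beta_summary")
}

#' Linear contrast of condition estimates
#'
#' `estimate = w' beta`, `t = estimate / SE`, two-sided p from the t
#' distribution at the fit's degrees of freedom. Works on a `beta_summary`
#' (FIR window averages) or directly on a canonical-basis `glm_fit` whose
#' condition columns are named `expected` / `unexpected`.
#'
#' @param x A `beta_summary` or canonical `glm_fit`.
#' @param weights Named weights over conditions, e.g.
#'   `c(unexpected = 1, expected = -1)`.
#' @param label Contrast label (default built from the weights).
#' @return One-row data frame: `label`, `estimate`, `se`, `t`, `dof`, `p`.
#' @export
contrast <- function(x, weights, label = NULL) {
  if (inherits(x, "beta_summary")) {
    est_all <- stats::setNames(x$summary$estimate, x$summary$condition)
    covb <- x$cov; dof <- x$dof
  } else if (inherits(x, "glm_fit")) {
    if (is.null(x$design) || x$design$basis != "canonical")
      stop_arg("direct contrasts need a canonical-basis fit (or a beta_summary)")
    conds <- c("expected", "unexpected")
    ci <- match(conds, x$names)
    est_all <- stats::setNames(x$beta[ci], conds)
    covb <- x$cov[ci, ci]; dimnames(covb) <- list(conds, conds); dof <- x$dof
  } else stop_arg("x must be a beta_summary or glm_fit")
  if (is.null(names(weights)) || !all(names(weights) %in% names(est_all)))
    stop_arg("weights must be named by condition: ",
             paste(names(est_all), collapse = ", "))
  w <- stats::setNames(numeric(length(est_all)), names(est_all))
  w[names(weights)] <- weights
  est <- sum(w * est_all)
  se <- sqrt(as.numeric(t(w) %*% covb %*% w))
  tval <- if (se > 0) est / se else 0
  data.frame(label = label %||% paste(names(weights)[weights != 0], collapse = " vs "),
             estimate = est, se = se, t = tval, dof = dof,
             p = 2 * stats::pt(-abs(tval), dof))
}

#' Benjamini-Hochberg step-up false discovery rate control
#'
#' Adjusted values `p_(i) = min_(j >= i) ( p_(j) * m / j )` clipped at 1;
#' a test is rejected when its adjusted p-value is at most `q`. The main
#' ROI analysis pools `m = 12` tests (6 ROIs x 2 contrasts).
#'
#' @param pvals P-values in \[0, 1\].
#' @param q False discovery rate (default 0.05).
#' @param m Number of comparisons (default `length(pvals)`).
#' @return List with `p_adjusted` (input order), `reject`, `m`.
#' @export
fdr_bh <- function(pvals, q = 0.05, m = NULL) {
  if (!length(pvals)) return(list(p_adjusted = numeric(0), reject = logical(0),
                                  m = 0L))
  if (any(pvals < 0 | pvals > 1)) stop_arg("p-values must lie in [0, 1]")
  m <- m %||% length(pvals)
  if (m < length(pvals)) stop_arg("m must be at least length(pvals)")
  ord <- order(pvals)
  ranked <- pvals[ord] * m / seq_along(pvals)
  adj <- rev(cummin(rev(ranked)))
  adj <- pmin(adj, 1)
  out <- numeric(length(pvals))
  out[ord] <- adj
  list(p_adjusted = out, reject = out <= q, m = m)
}
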