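test_that("random-intercept fits match lm when the subject variance is forced off", {
  set.seed(1)
  tab <- data.frame(subject = rep(1:6, each = 5), x = rnorm(30))
  tab$y <- 0.5 * tab$x + rnorm(30)
  f0 <- fit_random_intercept(tab, "y", "x", force_zero_ranef = TRUE)
  m <- lm(y ~ x, tab)
  expect_lt(max(abs(f0$coefficients$estimate - coef(m))), 1e-6)
  expect_equal(f0$sigma2_subject, 0)
  expect_true(f0$boundary)
})

test_that("mixed-model likelihood matches a numerically integrated oracle", {
  set.seed(2)
  tab <- data.frame(subject = rep(1:3, each = 4), x = rnorm(12))
  tab$y <- rep(rnorm(3, 0, 0.5), each = 4) + 0.5 * tab$x + rnorm(12, 0, 0.4)
  m <- lme4::lmer(y ~ x + (1 | subject), data = tab, REML = FALSE)
  vc <- as.data.frame(lme4::VarCorr(m))
  s2b <- vc$vcov[1]; s2e <- vc$vcov[2]
  be <- lme4::fixef(m)
  ll <- sum(vapply(split(seq_len(12), tab$subject), function(idx) {
    f <- function(b) vapply(b, function(bi)
      prod(dnorm(tab$y[idx] - be[1] - be[2] * tab$x[idx] - bi, 0, sqrt(s2e))) *
        dnorm(bi, 0, sqrt(s2b)), numeric(1))
    log(integrate(f, -10, 10, rel.tol = 1e-10)$value)
  }, numeric(1)))
  expect_equal(as.numeric(logLik(m)), ll, tolerance = 1e-4)
})

test_that("the condition effect on DTR is recovered from a simulated cohort", {
  ch <- generate_cohort(200, seed = 99, n_anxiety = 200)
  rows <- vector("list", 200)
  for (i in 1:200) {
    sch <- generate_trial_schedule(27, 0.8, seed = 1000 + i)
    tr <- cohort_subject_truth(ch, i)
    tr$dtr_true <- trial_dtr_truth(tr, sch, seed = 2000 + i)
    g <- generate_gaze(sch, tr, seed = 3000 + i)
    d <- compute_dtr(g, sch)
    rows[[i]] <- data.frame(subject = i, condition = d$type, dtr = d$dtr,
                            trial = d$trial)
  }
  tab <- do.call(rbind, rows)
  tab <- tab[!is.na(tab$dtr), ]
  f <- fit_random_intercept(tab, "dtr", "condition")
  est <- f$coefficients$estimate[f$coefficients$term == "conditionunexpected"]
  expect_lt(abs(est - (-0.10)), 0.02)
  # generator calibration reference: conditional R2 near 0.48, marginal small
  expect_lt(abs(f$r2_conditional - 0.48), 0.08)
  expect_lt(f$r2_marginal, 0.05)
  expect_lte(f$r2_marginal, f$r2_conditional)
  # habituation model recovers the planted trial slope
  f2 <- fit_random_intercept(tab, "dtr", "trial * condition")
  sl <- f2$coefficients$estimate[f2$coefficients$term == "trial"]
  expect_lt(abs(sl - (-0.014)), 0.004)
})

test_that("variance-partition R2 follows the component formula", {
  expect_equal(unname(r2_nakagawa(var_fixed = 1, var_subject = 1, var_resid = 2)),
               c(0.25, 0.50))
  expect_equal(unname(r2_nakagawa(var_fixed = 0, var_subject = 0, var_resid = 0)),
               c(1, 1))
  set.seed(3)
  tab <- data.frame(subject = rep(1:8, each = 6), x = rnorm(48))
  tab$y <- rep(rnorm(8), each = 6) + 0.8 * tab$x + rnorm(48)
  f <- fit_random_intercept(tab, "y", "x")
  expect_lte(f$r2_marginal, f$r2_conditional)
  expect_lte(f$r2_conditional, 1)
  expect_equal(unname(r2_nakagawa(f)),
               c(f$r2_marginal, f$r2_conditional))
})

test_that("anxiety interaction model recovers planted coupling structure", {
  # planted slope on unexpected only: expected-condition slope stays null
  est_u <- est_e <- p_e <- numeric(30)
  for (r in 1:30) {
    tab <- anxiety_table(r * 31, b1 = 0.01)
    f <- suppressMessages(fit_anxiety_interaction(tab))
    co <- f$coefficients
    est_u[r] <- co$estimate[grepl("unexpected:", co$term)]
    est_e[r] <- co$estimate[grepl("expected:", co$term) &
                              !grepl("unexpected", co$term)]
    p_e[r] <- co$p[grepl("expected:", co$term) & !grepl("unexpected", co$term)]
  }
  expect_lt(abs(mean(est_u) - 0.01), 0.003)
  expect_lt(abs(mean(est_e)), 0.004)
  expect_lt(mean(p_e < 0.05), 0.25)
  # missing-anxiety rows are dropped with a message
  tab <- anxiety_table(1, b1 = 0.01)
  tab$trait_anxiety[1:4] <- NA
  expect_message(fit_anxiety_interaction(tab), "dropping 4")
})

test_that("logistic prediction of clinical anxiety behaves at the boundaries", {
  # null predictor: Wald CI covers zero in about 95% of cohorts
  cover <- 0; nrep <- 200
  for (r in 1:nrep) {
    tab <- anxiety_table(r * 13 + 5, b1 = 0)
    sub <- tab[tab$condition == "unexpected", ]
    f <- fit_logistic_clinical(sub, "beta")
    if (f$separation) { cover <- cover + 1; next }  # no finite-claim case
    ci <- f$slope + c(-1, 1) * 1.96 * f$se
    if (ci[1] <= 0 && 0 <= ci[2]) cover <- cover + 1
  }
  expect_gt(cover / nrep, 0.90)
  expect_lt(cover / nrep, 1.00)
  # degenerate outcome errors
  tab <- data.frame(trait_anxiety = rep(30, 12), pred = rnorm(12))
  expect_error(fit_logistic_clinical(tab, "pred"), "degenerate")
  # perfect separation is flagged, not reported as a finite estimate
  tab2 <- data.frame(trait_anxiety = c(rep(30, 6), rep(60, 6)),
                     pred = c(rnorm(6, -5, 0.1), rnorm(6, 5, 0.1)))
  f2 <- fit_logistic_clinical(tab2, "pred")
  expect_true(f2$separation)
})
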