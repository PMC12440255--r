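#' Random-intercept linear mixed model
#'
#' REML fit of `response ~ fixed_terms + (1 | subject)` with
#' Satterthwaite-approximated fixed-effect tests, the standard model family
#' for trial-level DTR and subject-level beta analyses:
#' `DTR ~ condition + (1|subject)`, `DTR ~ trial * condition + (1|subject)`,
#' `beta ~ condition + (1|subject)`.
#'
#' @param table Data frame with a `subject` column, the response and the
#'   fixed-effect terms.
#' @param response Response column name.
#' @param fixed_terms Character vector of fixed-effect terms (formula
#'   syntax, e.g. `c("condition")` or `c("trial * condition")`).
#' @param reml REML (default) or ML estimation.
#' @param force_zero_ranef Fit with the subject variance forced to zero
#'   (plain linear regression through the same interface).
#' @return Object of class `mixed_fit`: list with `coefficients` (data frame
#'   `term`, `estimate`, `se`, `df`, `t`, `p`), `sigma2_subject`,
#'   `sigma2_resid`, `logLik`, `r2_marginal`, `r2_conditional`, `boundary`
#'   (TRUE when the subject variance hit zero), `n_obs`, `model`.
#' @export
fit_random_intercept <- function(table, response, fixed_terms,
                                 reml = TRUE, force_zero_ranef = FALSE) {
  if (!"subject" %in% names(table)) stop_arg("table needs a 'subject' column")
  if (length(unique(table$subject)) < 2) stop_arg("need at least 2 subjects")
  rhs <- paste(fixed_terms, collapse = " + ")
  if (force_zero_ranef) {
    f <- stats::as.formula(paste(response, "~", rhs))
    m <- stats::lm(f, data = table)
    sm <- summary(m)$coefficients
    coefs <- data.frame(term = rownames(sm), estimate = sm[, 1], se = sm[, 2],
                        df = m$df.residual, t = sm[, 3], p = sm[, 4],
                        row.names = NULL)
    s2e <- summary(m)$sigma^2
    r2 <- r2_components(stats::predict(m), 0, s2e)
    return(structure(list(coefficients = coefs, sigma2_subject = 0,
                          sigma2_resid = s2e, logLik = as.numeric(stats::logLik(m)),
                          r2_marginal = unname(r2[1]), r2_conditional = unname(r2[2]),
                          boundary = TRUE, n_obs = nrow(table), model = m),
                     class = "mixed_fit"))
  }
  f <- stats::as.formula(paste(response, "~", rhs, "+ (1 | subject)"))
  m <- lmerTest::lmer(f, data = table, REML = reml,
                      control = lme4::lmerControl(check.conv.singular = "ignore"))
  sm <- stats::coef(summary(m))
  coefs <- data.frame(term = rownames(sm), estimate = sm[, "Estimate"],
                      se = sm[, "Std. Error"], df = sm[, "df"],
                      t = sm[, "t value"], p = sm[, "Pr(>|t|)"],
                      row.names = NULL)
  vc <- as.data.frame(lme4::VarCorr(m))
  s2b <- vc$vcov[vc$grp == "subject"]
  s2e <- vc$vcov[vc$grp == "Residual"]
  r2 <- r2_components(stats::predict(m, re.form = NA), s2b, s2e)
  structure(list(coefficients = coefs, sigma2_subject = s2b, sigma2_resid = s2e,
                 logLik = as.numeric(stats::logLik(m)),
                 r2_marginal = unname(r2[1]), r2_conditional = unname(r2[2]),
                 boundary = lme4::isSingular(m), n_obs = nrow(table), model = m),
            class = "mixed_fit")
}

#' @export
print.mixed_fit <- function(x, ...) {
  cat(sprintf("<mixed_fit> n = %d, sigma2_subject = %.4g, sigma2_resid = %.4g, R2m = %.3f, R2c = %.3f%s\n",
              x$n_obs, x$sigma2_subject, x$sigma2_resid,
              x$r2_marginal, x$r2_conditional,
              if (isTRUE(x$boundary)) " (boundary fit)" else ""))
  print(x$coefficients, digits = 4)
  invisible(x)
}

r2_components <- function(fixed_pred, s2b, s2e) {
  s2f <- stats::var(fixed_pred)
  denom <- s2f + s2b + s2e
  c(marginal = s2f / denom, conditional = (s2f + s2b) / denom)
}

#' Variance-partition R-squared for mixed models
#'
#' `R2_marginal = var_fixed / (var_fixed + var_subject + var_resid)` and
#' `R2_conditional = (var_fixed + var_subject) / (same denominator)`, with
#' `var_fixed` the variance of the fixed-effect predictions over the rows —
#' the standard variance-partition definitions for random-intercept models.
#'
#' @param fit A `mixed_fit`, or `NULL` when the raw components are supplied.
#' @param var_fixed,var_subject,var_resid Raw variance components (used when
#'   `fit` is `NULL`).
#' @return Named vector `c(marginal, conditional)`.
#' @export
r2_nakagawa <- function(fit = NULL, var_fixed = NULL, var_subject = NULL,
                        var_resid = NULL) {
  if (!is.null(fit)) {
    stopifnot(inherits(fit, "mixed_fit"))
    return(c(marginal = fit$r2_marginal, conditional = fit$r2_conditional))
  }
  denom <- var_fixed + var_subject + var_resid
  if (denom == 0) return(c(marginal = 1, conditional = 1))
  c(marginal = var_fixed / denom,
    conditional = (var_fixed + var_subject) / denom)
}

#' Condition-by-trait-anxiety interaction model
#'
#' Fits `beta ~ -1 + condition + condition:trait_anxiety + (1 | subject)`:
#' no global intercept, one intercept and one trait-anxiety slope per
#' condition. The slope for the unexpected condition is the quantity of
#' interest — whether maternal trait anxiety predicts the infant's response
#' to unexpected events. Rows with missing anxiety (subjects whose mothers
#' did not complete the inventory) are dropped with a message.
#'
#' @param table Data frame with `subject`, `condition`
#'   (`"expected"`/`"unexpected"`), `beta`, `trait_anxiety`.
#' @param anxiety_col Anxiety predictor column (default `"trait_anxiety"`;
#'   use `"state_anxiety"` for the state-anxiety control model).
#' @return A `mixed_fit`; the coefficient table contains per-condition
#'   intercepts and `conditionX:...` slopes.
#' @export
fit_anxiety_interaction <- function(table, anxiety_col = "trait_anxiety") {
  need <- c("subject", "condition", "beta", anxiety_col)
  if (!all(need %in% names(table)))
    stop_arg("table needs columns ", paste(need, collapse = ", "))
  miss <- is.na(table[[anxiety_col]])
  if (any(miss)) {
    message("dropping ", sum(miss), " row(s) without ", anxiety_col, " scores")
    table <- table[!miss, ]
  }
  table$condition <- factor(table$condition, levels = c("expected", "unexpected"))
  f <- stats::as.formula(paste("beta ~ -1 + condition + condition:",
                               anxiety_col, "+ (1 | subject)"))
  m <- lmerTest::lmer(f, data = table,
                      control = lme4::lmerControl(check.conv.singular = "ignore"))
  sm <- stats::coef(summary(m))
  coefs <- data.frame(term = rownames(sm), estimate = sm[, "Estimate"],
                      se = sm[, "Std. Error"], df = sm[, "df"],
                      t = sm[, "t value"], p = sm[, "Pr(>|t|)"],
                      row.names = NULL)
  vc <- as.data.frame(lme4::VarCorr(m))
  s2b <- vc$vcov[vc$grp == "subject"]; s2e <- vc$vcov[vc$grp == "Residual"]
  r2 <- r2_components(stats::predict(m, re.form = NA), s2b, s2e)
  structure(list(coefficients = coefs, sigma2_subject = s2b, sigma2_resid = s2e,
                 logLik = as.numeric(stats::logLik(m)),
                 r2_marginal = unname(r2[1]), r2_conditional = unname(r2[2]),
                 boundary = lme4::isSingular(m), n_obs = nrow(table), model = m),
            class = "mixed_fit")
}

#' Logistic prediction of clinically elevated maternal anxiety
#'
#' Maximum-likelihood logistic regression of the clinical-anxiety flag
#' (STAI trait score above `cutoff`, default 40) on a subject-level neural
#' predictor — canonically the unexpected-event response in the right mPFC.
#' Wald statistics are reported; (quasi-)perfect separation is flagged
#' rather than reported as a finite estimate.
#'
#' @param table Subject-level data frame with `trait_anxiety` (or a logical
#'   `clinical` column) and the predictor.
#' @param predictor Predictor column name.
#' @param cutoff Clinical STAI cutoff (default 40).
#' @return List of class `logistic_fit`: `slope`, `se`, `z`, `p`,
#'   `separation` (logical), `n`, `model`.
#' @export
fit_logistic_clinical <- function(table, predictor, cutoff = 40) {
  y <- if ("clinical" %in% names(table)) as.logical(table$clinical)
       else table$trait_anxiety > cutoff
  x <- table[[predictor]]
  ok <- !is.na(y) & !is.na(x)
  y <- y[ok]; x <- x[ok]
  if (length(unique(y)) < 2) stop_arg("degenerate outcome: only one class present")
  m <- suppressWarnings(stats::glm(y ~ x, family = stats::binomial()))
  sm <- summary(m)$coefficients
  sep <- !m$converged || any(abs(sm[, 1]) > 15) ||
    all(m$fitted.values[y] > 1 - 1e-6) && all(m$fitted.values[!y] < 1e-6)
  structure(list(slope = unname(sm["x", 1]), se = unname(sm["x", 2]),
                 z = unname(sm["x", 3]), p = unname(sm["x", 4]),
                 separation = sep, n = length(y), model = m),
            class = "logistic_fit")
}
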