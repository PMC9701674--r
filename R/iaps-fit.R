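#' Fit a mixed-model group comparison by likelihood ratio
#'
#' The inferential core of the package: fits a (generalized) linear mixed
#' model by maximum likelihood together with the nested null model obtained
#' by dropping one fixed term, and tests the term's contribution with a
#' likelihood-ratio test. Coefficients carry Satterthwaite-approximation
#' p-values and confidence intervals for Gaussian responses (Wald for
#' binomial). If a random-slopes model fails to converge the pair is refitted
#' with random intercepts only (the documented fallback; reported, never
#' silent). For binomial responses, complete separation of the tested factor
#' is detected and flagged: the coefficient's inference is then unreliable.
#'
#' @param formula Mixed-model formula in \pkg{lme4} syntax, e.g.
#'   `delay ~ group + block + side + (1 + block + side | subject)`. Must
#'   contain at least one random term and the tested term as a fixed effect.
#' @param data Data frame in long format, one row per measurement.
#' @param test Name of the fixed term whose contribution is tested
#'   (default `"group"`).
#' @param family `gaussian` (LMM) or `binomial` (logistic GLMM).
#' @param fallback Refit with intercept-only random effects on convergence
#'   failure (default TRUE).
#' @param conf_level Confidence level for coefficient intervals.
#' @return Object of class `iaps_fit` with components `fit_alt`, `fit_null`
#'   (merMod objects), `coefficients` (estimate, SE, df, statistic, p, CI),
#'   `lrt` (chisq, df, p), `converged`, `fallback`, `separation`.
#' @seealso [lrt()], [anova.iaps_fit()]
#' @examples
#' \donttest{
#' cohort <- simulate_cohort(cohort_config(n_per_group = 6, seed = 3),
#'                           signals = FALSE)
#' d <- subset(cohort$truth, exclusion == "none")
#' d$delay <- d$true_delay
#' fit <- iaps_fit(delay ~ group + block + side + (1 | subject), d)
#' fit
#' }
#' @export
iaps_fit <- function(formula, data, test = "group", family = gaussian,
                     fallback = TRUE, conf_level = 0.95) {
  fam <- .resolve_family(family)
  bars <- lme4::findbars(formula)
  if (!length(bars))
    stop("formula must contain at least one random term", call. = FALSE)
  fixed_labels <- attr(stats::terms(lme4::nobars(formula)), "term.labels")
  if (!test %in% fixed_labels)
    stop(sprintf("tested term '%s' is not a fixed effect in the formula", test),
         call. = FALSE)
  f_null <- .drop_fixed_term(formula, test, bars)

  fits <- .fit_pair(f_null, formula, data, fam)
  used_fallback <- FALSE
  if (fallback && !fits$converged && .has_slopes(bars)) {
    f_alt_fb <- .intercept_only(formula, bars)
    f_null_fb <- .intercept_only(f_null, bars)
    message("random-slopes model failed to converge; refitting with random intercepts only")
    fits <- .fit_pair(f_null_fb, f_alt_fb, data, fam)
    used_fallback <- TRUE
  }

  sep <- FALSE
  if (fam$family == "binomial") {
    mf <- stats::model.frame(lme4::nobars(formula), data)
    resp <- stats::model.response(mf)
    if (test %in% names(mf)) {
      by_level <- tapply(resp, mf[[test]], function(v) length(unique(v)))
      sep <- any(by_level == 1L)
      if (sep)
        warning(sprintf("complete separation of '%s': inference on this coefficient is unreliable", test))
    }
  }

  coefs <- .coef_table(fits$alt, fam, conf_level)
  lr <- lrt(fits$null, fits$alt)
  structure(list(call = match.call(), formula = formula,
                 formula_null = f_null, family = fam$family, test = test,
                 fit_alt = fits$alt, fit_null = fits$null,
                 coefficients = coefs, lrt = lr,
                 converged = fits$converged, fallback = used_fallback,
                 separation = sep, conf_level = conf_level),
            class = "iaps_fit")
}

#' Likelihood-ratio test of two nested maximum-likelihood fits
#'
#' `statistic = 2 * (logLik(alt) - logLik(null))`, degrees of freedom equal
#' to the parameter-count difference, p-value from the upper chi-square tail.
#' Small negative statistics (within 1e-6, numerical noise at convergence
#' tolerance) are clamped to zero; larger ones signal non-nested models and
#' raise an error.
#'
#' @param null_fit,alt_fit Fitted models with a [stats::logLik()] method
#'   (e.g. `merMod`), or `iaps_fit` objects (their alternative fits are
#'   compared).
#' @return Data frame: `chisq`, `df`, `p`, plus the two log-likelihoods.
#' @export
lrt <- function(null_fit, alt_fit) {
  if (inherits(null_fit, "iaps_fit")) null_fit <- null_fit$fit_alt
  if (inherits(alt_fit, "iaps_fit")) alt_fit <- alt_fit$fit_alt
  ll0 <- stats::logLik(null_fit); ll1 <- stats::logLik(alt_fit)
  df <- attr(ll1, "df") - attr(ll0, "df")
  if (df < 1) stop("models are not nested (no extra parameters in the alternative)",
                   call. = FALSE)
  stat <- 2 * (as.numeric(ll1) - as.numeric(ll0))
  if (stat < -1e-6)
    stop("alternative fits worse than null beyond numerical tolerance; models likely not nested",
         call. = FALSE)
  stat <- max(0, stat)
  data.frame(chisq = stat, df = df, p = stats::pchisq(stat, df, lower.tail = FALSE),
             logLik_null = as.numeric(ll0), logLik_alt = as.numeric(ll1))
}

# ---- internals -------------------------------------------------------------

.resolve_family <- function(family) {
  if (is.character(family)) family <- get(family, mode = "function",
                                          envir = parent.frame())
  if (is.function(family)) family <- family()
  if (!family$family %in% c("gaussian", "binomial"))
    stop("family must be gaussian or binomial", call. = FALSE)
  family
}

.drop_fixed_term <- function(formula, test, bars) {
  fixed <- attr(stats::terms(lme4::nobars(formula)), "term.labels")
  keep <- setdiff(fixed, test)
  rhs <- paste(c(if (length(keep)) keep else "1",
                 vapply(bars, function(b) paste0("(", deparse1(b), ")"), "")),
               collapse = " + ")
  stats::as.formula(paste(deparse1(formula[[2]]), "~", rhs),
                    env = environment(formula))
}

.has_slopes <- function(bars)
  any(vapply(bars, function(b) deparse1(b[[2]]) != "1", TRUE))

.intercept_only <- function(formula, bars) {
  groups <- unique(vapply(bars, function(b) deparse1(b[[3]]), ""))
  fixed <- attr(stats::terms(lme4::nobars(formula)), "term.labels")
  rhs <- paste(c(if (length(fixed)) fixed else "1",
                 paste0("(1 | ", groups, ")")), collapse = " + ")
  stats::as.formula(paste(deparse1(formula[[2]]), "~", rhs),
                    env = environment(formula))
}

# Fit null and alternative by ML, recording convergence failures.
.fit_pair <- function(f_null, f_alt, data, fam) {
  ok <- TRUE
  grab <- function(f) {
    msgs <- character()
    fit <- withCallingHandlers(
      if (fam$family == "gaussian")
        lmerTest::lmer(f, data = data, REML = FALSE)
      else
        lme4::glmer(f, data = data, family = fam),
      warning = function(w) {
        msgs <<- c(msgs, conditionMessage(w))
        invokeRestart("muffleWarning")
      })
    conv_fail <- any(grepl("converge", msgs, ignore.case = TRUE)) ||
      (!is.null(fit@optinfo$conv$opt) && fit@optinfo$conv$opt != 0)
    if (conv_fail) ok <<- FALSE
    fit
  }
  alt <- grab(f_alt)
  null <- grab(f_null)
  list(alt = alt, null = null, converged = ok)
}

.coef_table <- function(fit, fam, conf_level) {
  cs <- stats::coef(summary(fit))
  a <- 1 - conf_level
  if (fam$family == "gaussian" && ncol(cs) >= 5) {
    # lmerTest: Estimate, Std. Error, df (Satterthwaite), t value, Pr(>|t|)
    crit <- stats::qt(1 - a / 2, cs[, "df"])
    out <- data.frame(term = rownames(cs), estimate = cs[, 1], se = cs[, 2],
                      df = cs[, "df"], statistic = cs[, 4], p = cs[, 5],
                      ci_lo = cs[, 1] - crit * cs[, 2],
                      ci_hi = cs[, 1] + crit * cs[, 2])
  } else {
    crit <- stats::qnorm(1 - a / 2)
    out <- data.frame(term = rownames(cs), estimate = cs[, 1], se = cs[, 2],
                      df = NA_real_, statistic = cs[, 3],
                      p = cs[, ncol(cs)],
                      ci_lo = cs[, 1] - crit * cs[, 2],
                      ci_hi = cs[, 1] + crit * cs[, 2])
  }
  rownames(out) <- NULL
  out
}

# ---- S3 methods ------------------------------------------------------------

#' @export
print.iaps_fit <- function(x, ...) {
  cat(sprintf("Mixed-model comparison (%s, ML): term '%s'\n", x$family, x$test))
  cat(sprintf("  LRT: chisq(%d) = %.2f, p = %.4g\n",
              x$lrt$df, x$lrt$chisq, x$lrt$p))
  idx <- grep(paste0("^", x$test), x$coefficients$term)
  for (i in idx)
    cat(sprintf("  %s: beta = %.2f, %d%% CI [%.2f, %.2f], p = %.4g\n",
                x$coefficients$term[i], x$coefficients$estimate[i],
                round(100 * x$conf_level), x$coefficients$ci_lo[i],
                x$coefficients$ci_hi[i], x$coefficients$p[i]))
  if (x$fallback)
    cat("  note: random-intercepts fallback used (slopes model did not converge)\n")
  if (x$separation)
    cat("  note: complete separation detected; coefficient inference unreliable\n")
  invisible(x)
}

#' @export
summary.iaps_fit <- function(object, ...) {
  structure(list(fit = object), class = "summary.iaps_fit")
}

#' @export
print.summary.iaps_fit <- function(x, ...) {
  f <- x$fit
  print(f)
  cat("\nFixed effects (alternative model):\n")
  print(f$coefficients, digits = 4, row.names = FALSE)
  cat("\nRandom effects:\n")
  print(lme4::VarCorr(f$fit_alt))
  invisible(x)
}

#' @export
coef.iaps_fit <- function(object, ...) {
  stats::setNames(object$coefficients$estimate, object$coefficients$term)
}

#' Likelihood-ratio comparison table
#'
#' @param object An `iaps_fit`.
#' @param ... Unused.
#' @return Data frame with one row per model (null, alternative): number of
#'   parameters, log-likelihood, and the chi-square test of the increment.
#' @export
anova.iaps_fit <- function(object, ...) {
  ll0 <- stats::logLik(object$fit_null); ll1 <- stats::logLik(object$fit_alt)
  data.frame(model = c("null", "alternative"),
             npar = c(attr(ll0, "df"), attr(ll1, "df")),
             logLik = c(as.numeric(ll0), as.numeric(ll1)),
             chisq = c(NA, object$lrt$chisq),
             df = c(NA, object$lrt$df),
             p = c(NA, object$lrt$p))
}

#' @export
logLik.iaps_fit <- function(object, ...) stats::logLik(object$fit_alt)

#' @export
residuals.iaps_fit <- function(object, ...) stats::residuals(object$fit_alt, ...)

#' @export
fitted.iaps_fit <- function(object, ...) stats::fitted(object$fit_alt)

#' Residual diagnostics for an `iaps_fit`
#'
#' Normal Q-Q plot of residuals and residuals against fitted values for the
#' alternative model.
#'
#' @param x An `iaps_fit`.
#' @param ... Passed to the plotting functions.
#' @export
plot.iaps_fit <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  r <- stats::residuals(x$fit_alt)
  stats::qqnorm(r, main = "Residual Q-Q", ...)
  stats::qqline(r)
  graphics::plot(stats::fitted(x$fit_alt), r, xlab = "Fitted",
                 ylab = "Residuals", main = "Residuals vs fitted", ...)
  graphics::abline(h = 0, lty = 2)
  invisible(x)
}
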