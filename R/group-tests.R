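#' Two-group comparison with normality/variance-based test dispatch
#'
#' Implements the dispatch used for sample-characteristics tables: if a
#' Shapiro-Wilk test flags non-normality in either group, a Mann-Whitney test
#' is run and the effect size is `r = |Z| / sqrt(N)`; otherwise, if a
#' Bartlett test flags heterogeneous variances, Welch's two-sample t test
#' with Welch-Satterthwaite degrees of freedom and Cohen's d are reported;
#' otherwise Student's t test with Cohen's d.
#'
#' @param values Numeric measurements.
#' @param groups Two-level group labels (first level of `factor(groups)` is
#'   the first group in the difference).
#' @param alpha Dispatch significance level (default 0.05).
#' @param d_variant Cohen's d denominator, see [cohens_d()].
#' @return Object of class `iaps_group_test`: method, statistic, df, p,
#'   effect size (with its name), group summaries and dispatch p-values.
#' @export
compare_groups <- function(values, groups, alpha = 0.05,
                           d_variant = c("average", "pooled")) {
  d_variant <- match.arg(d_variant)
  g <- factor(groups)
  if (nlevels(g) != 2) stop("exactly two groups required", call. = FALSE)
  keep <- is.finite(values) & !is.na(g)
  values <- values[keep]; g <- droplevels(g[keep])
  ns <- table(g)
  if (any(ns < 3)) stop("each group needs at least 3 values", call. = FALSE)
  v1 <- values[g == levels(g)[1]]; v2 <- values[g == levels(g)[2]]
  sw <- c(stats::shapiro.test(v1)$p.value, stats::shapiro.test(v2)$p.value)

  if (any(sw < alpha)) {
    wt <- stats::wilcox.test(v1, v2, exact = FALSE, correct = FALSE)
    z <- stats::qnorm(wt$p.value / 2, lower.tail = FALSE) *
      sign(unname(wt$statistic) - length(v1) * length(v2) / 2)
    res <- list(method = "mann-whitney", statistic = unname(wt$statistic),
                df = NA_real_, p = wt$p.value,
                effect = abs(z) / sqrt(length(values)), effect_name = "r",
                dispatch = list(shapiro_p = sw, bartlett_p = NA_real_))
  } else {
    bt <- stats::bartlett.test(values, g)$p.value
    welch <- bt < alpha
    tt <- stats::t.test(v1, v2, var.equal = !welch)
    res <- list(method = if (welch) "welch" else "student",
                statistic = unname(tt$statistic),
                df = unname(tt$parameter), p = tt$p.value,
                effect = cohens_d(mean(v1), stats::sd(v1), length(v1),
                                  mean(v2), stats::sd(v2), length(v2),
                                  variant = d_variant),
                effect_name = "d",
                dispatch = list(shapiro_p = sw, bartlett_p = bt))
  }
  res$groups <- levels(g)
  res$n <- as.integer(ns)
  structure(res, class = "iaps_group_test")
}

#' Two-group t statistics from printed summary statistics
#'
#' Recomputes Student or Welch t, degrees of freedom, p and Cohen's d from
#' group means, SDs and sizes (as printed in a characteristics table).
#' Dispatch between Student and Welch can be automatic via a Bartlett test,
#' which only needs the summary statistics.
#'
#' @param m1,sd1,n1,m2,sd2,n2 Group means, SDs, sizes.
#' @param test `"auto"` (Bartlett dispatch), `"student"`, or `"welch"`.
#' @param alpha Dispatch level for `"auto"`.
#' @param d_variant Cohen's d denominator, see [cohens_d()].
#' @return Object of class `iaps_group_test`.
#' @examples
#' # Age summaries of a matched two-group sample -> t(46) = 1.06
#' compare_groups_summary(40.84, 12.12, 24, 37.05, 12.66, 24)
#' @export
compare_groups_summary <- function(m1, sd1, n1, m2, sd2, n2,
                                   test = c("auto", "student", "welch"),
                                   alpha = 0.05,
                                   d_variant = c("average", "pooled")) {
  test <- match.arg(test)
  d_variant <- match.arg(d_variant)
  if (any(c(sd1, sd2) <= 0)) stop("sds must be > 0", call. = FALSE)
  if (any(c(n1, n2) < 3)) stop("each group needs at least 3 values", call. = FALSE)
  bt <- bartlett_from_summary(sd1, n1, sd2, n2)
  if (test == "auto") test <- if (bt < alpha) "welch" else "student"
  if (test == "student") {
    sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2)
    t <- (m1 - m2) / sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  } else {
    se2 <- sd1^2 / n1 + sd2^2 / n2
    t <- (m1 - m2) / sqrt(se2)
    df <- welch_satterthwaite_df(sd1, n1, sd2, n2)
  }
  structure(list(method = test, statistic = t, df = df,
                 p = 2 * stats::pt(-abs(t), df),
                 effect = cohens_d(m1, sd1, n1, m2, sd2, n2, variant = d_variant),
                 effect_name = "d",
                 dispatch = list(shapiro_p = c(NA_real_, NA_real_),
                                 bartlett_p = bt),
                 groups = c("group1", "group2"), n = c(n1, n2)),
            class = "iaps_group_test")
}

#' @export
print.iaps_group_test <- function(x, ...) {
  lab <- switch(x$method,
                student = sprintf("t(%g)", round(x$df, 1)),
                welch = sprintf("Welch t(%.1f)", x$df),
                "mann-whitney" = "U")
  cat(sprintf("%s comparison: %s = %.2f, p = %.4g, %s = %.2f\n",
              x$method, lab, x$statistic, x$p, x$effect_name, x$effect))
  invisible(x)
}

# Bartlett's test of equal variances (k = 2) from summary statistics.
bartlett_from_summary <- function(sd1, n1, sd2, n2) {
  ns <- c(n1, n2); vars <- c(sd1^2, sd2^2)
  N <- sum(ns); k <- 2
  sp2 <- sum((ns - 1) * vars) / (N - k)
  stat <- ((N - k) * log(sp2) - sum((ns - 1) * log(vars))) /
    (1 + (sum(1 / (ns - 1)) - 1 / (N - k)) / (3 * (k - 1)))
  stats::pchisq(stat, k - 1, lower.tail = FALSE)
}

#' Cohen's d from group summaries
#'
#' `variant = "average"` (default) uses the equal-weight pooled SD
#' `sqrt((sd1^2 + sd2^2) / 2)`, the convention for independent,
#' (near-)equally sized groups; `variant = "pooled"` uses the
#' (n-1)-weighted pooled SD.
#'
#' @param m1,sd1,n1,m2,sd2,n2 Group means, SDs, sizes.
#' @param variant Denominator convention.
#' @return Cohen's d (antisymmetric under group swap).
#' @examples
#' cohens_d(206.02, 59.45, 24, 264.05, 103.13, 24)  # |d| ~ 0.69
#' @export
cohens_d <- function(m1, sd1, n1, m2, sd2, n2,
                     variant = c("average", "pooled")) {
  variant <- match.arg(variant)
  if (any(c(n1, n2) <= 0)) stop("group sizes must be positive", call. = FALSE)
  if (any(c(sd1, sd2) <= 0)) stop("sds must be > 0", call. = FALSE)
  s <- if (variant == "average") sqrt((sd1^2 + sd2^2) / 2) else
    sqrt(((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2))
  (m1 - m2) / s
}

#' Welch-Satterthwaite effective degrees of freedom
#'
#' @param sd1,n1,sd2,n2 Group SDs and sizes.
#' @return Effective df of the unequal-variance two-sample t statistic.
#' @export
welch_satterthwaite_df <- function(sd1, n1, sd2, n2) {
  v1 <- sd1^2 / n1; v2 <- sd2^2 / n2
  (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
}

#' Pearson correlation with Fisher-z confidence interval
#'
#' @param x,y Paired numeric vectors, n >= 4.
#' @param conf_level Confidence level (default 0.95).
#' @return List: `r`, `ci` (Fisher-z), `p`, `n`.
#' @export
pearson_cor <- function(x, y, conf_level = 0.95) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 4) stop("need at least 4 complete pairs", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance in x or y", call. = FALSE)
  ct <- stats::cor.test(x, y, conf.level = conf_level)
  list(r = unname(ct$estimate), ci = as.numeric(ct$conf.int),
       p = ct$p.value, n = length(x))
}

#' Multiple-comparison adjustment of p-values
#'
#' Benjamini-Hochberg step-up adjustment by default; any method of
#' [stats::p.adjust()] is accepted. Adjusted values are monotone in the
#' input order statistics and bounded by 1.
#'
#' @param ps Numeric p-values in [0, 1].
#' @param method Adjustment method (default `"BH"`).
#' @return Adjusted p-values.
#' @export
adjust_pvalues <- function(ps, method = "BH") {
  if (any(!is.finite(ps)) || any(ps < 0) || any(ps > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  stats::p.adjust(ps, method = method)
}
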