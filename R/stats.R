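new_stat_result <- function(statistic, p, effect, ci, n_a, n_b = NA_integer_,
                            method, flag = NULL) {
  structure(list(statistic = statistic, p = p, effect = effect, ci = ci,
                 n_a = n_a, n_b = n_b, method = method, flag = flag),
            class = "stat_result")
}

#' @export
print.stat_result <- function(x, ...) {
  cat(sprintf("<stat_result> %s\n", x$method))
  cat(sprintf("  statistic = %.3f, p = %.4g, effect = %.3f, 95%% CI (%.3f, %.3f), n = %s\n",
              x$statistic, x$p, x$effect, x$ci[1], x$ci[2],
              if (is.na(x$n_b)) x$n_a else paste(x$n_a, x$n_b, sep = "/")))
  if (!is.null(x$flag)) cat("  flag:", x$flag, "\n")
  invisible(x)
}

#' Group comparison of a model parameter from two posteriors
#'
#' Cohen's d is computed from the group means and standard deviations of the
#' pooled subject-level posterior samples of the parameter (all draws of all
#' subjects in each group); the p-value comes from a two-sample t-test on
#' the per-participant posterior means.  The sign convention is
#' positive = group b larger than group a.
#'
#' @param samples_a,samples_b converged `rlddm_fit` objects for the two
#'   groups.
#' @param parameter a free parameter name, e.g. `"nu"`.
#' @param pooled use the pooled-variance (Student) t-test (default); `FALSE`
#'   gives Welch.
#' @param override bypass the convergence gate.
#' @return a `stat_result` (t statistic, p, Cohen's d, CI of the mean
#'   difference).
#' @export
param_group_test <- function(samples_a, samples_b, parameter,
                             pooled = TRUE, override = FALSE) {
  assert_converged(samples_a, override)
  assert_converged(samples_b, override)
  if (!parameter %in% samples_a$free || !parameter %in% samples_b$free)
    stop("parameter is not free in both fits")
  pool <- function(fit) {
    cols <- sprintf("%s[%d]", parameter, seq_along(fit$subject_ids))
    as.vector(posterior_draws(fit, cols, merge_chains = TRUE))
  }
  subj_means <- function(fit) subject_posterior_means(fit)[[parameter]]
  da <- pool(samples_a); db <- pool(samples_b)
  d <- (mean(db) - mean(da)) / sqrt((var(da) + var(db)) / 2)
  ma <- subj_means(samples_a); mb <- subj_means(samples_b)
  flag <- NULL
  if (length(ma) < 2 || length(mb) < 2) {
    tt <- list(statistic = NA_real_, p.value = NA_real_,
               conf.int = c(NA_real_, NA_real_))
    flag <- "single-subject group: p undefined, d still computed"
  } else {
    tt <- t.test(mb, ma, var.equal = pooled)
  }
  new_stat_result(statistic = unname(tt$statistic), p = tt$p.value,
                  effect = d, ci = as.numeric(tt$conf.int),
                  n_a = length(ma), n_b = length(mb),
                  method = sprintf(
                    "%s t-test on per-subject posterior means of %s; d from pooled posterior samples (b - a)",
                    if (pooled) "pooled-variance" else "Welch", parameter),
                  flag = flag)
}

#' Group test on derived signal means
#'
#' One-sample t-test against zero for detrended value means (pass only
#' `values_a`), or a two-sample t-test for comparing signal means between
#' groups; Cohen's d is reported alongside.
#'
#' @param values_a numeric vector (one value per subject).
#' @param values_b optional second group; when `NULL` a one-sample test
#'   against `mu` is performed.
#' @param mu null value for the one-sample test.
#' @param pooled pooled-variance (Student) vs Welch two-sample test.
#' @return a `stat_result`.
#' @export
signal_group_test <- function(values_a, values_b = NULL, mu = 0,
                              pooled = TRUE) {
  values_a <- values_a[!is.na(values_a)]
  if (is.null(values_b)) {
    if (length(values_a) < 2) stop("need at least 2 values")
    if (sd(values_a) < .Machine$double.eps)
      return(new_stat_result(NA_real_, NA_real_,
                             effect = NA_real_, ci = c(NA_real_, NA_real_),
                             n_a = length(values_a),
                             method = "one-sample t-test vs 0",
                             flag = "zero variance: t undefined"))
    tt <- t.test(values_a, mu = mu)
    d <- (mean(values_a) - mu) / sd(values_a)
    return(new_stat_result(unname(tt$statistic), tt$p.value, d,
                           as.numeric(tt$conf.int), length(values_a),
                           method = sprintf("one-sample t-test vs %g", mu)))
  }
  values_b <- values_b[!is.na(values_b)]
  if (length(values_a) < 2 || length(values_b) < 2)
    stop("need at least 2 values per group")
  na <- length(values_a); nb <- length(values_b)
  sp <- sqrt(((na - 1) * var(values_a) + (nb - 1) * var(values_b)) /
               (na + nb - 2))
  if (sp < .Machine$double.eps)
    return(new_stat_result(0, 1, 0, c(0, 0), na, nb,
                           method = "two-sample t-test",
                           flag = "zero variance"))
  tt <- t.test(values_b, values_a, var.equal = pooled)
  d <- (mean(values_b) - mean(values_a)) / sp
  new_stat_result(unname(tt$statistic), tt$p.value, d,
                  as.numeric(tt$conf.int), na, nb,
                  method = sprintf("%s two-sample t-test (b - a)",
                                   if (pooled) "pooled-variance" else
                                     "Welch"))
}

#' Severity correlation
#'
#' Pearson correlation between a per-subject quantity (e.g. posterior-mean
#' non-decision time) and a severity rating (e.g. HAM-D), with the
#' Fisher-z 95% confidence interval and two-sided p-value.
#'
#' @param values numeric vector.
#' @param ratings numeric vector of the same length.
#' @return a `stat_result` with `effect` = r.
#' @export
severity_correlation <- function(values, ratings) {
  ok <- complete.cases(values, ratings)
  values <- values[ok]; ratings <- ratings[ok]
  if (length(values) < 3) stop("need at least 3 paired observations")
  if (sd(ratings) < .Machine$double.eps ||
      sd(values) < .Machine$double.eps)
    return(new_stat_result(NA_real_, NA_real_, NA_real_,
                           c(NA_real_, NA_real_), length(values),
                           method = "Pearson correlation",
                           flag = "constant input: r undefined"))
  ct <- cor.test(values, ratings, method = "pearson")
  new_stat_result(unname(ct$statistic), ct$p.value,
                  unname(ct$estimate), as.numeric(ct$conf.int),
                  length(values),
                  method = "Pearson correlation (Fisher-z CI)")
}

#' Multiple-testing adjustment of a results table
#'
#' The primary reporting follows the overall-pattern convention with no
#' correction; a Benjamini-Hochberg adjustment is available behind this
#' helper for sensitivity analyses.
#'
#' @param results data frame with a `p` column.
#' @param method see [stats::p.adjust()].
#' @return the data frame with an added `p_adj` column.
#' @export
adjust_pvalues <- function(results, method = "BH") {
  results$p_adj <- stats::p.adjust(results$p, method = method)
  results
}
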