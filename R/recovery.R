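#' Parameter recovery study
#'
#' Simulates a synthetic cohort from known subject-level parameters drawn
#' from `true_spec`, fits the model hierarchically, and regresses the
#' recovered posterior means on the generating values for every free
#' parameter - the standard check that the experimental design carries
#' enough information to estimate the model.
#'
#' @param variant model variant (default the winning boundary-power model).
#' @param n_subjects number of synthetic subjects.
#' @param schedule a [build_schedule()] object.
#' @param true_spec a [group_spec()] giving the generating distribution.
#' @param seeds list with elements `sim` and `fit`.
#' @param config a [sampler_config()] for the fit (reduced settings are
#'   typical here).
#' @param dt Euler step for the simulations.
#' @return a `recovery_report`: `stats` (per parameter: Pearson correlation,
#'   regression slope/intercept with 95% CI of the slope), `values` (true
#'   and recovered per subject), `converged` flag of the underlying fit.
#'   Degenerate (zero-spread) parameters are flagged with `NA` statistics.
#' @export
parameter_recovery <- function(variant = winning_variant(), n_subjects,
                               schedule, true_spec = NULL,
                               seeds = list(sim = 1, fit = 2),
                               config = sampler_config(), dt = 1e-3) {
  variant <- match_variant(variant)
  if (is.null(true_spec)) true_spec <- recovery_spec(variant)
  cohort <- simulate_cohort(list(synthetic = true_spec), n_subjects,
                            schedule, seeds$sim, dt = dt)
  config$seed <- seeds$fit
  fit <- withCallingHandlers(
    fit_hierarchical(cohort, variant, config),
    warning = function(w) {
      if (grepl("non-converged", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  pm <- subject_posterior_means(fit)
  truth <- cohort$true_params[match(pm$subject_id,
                                    cohort$true_params$subject_id), ]
  free <- fit$free
  stats <- do.call(rbind, lapply(free, function(nm) {
    x <- truth[[nm]]; y <- pm[[nm]]
    if (sd(x) < 1e-12)
      return(data.frame(parameter = nm, r = NA_real_, slope = NA_real_,
                        intercept = NA_real_, slope_lo = NA_real_,
                        slope_hi = NA_real_, degenerate = TRUE))
    fit_lm <- lm(y ~ x)
    ci <- confint(fit_lm)["x", ]
    data.frame(parameter = nm, r = cor(x, y),
               slope = coef(fit_lm)[["x"]],
               intercept = coef(fit_lm)[["(Intercept)"]],
               slope_lo = ci[1], slope_hi = ci[2], degenerate = FALSE)
  }))
  values <- do.call(rbind, lapply(free, function(nm)
    data.frame(subject_id = pm$subject_id, parameter = nm,
               true = truth[[nm]], recovered = pm[[nm]])))
  structure(list(stats = stats, values = values, variant = variant,
                 converged = fit$converged, fit = fit),
            class = "recovery_report")
}

# a generating distribution with generous spreads, so recovery regressions
# span a usable range of each parameter
recovery_spec <- function(variant = winning_variant()) {
  info <- variant_info(variant)
  means <- list(alpha = 0.25, nu = 3.0, a = 1.4, bb = 1.2, bp = -0.15,
                p = -0.1, t_nd = 0.38)
  sds <- list(alpha = 0.6, nu = 0.35, a = 0.25, bb = 0.25, bp = 0.25,
              p = 0.2, t_nd = 0.3)
  group_spec(mean = means[info$free], sd = sds[info$free],
             variant = variant)
}

#' @export
print.recovery_report <- function(x, ...) {
  cat(sprintf("<recovery_report> %s, %d subjects (fit %sconverged)\n",
              x$variant, length(unique(x$values$subject_id)),
              if (isTRUE(x$converged)) "" else "NOT "))
  print(x$stats, row.names = FALSE, digits = 3)
  invisible(x)
}
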