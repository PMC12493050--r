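#' End-to-end pipeline stages
#'
#' Three orchestration functions cover a full synthetic study; each stage
#' writes plain-text tables so any stage can be rerun in isolation.
#' `run_synth()` builds the schedule and cohort and writes the session table
#' plus a manifest of seeds; `run_fit_compare()` fits the requested model
#' variants, enforces the convergence gate and performs the k-fold ELPD
#' comparison; `run_analysis()` derives value/prediction-error traces,
#' detrends against the control group, computes section means, group
#' statistics, severity correlations and posterior predictive summaries,
#' and exports the parametric-modulator event files.
#'
#' @param config a [run_config()].
#' @param out_dir output directory (created if needed).
#' @return `run_synth()`: the cohort (invisibly; files on disk);
#'   `run_fit_compare()`: list with `fits` and `comparison`;
#'   `run_analysis()`: list with `stats`, `sections`, `ppc`, `events_dir`.
#' @name pipeline
NULL

#' @rdname pipeline
#' @export
run_synth <- function(config, out_dir) {
  stopifnot(inherits(config, "run_config"))
  if (any(config$n_per_group < 1))
    stop("n_per_group must be at least 1 for every group")
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  schedule <- build_schedule(config$seed, config$n_per_type)
  cohort <- simulate_cohort(config$specs, config$n_per_group, schedule,
                            rng_seed = config$seed + 1, dt = config$dt)
  write.table(as.data.frame(schedule), file.path(out_dir, "schedule.tsv"),
              sep = "\t", row.names = FALSE, quote = FALSE)
  write_sessions(cohort, file.path(out_dir, "sessions.tsv"))
  write.table(cohort$true_params, file.path(out_dir, "true_params.tsv"),
              sep = "\t", row.names = FALSE, quote = FALSE)
  yaml::write_yaml(list(seed = config$seed, cohort_seed = config$seed + 1,
                        n_per_type = config$n_per_type,
                        n_per_group = as.list(setNames(config$n_per_group,
                                                       config$groups))),
                   file.path(out_dir, "manifest.yaml"))
  invisible(cohort)
}

#' @rdname pipeline
#' @param cohort an `rlddm_cohort` (e.g. from [run_synth()] or
#'   [read_sessions()]).
#' @param override proceed despite failed convergence diagnostics.
#' @export
run_fit_compare <- function(config, cohort, out_dir, override = FALSE) {
  stopifnot(inherits(config, "run_config"))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  fits <- list(); elpds <- list()
  for (v in config$variants) {
    cfg <- config$sampler
    cfg$seed <- config$seed + 10 + match(v, rlddm_variants())
    fits[[v]] <- fit_hierarchical(cohort, v, cfg)
    write_draws(fits[[v]], file.path(out_dir, paste0("draws_", v, ".tsv")))
    write.table(fits[[v]]$diagnostics,
                file.path(out_dir, paste0("diagnostics_", v, ".tsv")),
                sep = "\t", row.names = FALSE, quote = FALSE)
    if (!isTRUE(fits[[v]]$converged) && !override)
      stop(sprintf("variant %s failed convergence diagnostics; rerun with more iterations or override",
                   v))
    elpds[[v]] <- kfold_elpd(cohort, v, k = config$k,
                             seeds = list(fold = config$seed,
                                          fit = config$seed + 20),
                             config = config$sampler)
  }
  comparison <- if (length(elpds) > 1) compare_models(elpds) else
    data.frame(variant = names(elpds),
               elpd = elpds[[1]]$elpd, se = elpds[[1]]$se,
               elpd_diff = 0, diff_se = 0, winner = TRUE)
  write.table(as.data.frame(comparison)[
    c("variant", "elpd", "se", "elpd_diff", "diff_se", "winner")],
    file.path(out_dir, "model_comparison.tsv"),
    sep = "\t", row.names = FALSE, quote = FALSE)
  list(fits = fits, comparison = comparison)
}

#' @rdname pipeline
#' @param fit converged `rlddm_fit` of the winning variant.
#' @param detrend subtract the control-group per-trial value means (needs a
#'   `control` group in the cohort).
#' @export
run_analysis <- function(config, fit, cohort, out_dir, detrend = TRUE,
                         override = FALSE) {
  stopifnot(inherits(config, "run_config"))
  assert_converged(fit, override)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  groups <- cohort$subjects$group
  is_ctrl <- groups == "control"
  if (detrend && !any(is_ctrl))
    stop("detrending requested but the cohort has no control group")
  traces <- lapply(seq_along(cohort$sessions), function(s)
    compute_traces(subject_point_params(fit, s), cohort$sessions[[s]],
                   cohort$schedule))
  if (detrend) traces <- detrend_values(traces, traces[is_ctrl])
  sections <- do.call(rbind, lapply(traces, section_means))
  write.table(sections, file.path(out_dir, "section_means.tsv"),
              sep = "\t", row.names = FALSE, quote = FALSE)

  pm <- subject_posterior_means(fit)
  stats_rows <- list()
  pat <- !is_ctrl
  if (any(pat)) {
    # detrended value means: one-sample tests vs 0 per measure (patients)
    full <- sections[sections$section == "full" &
                       sections$subject_id %in%
                       cohort$subjects$subject_id[pat], ]
    for (m in unique(full$measure)) {
      v <- full$mean[full$measure == m]
      if (sum(!is.na(v)) >= 2 && sd(v, na.rm = TRUE) > 0) {
        r <- signal_group_test(v)
        stats_rows[[length(stats_rows) + 1]] <- data.frame(
          contrast = paste0("patients_", m, "_vs0"),
          statistic = r$statistic, p = r$p, effect_size = r$effect,
          ci_low = r$ci[1], ci_high = r$ci[2], n_a = r$n_a, n_b = NA)
      }
    }
  }
  # severity correlations over the combined depression group
  if (sum(pat) >= 3) {
    for (par in intersect(c("nu", "t_nd"), fit$free)) {
      r <- severity_correlation(pm[[par]][pat],
                                cohort$subjects$hamd[pat])
      stats_rows[[length(stats_rows) + 1]] <- data.frame(
        contrast = paste0("hamd_vs_", par), statistic = r$statistic,
        p = r$p, effect_size = r$effect, ci_low = r$ci[1],
        ci_high = r$ci[2], n_a = r$n_a, n_b = NA)
    }
  }
  stats_tab <- if (length(stats_rows)) do.call(rbind, stats_rows) else
    data.frame()
  write.table(stats_tab, file.path(out_dir, "group_stats.tsv"),
              sep = "\t", row.names = FALSE, quote = FALSE)

  ppc <- posterior_predictive(fit, cohort, n_draws = 50,
                              seed = config$seed + 30, dt = config$dt,
                              override = override)
  write.table(ppc$summary, file.path(out_dir, "ppc_summary.tsv"),
              sep = "\t", row.names = FALSE, quote = FALSE)

  events_dir <- file.path(out_dir, "events")
  for (s in seq_along(cohort$sessions))
    export_modulators(cohort$sessions[[s]], traces[[s]], cohort$schedule,
                      dir = events_dir)
  list(stats = stats_tab, sections = sections, ppc = ppc,
       events_dir = events_dir)
}
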