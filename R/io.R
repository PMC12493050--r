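#' Read and write behavioural session tables
#'
#' Cohorts are persisted as a single tab-separated table with one row per
#' trial and columns `subject_id`, `group`, `trial_index`, `trial_type`,
#' `within_type_index`, `choice`, `rt_s`, `reinforcement`, `hamd`, `hama`.
#' Missing reaction times (omitted trials) are written as empty fields.
#'
#' @param cohort an `rlddm_cohort`.
#' @param path file path.
#' @return `write_sessions()` returns `path` invisibly; `read_sessions()`
#'   returns an `rlddm_cohort` (with `schedule` attached if supplied).
#' @export
write_sessions <- function(cohort, path) {
  rows <- lapply(seq_along(cohort$sessions), function(i) {
    s <- cohort$sessions[[i]]
    meta <- cohort$subjects[cohort$subjects$subject_id == s$subject_id[1], ]
    data.frame(subject_id = s$subject_id, group = meta$group,
               trial_index = s$trial, trial_type = s$trial_type,
               within_type_index = s$within_type_index,
               choice = s$choice, rt_s = s$rt,
               reinforcement = s$reinforcement,
               hamd = meta$hamd, hama = meta$hama)
  })
  tab <- do.call(rbind, rows)
  write.table(tab, path, sep = "\t", row.names = FALSE, quote = FALSE,
              na = "")
  invisible(path)
}

#' @rdname write_sessions
#' @param schedule optional [build_schedule()] to attach to the cohort.
#' @export
read_sessions <- function(path, schedule = NULL) {
  tab <- read.delim(path, na.strings = "", stringsAsFactors = FALSE)
  need <- c("subject_id", "group", "trial_index", "trial_type",
            "within_type_index", "choice", "rt_s", "reinforcement",
            "hamd", "hama")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  sids <- unique(tab$subject_id)
  sessions <- lapply(sids, function(id) {
    s <- tab[tab$subject_id == id, ]
    s <- s[order(s$trial_index), ]
    out <- data.frame(
      subject_id = s$subject_id, trial = s$trial_index,
      trial_type = factor(s$trial_type,
                          levels = c("reward", "neutral", "loss")),
      within_type_index = s$within_type_index,
      choice = factor(s$choice, levels = c("better", "worse", "omitted")),
      rt = s$rt_s, reinforcement = s$reinforcement)
    class(out) <- c("behavioural_session", "data.frame")
    out
  })
  subjects <- unique(tab[, c("subject_id", "group", "hamd", "hama")])
  rownames(subjects) <- NULL
  out <- list(sessions = sessions, subjects = subjects,
              true_params = NULL, schedule = schedule)
  class(out) <- "rlddm_cohort"
  out
}

#' Persist posterior draws as a tidy table
#'
#' @param fit an `rlddm_fit`.
#' @param path file path; tab-separated columns `chain`, `iteration`,
#'   `parameter`, `value`.
#' @return `path`, invisibly.
#' @export
write_draws <- function(fit, path) {
  d <- fit$draws
  dn <- dimnames(d)[[3]]
  tab <- data.frame(
    chain = rep(seq_len(dim(d)[2]), each = dim(d)[1], times = dim(d)[3]),
    iteration = rep(seq_len(dim(d)[1]), times = dim(d)[2] * dim(d)[3]),
    parameter = rep(dn, each = dim(d)[1] * dim(d)[2]),
    value = as.vector(d))
  write.table(tab, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_draws
#' @export
read_draws <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  pars <- unique(tab$parameter)
  chains <- sort(unique(tab$chain))
  iters <- max(tab$iteration)
  a <- array(NA_real_, c(iters, length(chains), length(pars)),
             dimnames = list(iteration = NULL, chain = NULL,
                             parameter = pars))
  for (p in pars) {
    sub <- tab[tab$parameter == p, ]
    a[cbind(sub$iteration, match(sub$chain, chains), match(p, pars))] <-
      sub$value
  }
  a
}

#' Run configuration
#'
#' A serializable description of a full synthetic study: seeds, schedule
#' settings, per-group generative parameters, model variants, sampler
#' settings, cross-validation folds and section definitions.  A persisted
#' configuration reproduces a run exactly.
#'
#' @param seed master seed.
#' @param n_per_type trials per trial type.
#' @param n_per_group subjects per group (vector aligned with `groups`).
#' @param groups group labels; must name entries of
#'   [default_group_specs()] or `specs`.
#' @param specs optional named list of [group_spec()]s (default
#'   [default_group_specs()]).
#' @param variants variants to fit and compare.
#' @param sampler a [sampler_config()].
#' @param k cross-validation folds.
#' @param dt Euler step for simulations.
#' @return a `run_config` list.
#' @export
run_config <- function(seed = 1, n_per_type = 60,
                       n_per_group = c(21, 20, 17),
                       groups = c("control", "unipolar", "bipolar"),
                       specs = NULL, variants = rlddm_variants(),
                       sampler = sampler_config(), k = 5, dt = 1e-3) {
  if (is.null(specs)) specs <- default_group_specs()[groups]
  structure(list(seed = seed, n_per_type = n_per_type,
                 n_per_group = n_per_group, groups = groups, specs = specs,
                 variants = variants, sampler = sampler, k = k, dt = dt),
            class = "run_config")
}

#' @rdname run_config
#' @param config a `run_config`.
#' @param path YAML file path.
#' @export
write_run_config <- function(config, path) {
  plain <- rapply(unclass(config), unclass, how = "replace")
  yaml::write_yaml(plain, path)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  raw <- yaml::yaml.load_file(path)
  specs <- lapply(raw$specs, function(s)
    group_spec(mean = s$mean, sd = s$sd, severity = s$severity,
               variant = s$variant))
  run_config(seed = raw$seed, n_per_type = raw$n_per_type,
             n_per_group = unlist(raw$n_per_group), groups = raw$groups,
             specs = specs, variants = unlist(raw$variants),
             sampler = do.call(sampler_config, raw$sampler[
               c("chains", "warmup", "iter", "thin", "init_step", "seed")]),
             k = raw$k, dt = raw$dt)
}
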