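#' Sampler configuration
#'
#' Defaults mirror the study design: four chains, 1000 discarded warm-up
#' iterations and 3000 sampling iterations each.  `thin` keeps every
#' `thin`-th post-warm-up draw (the recorded iteration count is
#' `iter / thin`); increasing `iter` with proportional thinning is the
#' supported way to raise effective sample sizes at fixed memory.
#'
#' @param chains number of chains (>= 2 for diagnostics).
#' @param warmup warm-up (adaptation) iterations per chain, discarded.
#' @param iter post-warm-up iterations per chain.
#' @param thin keep every `thin`-th draw.
#' @param init_step initial random-walk step on the transformed scale.
#' @param seed integer seed; fits are bit-reproducible given it.
#' @return a list of class `sampler_config`.
#' @export
sampler_config <- function(chains = 4, warmup = 1000, iter = 3000, thin = 1,
                           init_step = 0.15, seed = 1) {
  stopifnot(chains >= 1, warmup >= 0, iter >= thin, thin >= 1)
  structure(list(chains = as.integer(chains), warmup = as.integer(warmup),
                 iter = as.integer(iter), thin = as.integer(thin),
                 init_step = init_step, seed = seed),
            class = "sampler_config")
}

# weakly-informative priors on the transformed scales: Normal(m0, s0) on the
# group means, half-Normal(tau) on the group spreads
default_priors <- function(free) {
  tab <- list(
    alpha = c(m0 = -1.0, s0 = 1.5, tau = 0.6),
    nu    = c(m0 = 0.8,  s0 = 1.0, tau = 0.5),
    a     = c(m0 = 0.3,  s0 = 0.8, tau = 0.5),
    bb    = c(m0 = 0.3,  s0 = 0.8, tau = 0.5),
    bp    = c(m0 = 0.0,  s0 = 0.5, tau = 0.3),
    p     = c(m0 = 0.0,  s0 = 0.5, tau = 0.3),
    t_nd  = c(m0 = -1.1, s0 = 0.8, tau = 0.5)
  )
  do.call(rbind, lapply(free, function(nm) tab[[nm]]))
}

#' Fit an RLDDM variant hierarchically to a cohort
#'
#' Two-level hierarchical Bayesian estimation: subject-level parameters on
#' transformed scales (logit for `alpha`, log for the positive parameters,
#' identity for the powers) are modelled as Normal around group-level means
#' with group-level spreads; group means carry weakly-informative Normal
#' priors and spreads half-Normal priors.  Sampling uses an adaptive
#' Metropolis-within-Gibbs scheme (conjugate Gibbs updates for the group
#' means, Metropolis on the log spreads, per-coordinate adaptive random-walk
#' Metropolis for the subject parameters; adaptation during warm-up only).
#' Convergence is summarized by rank-normalized split R-hat and tail
#' effective sample size over all recorded parameters; a fit violating the
#' acceptance rule (max split R-hat < 1.01 and min tail-ESS > 400) is
#' returned flagged `converged = FALSE` with a warning, never silently.
#'
#' Subjects with zero non-omitted trials are excluded with a warning.
#'
#' @param cohort an `rlddm_cohort` (or list with `sessions` and `schedule`).
#' @param variant one of [rlddm_variants()].
#' @param config a [sampler_config()].
#' @param include_nu see [variant_info()].
#' @param use list of per-subject likelihood masks (internal, used by
#'   [kfold_elpd()]); masked trials still drive the value updates.
#' @return an `rlddm_fit` with elements `draws` (array iterations x chains x
#'   parameters; group means/spreads on the transformed scale, subject
#'   parameters on the natural scale), `diagnostics` (per-parameter split
#'   R-hat and tail-ESS), `converged`, `variant`, `free`, `subject_ids`,
#'   `config`.
#' @examples
#' \donttest{
#' sched <- build_schedule(1, n_per_type = 20)
#' co <- simulate_cohort(default_group_specs()["control"], 3, sched, 1)
#' fit <- fit_hierarchical(co, "RLDDM_bspow",
#'                         sampler_config(chains = 2, warmup = 100,
#'                                        iter = 200))
#' }
#' @export
fit_hierarchical <- function(cohort, variant = winning_variant(),
                             config = sampler_config(), include_nu = FALSE,
                             use = NULL) {
  variant <- match_variant(variant)
  info <- variant_info(variant, include_nu)
  schedule <- cohort$schedule
  sessions <- cohort$sessions
  keep <- vapply(sessions, function(s) any(s$choice != "omitted"), TRUE)
  if (!all(keep)) {
    warning(sprintf("excluding %d subject(s) with no non-omitted trials",
                    sum(!keep)))
    sessions <- sessions[keep]
    if (!is.null(use)) use <- use[keep]
  }
  if (!length(sessions)) stop("no usable subjects")
  subs <- lapply(seq_along(sessions), function(i)
    session_to_cpp(sessions[[i]], schedule,
                   use = if (is.null(use)) NULL else use[[i]]))
  free <- info$free
  pr <- default_priors(free)
  raw <- cpp_fit_mcmc(subs,
                      slot = unname(CANON_SLOTS[free]) - 1L,
                      trans = unname(CANON_TRANS[free]),
                      m0 = pr[, "m0"], s0 = pr[, "s0"], tau = pr[, "tau"],
                      drpow = info$drpow, bspow = info$bspow,
                      chains = config$chains, warmup = config$warmup,
                      iter = config$iter, thin = config$thin,
                      init_step = config$init_step,
                      seed = as.numeric(config$seed))
  sids <- vapply(sessions, function(s) as.character(s$subject_id[1]), "")
  pnames <- c(paste0("mu_", free), paste0("sigma_", free),
              as.vector(t(outer(seq_along(sids), free,
                                function(s, f) sprintf("%s[%d]", f, s)))))
  kept <- nrow(raw[[1]])
  draws <- array(NA_real_, dim = c(kept, length(raw), length(pnames)),
                 dimnames = list(iteration = NULL, chain = NULL,
                                 parameter = pnames))
  for (c in seq_along(raw)) draws[, c, ] <- raw[[c]]
  fit <- structure(list(draws = draws, variant = variant,
                        include_nu = include_nu, free = free,
                        subject_ids = sids, config = config,
                        diagnostics = NULL, converged = NA),
                   class = "rlddm_fit")
  fit$diagnostics <- fit_diagnostics(fit)
  fit$converged <- all(fit$diagnostics$split_rhat < 1.01, na.rm = TRUE) &&
    all(fit$diagnostics$tail_ess > 400, na.rm = TRUE)
  if (!isTRUE(fit$converged))
    warning(sprintf(
      "fit flagged non-converged: max split R-hat %.3f, min tail-ESS %.0f",
      max(fit$diagnostics$split_rhat, na.rm = TRUE),
      min(fit$diagnostics$tail_ess, na.rm = TRUE)))
  fit
}

#' @export
print.rlddm_fit <- function(x, ...) {
  d <- dim(x$draws)
  cat(sprintf("<rlddm_fit> %s: %d subjects, %d chains x %d draws\n",
              x$variant, length(x$subject_ids), d[2], d[1]))
  cat(sprintf("  max split R-hat %.4f, min tail-ESS %.0f -> %s\n",
              max(x$diagnostics$split_rhat, na.rm = TRUE),
              min(x$diagnostics$tail_ess, na.rm = TRUE),
              if (isTRUE(x$converged)) "converged" else "NOT converged"))
  invisible(x)
}

#' Extract posterior draws
#'
#' @param fit an `rlddm_fit`.
#' @param parameter parameter name(s); default all.
#' @param merge_chains flatten chains into one vector/matrix.
#' @return a matrix (iterations x chains) for a single parameter, the full
#'   array otherwise; with `merge_chains = TRUE` a vector or draws x
#'   parameters matrix.
#' @export
posterior_draws <- function(fit, parameter = NULL, merge_chains = FALSE) {
  stopifnot(inherits(fit, "rlddm_fit"))
  a <- fit$draws
  if (!is.null(parameter)) {
    miss <- setdiff(parameter, dimnames(a)[[3]])
    if (length(miss)) stop("unknown parameter(s): ",
                           paste(miss, collapse = ", "))
    a <- a[, , parameter, drop = FALSE]
    if (length(parameter) == 1)
      a <- matrix(a, dim(fit$draws)[1], dim(fit$draws)[2])
  }
  if (!merge_chains) return(a)
  if (is.matrix(a)) as.vector(a) else apply(a, 3, as.vector)
}

# draws x 6 canonical natural-scale parameter matrix for one subject
subject_canon_draws <- function(fit, subject_index) {
  free <- fit$free
  cols <- sprintf("%s[%d]", free, subject_index)
  m <- posterior_draws(fit, cols, merge_chains = TRUE)
  m <- matrix(m, ncol = length(cols),
              dimnames = list(NULL, free))
  canon <- matrix(rep(c(NA, 1, NA, 0, 0, NA), each = nrow(m)),
                  nrow = nrow(m))
  for (nm in free) canon[, CANON_SLOTS[[nm]]] <- m[, nm]
  canon
}

#' Posterior-mean subject parameters
#'
#' @param fit an `rlddm_fit`.
#' @return data frame with one row per subject: posterior means of each free
#'   parameter on the natural scale.
#' @export
subject_posterior_means <- function(fit) {
  stopifnot(inherits(fit, "rlddm_fit"))
  S <- length(fit$subject_ids)
  out <- lapply(seq_len(S), function(s) {
    cols <- sprintf("%s[%d]", fit$free, s)
    v <- vapply(cols, function(p)
      mean(posterior_draws(fit, p, merge_chains = TRUE)), 0)
    names(v) <- fit$free
    as.data.frame(as.list(v))
  })
  cbind(data.frame(subject_id = fit$subject_ids), do.call(rbind, out))
}

# subject_params object from posterior means for one subject
subject_point_params <- function(fit, subject_index) {
  pm <- subject_posterior_means(fit)
  vals <- as.list(pm[subject_index, fit$free])
  do.call(subject_params, c(list(variant = fit$variant,
                                 include_nu = fit$include_nu), vals))
}
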