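#' K-fold cross-validated expected log predictive density
#'
#' Trials are partitioned into `k` folds within each subject, stratified by
#' trial type (so every fold's training set sees all subjects and a balanced
#' mix of conditions).  For each fold the model is refitted on the retained
#' trials - held-out trials are excluded from the likelihood but their
#' outcomes still drive the observed value-learning path - and each held-out
#' trial's log predictive density is the log of the posterior-mean trial
#' likelihood.  The ELPD is the sum of the pointwise values over all trials.
#'
#' @param cohort an `rlddm_cohort`.
#' @param variant model variant.
#' @param k number of folds (>= 2).
#' @param seeds list with `fold` (fold assignment) and `fit` (per-fold
#'   sampler seeds derive from it).
#' @param config [sampler_config()] used for every fold (reduced settings
#'   are typical); per-fold diagnostics are recorded.
#' @param include_nu see [variant_info()].
#' @return list with `elpd`, `se` (sqrt(n) times the sd of the pointwise
#'   values), `pointwise` (data frame `subject_id`, `trial`, `lpd`), `k`,
#'   `folds` (assignment matrix), `fold_converged` (per-fold diagnostic
#'   flag).
#' @export
kfold_elpd <- function(cohort, variant, k = 5,
                       seeds = list(fold = 1, fit = 2),
                       config = sampler_config(), include_nu = FALSE) {
  variant <- match_variant(variant)
  if (k < 2) stop("k must be at least 2")
  schedule <- cohort$schedule
  n_trial <- nrow(schedule)
  S <- length(cohort$sessions)
  folds <- local_seed(seeds$fold, {
    vapply(seq_len(S), function(s) {
      f <- integer(n_trial)
      for (ty in levels(schedule$trial_type)) {
        id <- which(schedule$trial_type == ty)
        f[id] <- sample(rep_len(seq_len(k), length(id)))
      }
      f
    }, integer(n_trial))
  })
  if (any(tabulate(folds, k) == 0)) stop("a fold has zero held-out trials")
  info <- variant_info(variant, include_nu)
  lpd <- matrix(NA_real_, n_trial, S)
  fold_conv <- logical(k)
  for (f in seq_len(k)) {
    use <- lapply(seq_len(S), function(s) as.integer(folds[, s] != f))
    cfg <- config
    cfg$seed <- as.numeric(seeds$fit) * 101 + f
    fit <- withCallingHandlers(
      fit_hierarchical(cohort, variant, cfg, include_nu = include_nu,
                       use = use),
      warning = function(w) {
        if (grepl("non-converged", conditionMessage(w)))
          invokeRestart("muffleWarning")
      })
    fold_conv[f] <- isTRUE(fit$converged)
    for (s in seq_len(S)) {
      held <- which(folds[, s] == f)
      sub <- session_to_cpp(cohort$sessions[[s]], schedule)
      ll <- cpp_pointwise_loglik(sub, subject_canon_draws(fit, s),
                                 info$drpow, info$bspow)
      lpd[held, s] <- apply(ll[, held, drop = FALSE], 2, log_mean_exp)
    }
  }
  pw <- data.frame(
    subject_id = rep(vapply(cohort$sessions,
                            function(x) as.character(x$subject_id[1]), ""),
                     each = n_trial),
    trial = rep(seq_len(n_trial), S),
    lpd = as.vector(lpd))
  # omitted trials carry NA and contribute nothing
  list(elpd = sum(pw$lpd, na.rm = TRUE),
       se = sqrt(sum(!is.na(pw$lpd))) * sd(pw$lpd, na.rm = TRUE),
       pointwise = pw, k = k, folds = folds, fold_converged = fold_conv)
}

log_mean_exp <- function(x) {
  x <- x[!is.na(x)]
  if (!length(x)) return(NA_real_)
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(mean(exp(x - m)))
}

#' Compare model variants by ELPD
#'
#' Pairwise ELPD differences are computed per held-out trial and summed;
#' the standard error of a difference is `sqrt(n) * sd` of the pointwise
#' differences.  All variants must have been evaluated on identical held-out
#' trial sets (use the same fold seed).
#'
#' @param pointwise_by_variant named list: per variant either the result of
#'   [kfold_elpd()] or its `pointwise` data frame.
#' @return a `model_comparison` data frame (one row per variant: `elpd`,
#'   `se`, `elpd_diff` and `diff_se` versus the best variant, winner first)
#'   with the full pairwise difference matrices as attributes.
#' @export
compare_models <- function(pointwise_by_variant) {
  pw <- lapply(pointwise_by_variant, function(x)
    if (is.data.frame(x)) x else x$pointwise)
  n <- unique(vapply(pw, nrow, 0L))
  if (length(n) != 1)
    stop("pointwise vectors have mismatched lengths across variants")
  key <- lapply(pw, function(d) paste(d$subject_id, d$trial))
  if (!all(vapply(key, identical, TRUE, y = key[[1]])))
    stop("held-out trial sets differ across variants")
  vals <- vapply(pw, function(d) d$lpd, numeric(n))
  elpd <- colSums(vals, na.rm = TRUE)
  se <- apply(vals, 2, function(v)
    sqrt(sum(!is.na(v))) * sd(v, na.rm = TRUE))
  nv <- length(elpd)
  dmat <- matrix(0, nv, nv, dimnames = list(names(elpd), names(elpd)))
  dse <- dmat
  for (i in seq_len(nv)) for (j in seq_len(nv)) {
    dv <- vals[, i] - vals[, j]
    dmat[i, j] <- sum(dv, na.rm = TRUE)
    dse[i, j] <- if (i == j) 0 else
      sqrt(sum(!is.na(dv))) * sd(dv, na.rm = TRUE)
  }
  best <- names(elpd)[which.max(elpd)]
  out <- data.frame(variant = names(elpd), elpd = elpd, se = se,
                    elpd_diff = dmat[, best], diff_se = dse[, best],
                    winner = names(elpd) == best, row.names = NULL)
  out <- out[order(-out$elpd), ]
  attr(out, "diff_matrix") <- dmat
  attr(out, "diff_se_matrix") <- dse
  class(out) <- c("model_comparison", "data.frame")
  out
}

#' @export
print.model_comparison <- function(x, ...) {
  cat("<model_comparison> k-fold ELPD (higher is better)\n")
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}
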