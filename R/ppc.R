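#' Posterior predictive check of choices and reaction times
#'
#' For each of `n_draws` posterior draws, every subject's session is
#' re-simulated from that draw's parameters on the shared schedule.  Within
#' each trial type, trials are grouped into blocks of `block_size` (default
#' 18; with 60 trials per type the last block is partial), and two block
#' summaries computed: the probability of choosing the best option and the
#' mean reaction time (both over non-omitted trials).  The observed block
#' means with standard errors are compared with the 95% highest density
#' interval (narrowest interval) of the simulated block means.
#'
#' @param fit a converged `rlddm_fit`.
#' @param cohort the fitted cohort (sessions + schedule).
#' @param n_draws posterior draws to simulate (<= available draws).
#' @param block_size trials per block within each trial type.
#' @param dt Euler step for the simulations.
#' @param seed integer seed for draw selection and simulation.
#' @param prob HDI mass (default 0.95).
#' @param override bypass the convergence gate.
#' @return an `rlddm_ppc`: data frame `summary` with columns `trial_type`,
#'   `block`, `stat` (`p_best`/`mean_rt`), `observed`, `se`, `hdi_lo`,
#'   `hdi_hi`, `inside`; plus `coverage`, the fraction of observed block
#'   means inside the HDI envelope.
#' @export
posterior_predictive <- function(fit, cohort, n_draws = 100,
                                 block_size = 18, dt = 1e-3, seed = 1,
                                 prob = 0.95, override = FALSE) {
  assert_converged(fit, override)
  schedule <- cohort$schedule
  kept <- dim(fit$draws)[1] * dim(fit$draws)[2]
  if (n_draws > kept) stop("n_draws exceeds the available posterior draws")
  S <- length(fit$subject_ids)
  canon_by_subj <- lapply(seq_len(S), function(s)
    subject_canon_draws(fit, s))
  info <- variant_info(fit$variant, fit$include_nu)
  ints <- schedule_to_int(schedule)
  gp <- ifelse(is.na(schedule$good_option_prob), 0.5,
               schedule$good_option_prob)
  blocks <- block_index(schedule, block_size)

  obs <- do.call(rbind, lapply(cohort$sessions, function(sess)
    block_stats(sess, blocks)))
  obs_mean <- aggregate(cbind(p_best, mean_rt) ~ trial_type + block, obs,
                        mean, na.action = stats::na.pass, na.rm = TRUE)
  obs_se <- aggregate(cbind(p_best, mean_rt) ~ trial_type + block, obs,
                      function(v) sd(v, na.rm = TRUE) /
                        sqrt(sum(is.finite(v))),
                      na.action = stats::na.pass)

  idx <- local_seed(seed, sample.int(kept, n_draws))
  sim_means <- vector("list", n_draws)
  for (j in seq_len(n_draws)) {
    per_subj <- lapply(seq_len(S), function(s) {
      canon <- canon_by_subj[[s]][idx[j], ]
      sim <- cpp_sim_session(ints$type, ints$tt, gp, canon, info$drpow,
                             info$bspow, 3, dt,
                             as.numeric(seed) * 131071 + j * 8191 + s)
      sess <- data.frame(trial_type = schedule$trial_type,
                         within_type_index = schedule$within_type_index,
                         choice = factor(c("worse", "better",
                                           "omitted")[match(sim$choice,
                                                            c(0L, 1L, -1L))],
                                         levels = c("better", "worse",
                                                    "omitted")),
                         rt = sim$rt)
      block_stats(sess, blocks)
    })
    sim_means[[j]] <- aggregate(cbind(p_best, mean_rt) ~ trial_type + block,
                                do.call(rbind, per_subj), mean,
                                na.action = stats::na.pass, na.rm = TRUE)
  }

  key <- paste(obs_mean$trial_type, obs_mean$block)
  long <- function(df, col) df[[col]][match(key, paste(df$trial_type,
                                                       df$block))]
  out <- NULL
  for (stat in c("p_best", "mean_rt")) {
    gen <- vapply(sim_means, long, numeric(length(key)), col = stat)
    gen <- matrix(gen, nrow = length(key))
    hdi_bounds <- t(apply(gen, 1, hdi, prob = prob))
    o <- long(obs_mean, stat)
    out <- rbind(out, data.frame(
      trial_type = obs_mean$trial_type, block = obs_mean$block, stat = stat,
      observed = o, se = long(obs_se, stat),
      hdi_lo = hdi_bounds[, 1], hdi_hi = hdi_bounds[, 2],
      inside = o >= hdi_bounds[, 1] & o <= hdi_bounds[, 2]))
  }
  structure(list(summary = out,
                 coverage = mean(out$inside, na.rm = TRUE),
                 n_draws = n_draws, block_size = block_size),
            class = "rlddm_ppc")
}

#' @export
print.rlddm_ppc <- function(x, ...) {
  cat(sprintf(
    "<rlddm_ppc> %d draws, blocks of %d trials: %.0f%% of observed block means inside the 95%% HDI\n",
    x$n_draws, x$block_size, 100 * x$coverage))
  invisible(x)
}

block_index <- function(schedule, block_size) {
  ceiling(schedule$within_type_index / block_size)
}

block_stats <- function(sess, blocks) {
  ok <- sess$choice != "omitted"
  df <- data.frame(trial_type = sess$trial_type, block = blocks,
                   best = ifelse(ok, sess$choice == "better", NA),
                   rt = ifelse(ok, sess$rt, NA))
  p <- aggregate(best ~ trial_type + block, df, mean,
                 na.action = stats::na.pass, na.rm = TRUE)
  r <- aggregate(rt ~ trial_type + block, df, mean,
                 na.action = stats::na.pass, na.rm = TRUE)
  data.frame(trial_type = p$trial_type, block = p$block,
             p_best = ifelse(is.nan(p$best), NA, p$best),
             mean_rt = ifelse(is.nan(r$rt), NA, r$rt))
}

#' Highest density interval
#'
#' Narrowest interval containing a given mass of the draws (not
#' equal-tailed).
#'
#' @param x numeric draws.
#' @param prob interval mass.
#' @return c(lower, upper).
#' @export
hdi <- function(x, prob = 0.95) {
  x <- sort(x[is.finite(x)])
  n <- length(x)
  if (!n) return(c(NA_real_, NA_real_))
  k <- max(1, ceiling(prob * n))
  if (k >= n) return(range(x))
  widths <- x[k:n] - x[seq_len(n - k + 1)]
  i <- which.min(widths)
  c(x[i], x[i + k - 1])
}
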