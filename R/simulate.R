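#' Simulate one subject's behavioural session
#'
#' Plays a subject with known RLDDM parameters through a task schedule.  Per
#' trial, the drift rate and boundary are computed for the variant, a
#' (boundary hit, decision time) pair is drawn from the first-passage process
#' (Euler scheme with within-step Brownian-bridge crossing checks), the
#' non-decision time is added, responses exceeding the 3 s window are
#' censored as omitted, the outcome is sampled from the contingencies and the
#' chosen option's value updated.  Omitted trials carry no outcome and leave
#' the values unchanged.
#'
#' @param params a [subject_params()] object.
#' @param schedule a [build_schedule()] object.
#' @param rng_seed integer seed (the simulation is deterministic given it).
#' @param subject_id identifier stored in the session table.
#' @param rt_max response window in seconds (default 3).
#' @param dt Euler step in seconds (default 1e-3; the bridge correction
#'   removes the leading discretization bias).
#' @param variant optional override; defaults to `params$variant`.
#' @return a `behavioural_session` data frame: `subject_id`, `trial`,
#'   `trial_type`, `within_type_index`, `choice` (better/worse/omitted),
#'   `rt` (s, `NA` when omitted), `reinforcement` (`NA` when omitted).
#' @examples
#' sched <- build_schedule(1, n_per_type = 10)
#' pars <- subject_params("RLDDM_bspow", alpha = .3, nu = 3, bb = 1.2,
#'                        bp = -0.2, t_nd = .35)
#' sess <- simulate_subject(pars, sched, rng_seed = 7)
#' table(sess$choice)
#' @export
simulate_subject <- function(params, schedule, rng_seed, subject_id = "s1",
                             rt_max = 3, dt = 1e-3, variant = NULL) {
  stopifnot(inherits(params, "subject_params"))
  if (!is.null(variant) && variant != params$variant)
    stop("variant override must match params$variant")
  info <- variant_info(params$variant, params$include_nu)
  ints <- schedule_to_int(schedule)
  gp <- ifelse(is.na(schedule$good_option_prob), 0.5,
               schedule$good_option_prob)
  sim <- cpp_sim_session(ints$type, ints$tt, gp, canon_vector(params),
                         info$drpow, info$bspow, rt_max, dt,
                         as.numeric(rng_seed))
  out <- data.frame(
    subject_id = subject_id,
    trial = schedule$trial,
    trial_type = schedule$trial_type,
    within_type_index = schedule$within_type_index,
    choice = factor(c("worse", "better", "omitted")[match(sim$choice,
                                                          c(0L, 1L, -1L))],
                    levels = c("better", "worse", "omitted")),
    rt = sim$rt,
    reinforcement = sim$reinf
  )
  class(out) <- c("behavioural_session", "data.frame")
  out
}

#' Brute-force first-passage oracle
#'
#' Plain Euler-Maruyama simulation of the unit-noise diffusion, with no
#' crossing correction - a deliberately naive reference used to validate the
#' analytic WFPT density in tests.
#'
#' @param drift,boundary,z_frac,t_nd diffusion parameters as in
#'   [wfpt_density()].
#' @param n_paths number of simulated paths.
#' @param dt Euler step (s).  A warning is given if `dt` is not much smaller
#'   than the typical first-passage time.
#' @param rng_seed integer seed.
#' @param t_max censoring horizon for the decision time (s).
#' @return a data frame with one row per path: `hit` (upper/lower/none) and
#'   `rt` (decision time + `t_nd`; `NA` if censored).
#' @examples
#' o <- diffusion_oracle(0, 1, 0.5, 0.3, n_paths = 500, dt = 1e-3,
#'                       rng_seed = 1)
#' mean(o$hit == "upper")
#' @export
diffusion_oracle <- function(drift, boundary, z_frac, t_nd, n_paths,
                             dt = 1e-4, rng_seed = 1, t_max = 30) {
  stopifnot(boundary > 0, z_frac > 0, z_frac < 1, dt > 0, n_paths >= 1)
  typ <- z_frac * (1 - z_frac) * boundary^2  # zero-drift mean passage time
  if (dt >= typ)
    warning("dt is not small relative to the typical first-passage time")
  m <- cpp_oracle_fpt(drift, boundary, z_frac, t_nd, as.integer(n_paths),
                      dt, t_max, as.numeric(rng_seed))
  data.frame(hit = factor(c("lower", "none", "upper")[m[, 1] + 2],
                          levels = c("upper", "lower", "none")),
             rt = m[, 2])
}

#' Group-level generative specification
#'
#' Defines the distribution subject parameters are drawn from when
#' simulating a cohort group: per-parameter means on the natural scale,
#' spreads on the sampling (transformed) scale - logit for `alpha`, log for
#' `nu`, `bb`/`a` and `t_nd`, identity for the powers - plus a linear
#' severity model mapping the slowing parameters to an expected Hamilton
#' depression rating, `HAM-D = round(c0 - c_nu*nu + c_bp*bp + c_tnd*t_nd +
#' noise)` clipped at 0, with an affine HAM-A model on top of HAM-D.
#'
#' @param mean named list/vector of parameter means (natural scale) for the
#'   variant's free parameters.
#' @param sd named list/vector of spreads (transformed scale), strictly
#'   positive (0 is allowed only for degenerate test cohorts).
#' @param severity list with `c0`, `c_nu`, `c_bp`, `c_tnd`, `sd` and
#'   `hama_intercept`, `hama_slope`, `hama_sd`.
#' @param variant model variant the parameters are for.
#' @return a `group_spec` object.
#' @seealso [default_group_specs()]
#' @export
group_spec <- function(mean, sd, severity = NULL,
                       variant = winning_variant()) {
  info <- variant_info(variant)
  mean <- as.list(mean); sd <- as.list(sd)
  missing <- setdiff(info$free, names(mean))
  if (length(missing))
    stop("missing mean for parameter(s): ", paste(missing, collapse = ", "))
  if (any(unlist(sd) < 0)) stop("spreads must be non-negative")
  if (!is.null(mean$alpha) && (mean$alpha <= 0 || mean$alpha >= 1))
    stop("alpha mean must lie in (0, 1)")
  if (is.null(severity))
    severity <- list(c0 = 0.5, c_nu = 0, c_bp = 0, c_tnd = 0, sd = 0.8,
                     hama_intercept = 0.4, hama_slope = 0, hama_sd = 0.8)
  out <- list(mean = mean, sd = sd, severity = severity,
              variant = info$name)
  class(out) <- "group_spec"
  out
}

#' Default generative specifications for the three study groups
#'
#' The control group learns with a moderately collapsing boundary and a
#' brisk drift scalar; the two depression groups share the injected
#' "psychomotor slowing" profile: a lower drift-rate scalar, a higher
#' (less collapsing) boundary-separation power and a longer non-decision
#' time.  Severity coefficients are set so simulated Hamilton depression
#' ratings sit near 0 for controls and span roughly 5-25 in the depression
#' groups, with HAM-D increasing in `t_nd`.
#'
#' @param variant model variant (default the winning boundary-power model).
#' @return named list of [group_spec()] objects (`control`, `unipolar`,
#'   `bipolar`).
#' @examples
#' names(default_group_specs())
#' @export
default_group_specs <- function(variant = winning_variant()) {
  sds <- list(alpha = 0.5, nu = 0.25, bb = 0.15, bp = 0.12, t_nd = 0.15)
  sev_pat <- function(c0) list(c0 = c0, c_nu = 2, c_bp = 10, c_tnd = 30,
                               sd = 2.5, hama_intercept = 1,
                               hama_slope = 0.9, hama_sd = 2)
  list(
    control = group_spec(
      mean = list(alpha = 0.25, nu = 3.5, bb = 1.2, bp = -0.25, t_nd = 0.35),
      sd = sds, variant = variant),
    unipolar = group_spec(
      mean = list(alpha = 0.25, nu = 2.0, bb = 1.2, bp = -0.05, t_nd = 0.45),
      sd = sds, severity = sev_pat(8), variant = variant),
    bipolar = group_spec(
      mean = list(alpha = 0.25, nu = 2.4, bb = 1.2, bp = -0.10, t_nd = 0.42),
      sd = sds, severity = sev_pat(3), variant = variant)
  )
}

draw_subject_params <- function(spec, include_nu = FALSE) {
  info <- variant_info(spec$variant, include_nu)
  vals <- list()
  for (nm in info$free) {
    m <- transform_to_unconstrained(spec$mean[[nm]], nm)
    s <- if (!is.null(spec$sd[[nm]])) spec$sd[[nm]] else 0
    vals[[nm]] <- transform_to_natural(m + s * rnorm(1), nm)
  }
  do.call(subject_params,
          c(list(variant = spec$variant, include_nu = include_nu), vals))
}

severity_ratings <- function(spec, params) {
  sev <- spec$severity
  nu <- if (!is.null(params$nu)) params$nu else 0
  bp <- if (!is.null(params$bp)) params$bp else 0
  hamd <- sev$c0 - sev$c_nu * nu + sev$c_bp * bp + sev$c_tnd * params$t_nd +
    rnorm(1, 0, sev$sd)
  hamd <- max(0, round(hamd))
  hama <- max(0, round(sev$hama_intercept + sev$hama_slope * hamd +
                         rnorm(1, 0, sev$hama_sd)))
  list(hamd = as.integer(hamd), hama = as.integer(hama))
}

#' Simulate a cohort of subjects
#'
#' Draws subject parameters from per-group generative specifications,
#' simulates each subject's session on the shared schedule, and generates
#' HAM-D/HAM-A severity ratings from the groups' severity models.
#'
#' @param spec_by_group named list of [group_spec()] objects; the names are
#'   the group labels.
#' @param n_per_group subjects per group; either a single integer or a
#'   vector named after (or aligned with) the groups.
#' @param schedule a [build_schedule()] object shared by all subjects.
#' @param rng_seed integer master seed (parameter draws, ratings and
#'   sessions all derive from it).
#' @param rt_max,dt passed to [simulate_subject()].
#' @return an `rlddm_cohort`: list with `sessions` (list of session data
#'   frames), `subjects` (data frame `subject_id`, `group`, `hamd`, `hama`),
#'   `true_params` (data frame of generating parameters, for recovery
#'   checks), and `schedule`.
#' @examples
#' sched <- build_schedule(1, n_per_type = 10)
#' co <- simulate_cohort(default_group_specs()["control"], 2, sched, 1)
#' length(co$sessions)
#' @export
simulate_cohort <- function(spec_by_group, n_per_group, schedule, rng_seed,
                            rt_max = 3, dt = 1e-3) {
  if (!length(spec_by_group)) stop("spec_by_group must not be empty")
  if (is.null(names(spec_by_group)))
    stop("spec_by_group must be a named list")
  if (any(n_per_group < 1)) stop("n_per_group must be >= 1")
  n_per_group <- rep_len(as.integer(n_per_group), length(spec_by_group))
  groups <- names(spec_by_group)
  sessions <- list(); subjects <- list(); tps <- list()
  idx <- 0L
  local_seed(rng_seed, {
    for (g in seq_along(groups)) {
      spec <- spec_by_group[[g]]
      for (i in seq_len(n_per_group[g])) {
        idx <- idx + 1L
        sid <- sprintf("%s_%02d", groups[g], i)
        pars <- draw_subject_params(spec)
        rat <- severity_ratings(spec, pars)
        sess_seed <- (rng_seed * 1009 + idx * 7919) %% 2147483647
        sessions[[idx]] <- simulate_subject(pars, schedule, sess_seed,
                                            subject_id = sid,
                                            rt_max = rt_max, dt = dt)
        subjects[[idx]] <- data.frame(subject_id = sid, group = groups[g],
                                      hamd = rat$hamd, hama = rat$hama)
        free <- setdiff(names(pars), c("z", "variant", "include_nu"))
        tps[[idx]] <- data.frame(subject_id = sid,
                                 as.list(unlist(pars[free])))
      }
    }
  })
  out <- list(sessions = sessions,
              subjects = do.call(rbind, subjects),
              true_params = do.call(rbind, tps),
              schedule = schedule)
  class(out) <- "rlddm_cohort"
  out
}

#' @export
print.rlddm_cohort <- function(x, ...) {
  cat(sprintf("<rlddm_cohort> %d subjects, %d trials each\n",
              length(x$sessions), nrow(x$schedule)))
  print(table(x$subjects$group))
  invisible(x)
}
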