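#' Delta-rule value update and prediction error
#'
#' The value of the chosen option is updated by
#' `Q <- Q + alpha * (R - Q)`, where `R - Q` is the reward prediction error.
#' Only the chosen option's value changes on a trial.
#'
#' @param q current value estimate of the chosen option.
#' @param alpha learning rate in (0, 1).
#' @param r reinforcement received (+1/0 on reward trials, -1/0 on loss
#'   trials).
#' @return `q_update()`: the updated value; `prediction_error()`: the raw
#'   difference between reinforcement and expectation.
#' @examples
#' q_update(0, 0.5, 1)          # 0.5
#' prediction_error(0.7, 1)     # +0.3
#' @export
q_update <- function(q, alpha, r) {
  if (any(alpha <= 0) || any(alpha >= 1))
    stop("alpha must lie strictly in (0, 1)")
  q + alpha * (r - q)
}

#' @rdname q_update
#' @export
prediction_error <- function(q, r) r - q

#' Trial-wise drift rate
#'
#' The drift rate is the value difference between the options mapped to the
#' upper and lower decision boundaries, scaled by `nu` (base and
#' boundary-power variants) or by the power term `(t/10)^p` (drift-power
#' variants; `nu` is retained only when the parameters were built with
#' `include_nu = TRUE`).  Neutral trials use the fixed value difference 0.4.
#'
#' @param q_upper,q_lower value estimates of the options at the upper/lower
#'   boundary.  Pass `neutral = TRUE` to use the fixed neutral difference.
#' @param params a [subject_params()] object.
#' @param t 1-based within-trial-type index (used by the power variants).
#' @param neutral logical; neutral trial?
#' @return the drift rate (evidence units per second).
#' @examples
#' pars <- subject_params("RLDDM", alpha = .3, nu = 2, a = 1.5, t_nd = .3)
#' drift_rate(0.7, 0.3, pars, t = 1)   # 0.8
#' @export
drift_rate <- function(q_upper, q_lower, params, t = 1L, neutral = FALSE) {
  stopifnot(inherits(params, "subject_params"), t >= 1)
  info <- variant_info(params$variant, params$include_nu)
  qdiff <- if (neutral) 0.4 else q_upper - q_lower
  scal <- if (!info$drpow) params$nu
          else (if (params$include_nu) params$nu else 1) * (t / 10)^params$p
  qdiff * scal
}

#' Trial-wise boundary separation
#'
#' Constant `a` for the base and drift-power variants; `bb * (t/10)^bp` for
#' the boundary-power variants (collapsing when `bp < 0`).
#'
#' @inheritParams drift_rate
#' @return the boundary separation (> 0).
#' @examples
#' pars <- subject_params("RLDDM_bspow", alpha = .3, nu = 2, bb = 2, bp = 1,
#'                        t_nd = .3)
#' boundary_separation(pars, t = 20)   # 4
#' @export
boundary_separation <- function(params, t = 1L) {
  stopifnot(inherits(params, "subject_params"), t >= 1)
  info <- variant_info(params$variant, params$include_nu)
  if (info$bspow) params$bb * (t / 10)^params$bp else params$a
}

#' Wiener first passage time density
#'
#' Joint density over (boundary hit, reaction time) of the first passage of a
#' unit-noise diffusion with drift `drift`, boundary separation `boundary`,
#' relative starting point `z_frac`, shifted by the non-decision time `t_nd`.
#' The upper-boundary density is obtained from the lower-boundary series by
#' reflection (`z_frac -> 1 - z_frac`, `drift -> -drift`).  Evaluation uses
#' the dual small-time/large-time series with automatic switching, truncated
#' for absolute error below `1e-7`.  Reaction times at or below `t_nd` return
#' density zero (not an error), for robust likelihoods.
#'
#' @param rt reaction time(s) in seconds.
#' @param boundary boundary separation (> 0).
#' @param t_nd non-decision time (s).
#' @param z_frac starting-point fraction in (0, 1).
#' @param drift drift rate.
#' @param hit `"upper"` or `"lower"` - which boundary was reached.
#' @param log return the log density.
#' @return density in 1/s (integrates to 1 over rt and both hits).
#' @examples
#' wfpt_density(0.8, boundary = 2, t_nd = 0.3, z_frac = 0.5, drift = 1,
#'              hit = "upper")
#' @export
wfpt_density <- function(rt, boundary, t_nd, z_frac, drift,
                         hit = c("upper", "lower"), log = FALSE) {
  hit <- match.arg(hit)
  if (boundary <= 0) stop("boundary must be positive")
  if (z_frac <= 0 || z_frac >= 1) stop("z_frac must lie in (0, 1)")
  ld <- cpp_wfpt_logd(as.numeric(rt), boundary, t_nd, z_frac, drift,
                      hit == "upper")
  if (log) ld else exp(ld)
}

# closed-form absorption probability at the upper boundary (unit noise)
prob_upper <- function(drift, boundary, z_frac) {
  if (abs(drift) < 1e-12) return(z_frac)
  x0 <- z_frac * boundary
  expm1(-2 * drift * x0) / expm1(-2 * drift * boundary)
}

#' Session log likelihood
#'
#' Replays a behavioural session trial by trial, maintaining the per-pair
#' value estimates (neutral value difference fixed at 0.4, never updated),
#' and sums the log WFPT density over non-omitted trials.  Omitted trials
#' contribute nothing and leave the values unchanged.
#'
#' @param params a [subject_params()] object.
#' @param session a behavioural session as returned by [simulate_subject()].
#' @param schedule the [build_schedule()] the session was played on.
#' @param per_trial return the per-trial log densities instead of their sum.
#' @return the log likelihood (or a per-trial vector with `NA` on omitted
#'   trials).
#' @export
session_loglik <- function(params, session, schedule, per_trial = FALSE) {
  stopifnot(inherits(params, "subject_params"))
  if (nrow(session) != nrow(schedule))
    stop("session and schedule must be aligned trial-for-trial")
  info <- variant_info(params$variant, params$include_nu)
  sub <- session_to_cpp(session, schedule)
  res <- cpp_session_loglik(sub, canon_vector(params), info$drpow,
                            info$bspow, per_trial)
  if (per_trial) res else res[[1]]
}

# behavioural session data frame -> integer-coded list for the C++ core
session_to_cpp <- function(session, schedule, use = NULL) {
  ints <- schedule_to_int(schedule)
  choice <- match(as.character(session$choice),
                  c("worse", "better")) - 1L  # better = 1, worse = 0
  choice[is.na(choice)] <- -1L
  out <- list(type = ints$type, tt = ints$tt, choice = choice,
              rt = as.numeric(session$rt),
              reinf = as.numeric(session$reinforcement))
  if (!is.null(use)) out$use <- as.integer(use)
  out
}
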