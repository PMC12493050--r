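# Shared fixtures, built lazily and cached for the whole test run.  Sizes
# are scaled-down study analogues: full-length 180-trial schedules, small
# cohorts, reduced sampler settings (documented in the methods vignette).

.fx <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fx[[name]])) .fx[[name]] <- builder()
  .fx[[name]]
}

fx_schedule <- function() fixture("schedule", function() build_schedule(42))

fx_small_cohort <- function() fixture("small_cohort", function()
  simulate_cohort(default_group_specs()["control"], 5, fx_schedule(),
                  rng_seed = 11))

# one converged reference fit of the winning model (reused by the
# convergence-gate and posterior-predictive tests)
fx_small_fit <- function() fixture("small_fit", function()
  fit_hierarchical(fx_small_cohort(), "RLDDM_bspow",
                   sampler_config(chains = 4, warmup = 1000, iter = 6000,
                                  thin = 3, seed = 3)))

# recovery study for the winning model (reused by recovery and calibration
# tests)
fx_recovery <- function() fixture("recovery", function()
  parameter_recovery("RLDDM_bspow", 30, fx_schedule(),
                     seeds = list(sim = 101, fit = 202),
                     config = sampler_config(chains = 4, warmup = 600,
                                             iter = 1200, seed = 5)))

quiet_fit <- function(...) {
  withCallingHandlers(
    fit_hierarchical(...),
    warning = function(w) {
      if (grepl("non-converged", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
}

# empirical joint-scale Kolmogorov-Smirnov distance between first-passage
# samples and the analytic WFPT density (both boundaries, signed-time trick:
# lower-boundary times enter with negative sign)
wfpt_ks_distance <- function(samples, drift, boundary, t_nd,
                             z_frac = 0.5) {
  hit <- samples$hit
  stopifnot(all(hit %in% c("upper", "lower")))
  x <- ifelse(hit == "upper", samples$rt, -samples$rt)
  x <- sort(x)
  n <- length(x)
  cdf_joint <- function(q) {
    vapply(q, function(v) {
      if (v >= 0) {
        p_lower_total(drift, boundary, z_frac) +
          wfpt_cdf_num(v, drift, boundary, t_nd, z_frac, "upper")
      } else {
        p_lower_total(drift, boundary, z_frac) -
          wfpt_cdf_num(-v, drift, boundary, t_nd, z_frac, "lower")
      }
    }, 0)
  }
  # evaluate on a quantile grid (quadrature at every sample is wasteful)
  idx <- unique(round(seq(1, n, length.out = 400)))
  theo <- cdf_joint(x[idx])
  emp_hi <- idx / n
  emp_lo <- (idx - 1) / n
  max(pmax(abs(emp_hi - theo), abs(emp_lo - theo)))
}

p_lower_total <- function(drift, boundary, z_frac) {
  1 - rlddm:::prob_upper(drift, boundary, z_frac)
}

wfpt_cdf_num <- function(q, drift, boundary, t_nd, z_frac, hit) {
  if (q <= t_nd) return(0)
  stats::integrate(function(rt)
    wfpt_density(rt, boundary, t_nd, z_frac, drift, hit),
    t_nd, q, rel.tol = 1e-8, subdivisions = 400L)$value
}
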