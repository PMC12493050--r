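test_that("single-trial likelihood equals the WFPT density", {
  sched <- build_schedule(1, n_per_type = 1)
  pars <- subject_params("RLDDM", alpha = .3, nu = 2, a = 1.5, t_nd = .3)
  sess <- simulate_subject(pars, sched, rng_seed = 4)
  i <- which(sess$choice != "omitted")[1]
  one_sess <- sess[i, ]
  one_sched <- sched[i, ]
  ll <- session_loglik(pars, one_sess, one_sched)
  ty <- as.character(one_sched$trial_type)
  qdiff <- if (ty == "neutral") 0.4 else 0  # initial values are 0
  expect_equal(ll, wfpt_density(one_sess$rt, 1.5, 0.3, 0.5, qdiff * 2,
                                hit = if (one_sess$choice == "better")
                                  "upper" else "lower", log = TRUE))
})

test_that("per-trial log densities sum to the session log likelihood", {
  sched <- fx_schedule()
  pars <- subject_params("RLDDM_bspow", alpha = .3, nu = 3, bb = 1.2,
                         bp = -.2, t_nd = .35)
  sess <- simulate_subject(pars, sched, rng_seed = 5)
  pt <- session_loglik(pars, sess, sched, per_trial = TRUE)
  expect_length(pt, 180)
  expect_true(all(is.na(pt[sess$choice == "omitted"])))
  expect_equal(sum(pt, na.rm = TRUE), session_loglik(pars, sess, sched))
})

test_that("an all-omitted session contributes zero log likelihood", {
  sched <- build_schedule(1, n_per_type = 2)
  pars <- subject_params("RLDDM", alpha = .3, nu = 2, a = 1.5, t_nd = .3)
  sess <- simulate_subject(pars, sched, rng_seed = 4)
  sess$choice[] <- "omitted"
  sess$rt[] <- NA
  sess$reinforcement[] <- NA
  expect_equal(session_loglik(pars, sess, sched), 0)
})

test_that("generating parameters beat perturbed ones on a long session", {
  sched <- fx_schedule()
  pars <- subject_params("RLDDM_bspow", alpha = .3, nu = 3, bb = 1.2,
                         bp = -.2, t_nd = .35)
  ll_true <- 0; ll_halved <- 0
  half <- subject_params("RLDDM_bspow", alpha = .3, nu = 1.5, bb = 1.2,
                         bp = -.2, t_nd = .35)
  for (i in 1:5) {
    sess <- simulate_subject(pars, sched, rng_seed = 300 + i)
    ll_true <- ll_true + session_loglik(pars, sess, sched)
    ll_halved <- ll_halved + session_loglik(half, sess, sched)
  }
  expect_gt(ll_true, ll_halved)
})

test_that("likelihood rejects misaligned sessions and impossible t_nd", {
  sched <- fx_schedule()
  pars <- subject_params("RLDDM", alpha = .3, nu = 2, a = 1.5, t_nd = .3)
  sess <- simulate_subject(pars, sched, rng_seed = 4)
  expect_error(session_loglik(pars, sess[1:10, ], sched), "aligned")
  big_tnd <- subject_params("RLDDM", alpha = .3, nu = 2, a = 1.5, t_nd = 4)
  expect_identical(session_loglik(big_tnd, sess, sched), -Inf)
})
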