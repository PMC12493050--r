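test_that("simulated sessions respect the response window and t_nd floor", {
  sched <- fx_schedule()
  pars <- subject_params("RLDDM_bspow", alpha = .3, nu = 3, bb = 1.2,
                         bp = -.2, t_nd = .3)
  sess <- simulate_subject(pars, sched, rng_seed = 2)
  ok <- sess$choice != "omitted"
  expect_true(all(sess$rt[ok] > 0.3))
  expect_true(all(sess$rt[ok] <= 3))
  expect_true(all(is.na(sess$rt[!ok])))
  expect_true(all(sess$reinforcement[ok & sess$trial_type == "neutral"] ==
                    0))
  expect_true(all(sess$reinforcement[ok & sess$trial_type == "reward"] %in%
                    c(0, 1)))
  expect_true(all(sess$reinforcement[ok & sess$trial_type == "loss"] %in%
                    c(-1, 0)))
  # determinism
  expect_identical(sess, simulate_subject(pars, sched, rng_seed = 2))
})

test_that("zero drift scalar yields symmetric choices on reward trials", {
  sched <- build_schedule(3)
  pars <- subject_params("RLDDM", alpha = .3, nu = 1e-9, a = 1.2,
                         t_nd = .3)
  picks <- unlist(lapply(1:10, function(i) {
    s <- simulate_subject(pars, sched, rng_seed = i)
    s$choice[s$choice != "omitted" & s$trial_type != "neutral"] == "better"
  }))
  se <- sqrt(0.25 / length(picks))
  expect_lt(abs(mean(picks) - 0.5), 4 * se)
})

test_that("learning emerges: late reward accuracy beats early accuracy", {
  sched <- fx_schedule()
  pars <- subject_params("RLDDM", alpha = .3, nu = 3, a = 1.5, t_nd = .3)
  accs <- vapply(1:30, function(i) {
    s <- simulate_subject(pars, sched, rng_seed = 100 + i)
    r <- s[s$trial_type == "reward" & s$choice != "omitted", ]
    c(mean(r$choice[r$within_type_index <= 20] == "better"),
      mean(r$choice[r$within_type_index > 40] == "better"))
  }, c(0, 0))
  expect_gt(mean(accs[2, ]), mean(accs[1, ]))
  expect_gt(mean(accs[2, ]), 0.6)
})

test_that("raising the boundary baseline raises the omission rate", {
  sched <- fx_schedule()
  om <- vapply(c(1, 2.5, 4.5), function(bb) {
    pars <- subject_params("RLDDM_bspow", alpha = .3, nu = 2, bb = bb,
                           bp = 0.1, t_nd = .4)
    mean(vapply(1:5, function(i) {
      s <- simulate_subject(pars, sched, rng_seed = 200 + i)
      mean(s$choice == "omitted")
    }, 0))
  }, 0)
  expect_true(all(diff(om) >= 0))
  expect_gt(om[3], om[1])
})

test_that("cohorts have the requested shape and injected group effects", {
  sched <- build_schedule(5, n_per_type = 15)
  specs <- default_group_specs()
  co <- simulate_cohort(specs, 10, sched, rng_seed = 21)
  expect_equal(length(co$sessions), 30)
  expect_true(all(vapply(co$sessions, nrow, 0L) == 45))
  expect_equal(unname(table(co$subjects$group)), rep(10L, 3),
               ignore_attr = TRUE)
  expect_true(all(co$subjects$hamd >= 0) && all(co$subjects$hama >= 0))
  # identical specs => no systematic group difference
  co0 <- simulate_cohort(list(a = specs$control, b = specs$control),
                         30, sched, rng_seed = 8)
  tp <- merge(co0$true_params, co0$subjects)
  p <- t.test(nu ~ group, tp)$p.value
  expect_gt(p, 0.01)
  expect_error(simulate_cohort(list(), 5, sched, 1), "empty")
  expect_error(simulate_cohort(specs, 0, sched, 1), "n_per_group")
})

test_that("default depression spec injects lower nu and higher bp", {
  sched <- build_schedule(5, n_per_type = 5)
  specs <- default_group_specs()[c("control", "unipolar")]
  co <- simulate_cohort(specs, 20, sched, rng_seed = 31)
  tp <- merge(co$true_params, co$subjects)
  expect_lt(mean(tp$nu[tp$group == "unipolar"]),
            mean(tp$nu[tp$group == "control"]))
  expect_gt(mean(tp$bp[tp$group == "unipolar"]),
            mean(tp$bp[tp$group == "control"]))
  # severity model: depression HAM-D spans a clinical range, controls near 0
  expect_gt(mean(tp$hamd[tp$group == "unipolar"]), 5)
  expect_lt(mean(tp$hamd[tp$group == "control"]), 3)
})
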