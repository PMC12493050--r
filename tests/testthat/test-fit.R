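test_that("hierarchical fits are reproducible and respect supports", {
  sched <- build_schedule(9, n_per_type = 20)
  co <- simulate_cohort(default_group_specs()["control"], 3, sched, 13)
  cfg <- sampler_config(chains = 2, warmup = 150, iter = 300, seed = 77)
  f1 <- quiet_fit(co, "RLDDM_bspow", cfg)
  f2 <- quiet_fit(co, "RLDDM_bspow", cfg)
  expect_identical(f1$draws, f2$draws)
  # different seed -> different draws
  cfg$seed <- 78
  f3 <- quiet_fit(co, "RLDDM_bspow", cfg)
  expect_false(identical(f1$draws, f3$draws))
  # supports: alpha in (0,1), positives positive
  a <- posterior_draws(f1, "alpha[1]", merge_chains = TRUE)
  expect_true(all(a > 0 & a < 1))
  for (p in c("nu[1]", "bb[1]", "t_nd[1]"))
    expect_true(all(posterior_draws(f1, p, merge_chains = TRUE) > 0))
  expect_equal(dim(f1$draws), c(300, 2, 2 * 5 + 3 * 5))
})

test_that("every variant fits and exposes its own free parameters", {
  sched <- build_schedule(9, n_per_type = 15)
  co <- simulate_cohort(default_group_specs()["control"], 2, sched, 14)
  cfg <- sampler_config(chains = 2, warmup = 100, iter = 200, seed = 5)
  for (v in rlddm_variants()) {
    f <- quiet_fit(co, v, cfg)
    expect_setequal(f$free, variant_info(v)$free)
    expect_true(all(is.finite(f$draws)))
  }
})

test_that("a single-subject fit runs and is less informed than a cohort fit", {
  sched <- fx_schedule()
  co1 <- simulate_cohort(default_group_specs()["control"], 1, sched, 15)
  f1 <- quiet_fit(co1, "RLDDM_bspow",
                  sampler_config(chains = 2, warmup = 300, iter = 600,
                                 seed = 9))
  expect_equal(length(f1$subject_ids), 1)
  big <- fx_recovery()$fit
  sd1 <- sd(posterior_draws(f1, "mu_nu", merge_chains = TRUE))
  sd30 <- sd(posterior_draws(big, "mu_nu", merge_chains = TRUE))
  expect_gt(sd1, sd30)
})

test_that("subjects with no usable trials are excluded with a warning", {
  sched <- build_schedule(9, n_per_type = 5)
  co <- simulate_cohort(default_group_specs()["control"], 2, sched, 16)
  co$sessions[[2]]$choice[] <- "omitted"
  co$sessions[[2]]$rt[] <- NA
  co$sessions[[2]]$reinforcement[] <- NA
  expect_warning(
    quiet_fit(co, "RLDDM",
              sampler_config(chains = 2, warmup = 50, iter = 100,
                             seed = 2)),
    "excluding")
})

test_that("subject-level true values are covered by central posterior intervals", {
  rec <- fx_recovery()
  fit <- rec$fit
  truth <- rec$values
  covered <- vapply(seq_len(nrow(truth)), function(i) {
    s <- match(truth$subject_id[i], fit$subject_ids)
    dr <- posterior_draws(fit, sprintf("%s[%d]", truth$parameter[i], s),
                          merge_chains = TRUE)
    q <- quantile(dr, c(0.025, 0.975))
    truth$true[i] >= q[1] && truth$true[i] <= q[2]
  }, TRUE)
  expect_gte(mean(covered), 0.9)
})
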