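test_that("folds partition trials within subject, stratified by type", {
  sched <- fx_schedule()
  co <- simulate_cohort(default_group_specs()["control"], 3, sched, 17)
  cfg <- sampler_config(chains = 2, warmup = 100, iter = 200, seed = 4)
  res <- kfold_elpd(co, "RLDDM", k = 5, seeds = list(fold = 1, fit = 2),
                    config = cfg)
  expect_equal(dim(res$folds), c(180, 3))
  for (s in 1:3) {
    expect_equal(unname(table(res$folds[, s])), rep(36L, 5),
                 ignore_attr = TRUE)
    for (ty in levels(sched$trial_type)) {
      per_type <- table(res$folds[sched$trial_type == ty, s])
      expect_true(all(per_type == 12))
    }
  }
  # every non-omitted trial gets a pointwise value, omitted are NA
  omitted <- unlist(lapply(co$sessions, function(x) x$choice == "omitted"))
  expect_equal(is.na(res$pointwise$lpd), unname(omitted))
  expect_true(is.finite(res$elpd) && res$se > 0)
  # determinism
  res2 <- kfold_elpd(co, "RLDDM", k = 5, seeds = list(fold = 1, fit = 2),
                     config = cfg)
  expect_equal(res$elpd, res2$elpd)
  expect_error(kfold_elpd(co, "RLDDM", k = 1), "at least 2")
})

test_that("model comparison arithmetic follows the pointwise definition", {
  pw <- function(lpd) data.frame(subject_id = "s1",
                                 trial = seq_along(lpd), lpd = lpd)
  set.seed(1)
  base <- rnorm(100, -1)
  # identical model: zero difference, zero SE
  cmp <- compare_models(list(m1 = pw(base), m2 = pw(base)))
  expect_equal(cmp$elpd_diff, c(0, 0))
  expect_equal(cmp$diff_se, c(0, 0))
  # constant per-trial offset c: difference n*c, SE 0
  cmp2 <- compare_models(list(m1 = pw(base), m2 = pw(base + 0.3)))
  expect_equal(cmp2$variant[1], "m2")
  expect_equal(cmp2$elpd_diff[cmp2$variant == "m1"], -100 * 0.3)
  expect_equal(cmp2$diff_se[cmp2$variant == "m1"], 0)
  expect_true(cmp2$winner[1])
  expect_equal(cmp2$elpd[cmp2$variant == "m2"] -
                 cmp2$elpd[cmp2$variant == "m1"], 30)
  # mismatched pointwise sets are refused
  expect_error(compare_models(list(m1 = pw(base), m2 = pw(base[1:50]))),
               "length")
})

test_that("elpd is invariant to fold relabelling", {
  pw <- data.frame(subject_id = "s1", trial = 1:60,
                   lpd = rnorm(60, -1))
  perm <- sample(60)
  expect_equal(sum(pw$lpd), sum(pw$lpd[perm]))
  se <- function(v) sqrt(length(v)) * sd(v)
  expect_equal(se(pw$lpd), se(pw$lpd[perm]))
})
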