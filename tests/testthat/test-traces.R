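make_session <- function(sched, choice, reinf, rt = 0.8) {
  data.frame(subject_id = "s1", trial = sched$trial,
             trial_type = sched$trial_type,
             within_type_index = sched$within_type_index,
             choice = factor(choice, levels = c("better", "worse",
                                                "omitted")),
             rt = ifelse(choice == "omitted", NA, rt),
             reinforcement = reinf)
}

test_that("value traces replay the delta rule exactly", {
  sched <- build_schedule(1, n_per_type = 3)
  pars <- subject_params("RLDDM_bspow", alpha = .5, nu = 2, bb = 1.2,
                         bp = -.2, t_nd = .3)
  # always choose the better option, always rewarded (+1) on reward trials
  reinf <- ifelse(sched$trial_type == "reward", 1,
                  ifelse(sched$trial_type == "loss", 0, 0))
  sess <- make_session(sched, rep("better", nrow(sched)), reinf)
  tr <- compute_traces(pars, sess, sched)
  rw <- tr$values[tr$values$trial_type == "reward", ]
  expect_equal(rw$q_high, c(0, 0.5, 0.75))   # value before each update
  pe_rw <- tr$pe[tr$pe$trial_type == "reward", ]
  expect_equal(pe_rw$pe, c(1, 0.5, 0.25))
  expect_true(all(pe_rw$sign == "positive"))
  # neutral condition: fixed difference 0.4 on every trial
  ne <- tr$values[tr$values$trial_type == "neutral", ]
  expect_equal(ne$q_high - ne$q_low, rep(0.4, 3))
  expect_equal(nrow(tr$pe[tr$pe$trial_type == "neutral", ]), 0)
  # determinism
  expect_identical(tr, compute_traces(pars, sess, sched))
})

test_that("omitted trials carry values forward and produce no PE", {
  sched <- build_schedule(2, n_per_type = 3)
  choice <- rep("better", nrow(sched))
  choice[which(sched$trial_type == "reward")[2]] <- "omitted"
  reinf <- ifelse(sched$trial_type == "reward", 1, 0)
  reinf[choice == "omitted"] <- NA
  pars <- subject_params("RLDDM", alpha = .5, nu = 2, a = 1.5, t_nd = .3)
  tr <- compute_traces(pars, make_session(sched, choice, reinf), sched)
  rw <- tr$values[tr$values$trial_type == "reward", ]
  expect_equal(rw$q_high, c(0, 0.5, 0.5))  # carried forward over omission
  expect_equal(nrow(tr$pe[tr$pe$trial_type == "reward", ]), 2)
})

test_that("detrending centres controls and preserves shifts and correlations", {
  sched <- build_schedule(3, n_per_type = 10)
  pars <- lapply(c(.2, .3, .4), function(a)
    subject_params("RLDDM_bspow", alpha = a, nu = 3, bb = 1.2, bp = -.2,
                   t_nd = .35))
  ctrl <- lapply(1:3, function(i)
    compute_traces(pars[[i]], simulate_subject(pars[[i]], sched, 400 + i,
                                               subject_id = paste0("c", i)),
                   sched))
  det <- detrend_values(ctrl, ctrl)
  pooled <- do.call(rbind, lapply(det, `[[`, "values"))
  means <- aggregate(q_high ~ trial_type + within_type_index, pooled, mean)
  expect_true(all(abs(means$q_high) < 1e-12))
  # a constant offset survives detrending exactly
  shifted <- ctrl[[1]]
  shifted$values$q_high <- shifted$values$q_high + 0.2
  d1 <- detrend_values(shifted, ctrl)
  base <- detrend_values(ctrl[[1]], ctrl)
  expect_equal(d1$values$q_high - base$values$q_high,
               rep(0.2, nrow(d1$values)))
  # detrending subtracts a common trend: correlations across subjects with
  # any per-subject scalar are unchanged
  per_subj_raw <- vapply(ctrl, function(tr)
    mean(tr$values$q_high[tr$values$trial_type == "reward"]), 0)
  per_subj_det <- vapply(detrend_values(ctrl, ctrl), function(tr)
    mean(tr$values$q_high[tr$values$trial_type == "reward"]), 0)
  rating <- c(3, 9, 17)
  expect_equal(cor(per_subj_raw, rating), cor(per_subj_det, rating))
  expect_error(detrend_values(ctrl, list()), "non-empty")
})

test_that("section means partition the task and propagate empty cells", {
  sched <- fx_schedule()
  pars <- subject_params("RLDDM_bspow", alpha = .3, nu = 3, bb = 1.2,
                         bp = -.2, t_nd = .35)
  sess <- simulate_subject(pars, sched, 31)
  tr <- compute_traces(pars, sess, sched)
  sm <- section_means(tr)
  expect_setequal(unique(sm$section), c("full", "s1", "s2", "s3"))
  expect_equal(sum(sm$section == "full"), 8)  # 4 value + 4 PE measures
  # full-task value mean = mean over all 60 trials (partition identity)
  v <- tr$values[tr$values$trial_type == "reward", ]
  expect_equal(sm$mean[sm$section == "full" &
                         sm$measure == "value_reward_high"],
               mean(v$q_high))
  secs <- vapply(c("s1", "s2", "s3"), function(s)
    sm$mean[sm$section == s & sm$measure == "value_reward_high"], 0)
  expect_equal(mean(v$q_high), mean(secs), tolerance = 1e-12)
  # forced PE pattern: +0.1 in section 1, -0.1 in section 2
  tr2 <- tr
  tr2$pe <- data.frame(subject_id = "s1", trial = 1:40,
                       trial_type = factor(rep("reward", 40),
                                           levels = c("reward", "loss")),
                       within_type_index = 1:40,
                       pe = c(rep(0.1, 20), rep(-0.1, 20)),
                       sign = factor(c(rep("positive", 20),
                                       rep("negative", 20)),
                                     levels = c("positive", "negative")))
  sm2 <- section_means(tr2)
  expect_equal(sm2$mean[sm2$section == "s1" &
                          sm2$measure == "pe_reward_positive"], 0.1)
  expect_equal(sm2$mean[sm2$section == "s2" &
                          sm2$measure == "pe_reward_negative"], -0.1)
  expect_true(is.na(sm2$mean[sm2$section == "s1" &
                               sm2$measure == "pe_reward_negative"]))
})

test_that("event export passes modulators through with ordered onsets", {
  sched <- fx_schedule()
  pars <- subject_params("RLDDM_bspow", alpha = .3, nu = 3, bb = 1.5,
                         bp = 0.1, t_nd = .4)
  sess <- simulate_subject(pars, sched, 77)
  tr <- compute_traces(pars, sess, sched)
  dir <- withr::local_tempdir()
  ev <- export_modulators(sess, tr, sched, dir = dir)
  n_om <- sum(sess$choice == "omitted")
  n_neutral_ok <- sum(sess$trial_type == "neutral" &
                        sess$choice != "omitted")
  expect_equal(nrow(ev$value), 180 - n_om)
  expect_equal(nrow(ev$pe), 180 - n_om - n_neutral_ok)
  expect_true(all(diff(ev$value$onset_s) > 0))
  expect_true(all(diff(ev$pe$onset_s) > 0))
  ok <- sess$choice != "omitted"
  expect_equal(ev$value$modulator, tr$values$value_decision[ok])
  expect_true(all(file.exists(ev$paths)))
  reread <- read.delim(ev$paths["pe"])
  expect_equal(reread$modulator, ev$pe$modulator, tolerance = 1e-6)
})
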