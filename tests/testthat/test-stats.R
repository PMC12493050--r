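test_that("group parameter test recovers identity and unit effects", {
  fit <- fx_small_fit()
  # a group compared with itself: d = 0, p = 1 by construction
  r <- param_group_test(fit, fit, "nu")
  expect_equal(r$effect, 0)
  expect_gt(r$p, 0.99)
  expect_equal(r$statistic, 0)
  # d definition on synthetic posteriors: means 0 and 1, unit spread
  fake <- function(shift) {
    f <- fit
    i <- grep("^nu\\[", dimnames(f$draws)[[3]])
    f$draws[, , i] <- array(rnorm(prod(dim(f$draws)[1:2]) * length(i),
                                  shift), c(dim(f$draws)[1:2], length(i)))
    f
  }
  set.seed(4)
  d <- param_group_test(fake(0), fake(1), "nu")$effect
  expect_lt(abs(d - 1), 0.05)
  expect_error(param_group_test(fit, fit, "p"), "not free")
})

test_that("signal tests handle one-sample, two-sample and degenerate input", {
  r0 <- signal_group_test(c(0, 0, 0))
  expect_true(is.na(r0$statistic))
  expect_match(r0$flag, "zero variance")
  set.seed(5)
  x <- rnorm(100, 0.5)
  r1 <- signal_group_test(x)
  expect_true(r1$ci[1] < 0.5 && r1$ci[2] > 0.5)
  expect_lt(r1$p, 0.001)
  expect_equal(r1$effect, mean(x) / sd(x))
  r2 <- signal_group_test(x, x)
  expect_equal(r2$statistic, 0)
  # sign convention: positive effect means group b larger
  r3 <- signal_group_test(x, x + 1)
  expect_gt(r3$effect, 0)
})

test_that("false-positive rate of the null two-sample test is nominal", {
  set.seed(6)
  hits <- vapply(1:200, function(i)
    signal_group_test(rnorm(20), rnorm(20))$p < 0.05, TRUE)
  se <- sqrt(0.05 * 0.95 / 200)
  expect_lt(abs(mean(hits) - 0.05), 3.5 * se + 1e-9)
})

test_that("severity correlations match Pearson definitions", {
  x <- 1:10
  expect_equal(severity_correlation(x, 2 * x + 3)$effect, 1)
  expect_equal(severity_correlation(x, -x)$effect, -1)
  set.seed(7)
  a <- rnorm(40); b <- 0.6 * a + rnorm(40, 0, 0.8)
  r <- severity_correlation(a, b)
  # affine invariance
  r2 <- severity_correlation(10 + 5 * a, 2 - 3 * b)
  expect_equal(abs(r$effect), abs(r2$effect))
  expect_equal(r$p, r2$p)
  # Fisher-z CI contains the point estimate
  expect_true(r$ci[1] < r$effect && r$effect < r$ci[2])
  expect_match(severity_correlation(a, rep(1, 40))$flag, "constant")
  expect_error(severity_correlation(1:2, 1:2), "at least 3")
})

test_that("Benjamini-Hochberg adjustment is available behind a flag", {
  tab <- data.frame(p = c(0.01, 0.02, 0.04, 0.5))
  out <- adjust_pvalues(tab)
  expect_equal(out$p_adj, stats::p.adjust(tab$p, "BH"))
})
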