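test_that("WFPT density normalizes and splits mass by the closed form", {
  for (cfg in list(c(v = 0, a = 1.5), c(v = 1, a = 2), c(v = -0.8, a = 1),
                   c(v = 2.5, a = 0.8))) {
    up <- stats::integrate(function(rt)
      wfpt_density(rt, cfg[["a"]], 0.2, 0.5, cfg[["v"]], "upper"),
      0.2, 60, rel.tol = 1e-9)$value
    lo <- stats::integrate(function(rt)
      wfpt_density(rt, cfg[["a"]], 0.2, 0.5, cfg[["v"]], "lower"),
      0.2, 60, rel.tol = 1e-9)$value
    expect_lt(abs(up + lo - 1), 1e-3)
    expect_lt(abs(up - rlddm:::prob_upper(cfg[["v"]], cfg[["a"]], 0.5)),
              1e-6)
  }
})

test_that("zero drift from the midpoint splits mass exactly in half", {
  up <- stats::integrate(function(rt)
    wfpt_density(rt, 2, 0.3, 0.5, 0, "upper"), 0.3, 120,
    rel.tol = 1e-10)$value
  expect_lt(abs(up - 0.5), 1e-6)
})

test_that("reflection identity links upper and lower densities", {
  rt <- seq(0.35, 3, by = 0.12)
  for (v in c(-1, 0.5, 2)) for (w in c(0.3, 0.5, 0.7)) {
    expect_equal(wfpt_density(rt, 1.6, 0.3, w, v, "upper"),
                 wfpt_density(rt, 1.6, 0.3, 1 - w, -v, "lower"),
                 tolerance = 1e-10)
  }
})

test_that("zero-drift mean first-passage time matches the closed form", {
  for (w in c(0.3, 0.5)) for (a in c(1, 2)) {
    m <- stats::integrate(function(rt)
      rt * (wfpt_density(rt, a, 0, w, 0, "upper") +
              wfpt_density(rt, a, 0, w, 0, "lower")),
      0, 200, rel.tol = 1e-9)$value
    expect_lt(abs(m - w * (1 - w) * a^2), 1e-4)
  }
})

test_that("upper-boundary probability increases strictly with drift", {
  drifts <- seq(-2, 2, by = 0.5)
  mass <- vapply(drifts, function(v)
    stats::integrate(function(rt) wfpt_density(rt, 1.8, 0.2, 0.5, v,
                                               "upper"),
                     0.2, 80, rel.tol = 1e-9)$value, 0)
  expect_true(all(diff(mass) > 0))
})

test_that("density is zero at or below the non-decision time", {
  expect_equal(wfpt_density(c(0.1, 0.3), 2, 0.3, 0.5, 1, "upper"),
               c(0, 0))
  expect_identical(wfpt_density(0.2, 2, 0.3, 0.5, 1, "lower", log = TRUE),
                   -Inf)
  expect_error(wfpt_density(1, -1, 0.3, 0.5, 1), "boundary")
  expect_error(wfpt_density(1, 2, 0.3, 1.2, 1), "z_frac")
})

test_that("density matches the Euler-Maruyama oracle at moderate n", {
  o <- diffusion_oracle(1, 2, 0.5, 0.3, n_paths = 4e4, dt = 1e-4,
                        rng_seed = 5)
  expect_true(all(o$hit != "none"))
  ks <- wfpt_ks_distance(o, 1, 2, 0.3)
  expect_lt(ks, 0.015)  # 3 sd of the KS noise floor at this n
  # oracle sanity: symmetric split at zero drift, drift dominance at high v
  o0 <- diffusion_oracle(0, 1.5, 0.5, 0, n_paths = 2e4, dt = 2e-4,
                         rng_seed = 6)
  expect_lt(abs(mean(o0$hit == "upper") - 0.5), 3 * sqrt(0.25 / 2e4))
  o9 <- diffusion_oracle(8, 1.5, 0.5, 0, n_paths = 2000, dt = 2e-4,
                         rng_seed = 7)
  expect_gt(mean(o9$hit == "upper"), 0.98)
  expect_warning(diffusion_oracle(0, 1, 0.5, 0, 10, dt = 0.5,
                                  rng_seed = 1), "dt")
})
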