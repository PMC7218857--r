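test_that("nrmse follows the range-normalized formula", {
  ref <- c(0, 10)
  expect_equal(nrmse(ref, ref), 0)
  expect_equal(nrmse(ref + 1, ref), 0.1)
  expect_error(nrmse(c(1, 2), c(5, 5)), "zero range")
  # invariant under a common shift of both series
  set.seed(71)
  a <- rnorm(100); b <- rnorm(100)
  expect_equal(nrmse(a + 13, b + 13), nrmse(a, b))
})

test_that("pearson rho is exact for affine pairs and null for noise", {
  set.seed(72)
  r <- rnorm(50)
  expect_equal(pearson_rho(2 * r + 5, r), 1)
  expect_equal(pearson_rho(-r, r), -1)
  x <- rnorm(10000); y <- rnorm(10000)
  expect_lt(abs(pearson_rho(x, y)), 0.05)
  expect_error(pearson_rho(rep(1, 10), rnorm(10)), "constant")
  # invariance under positive affine maps of either input
  expect_equal(pearson_rho(3 * x + 2, y), pearson_rho(x, y))
})

test_that("xapen is zero for identical constants and matches the double loop", {
  expect_equal(xapen(rep(2, 30), rep(2, 30), r = 0.2), 0)
  set.seed(73)
  for (i in 1:3) {
    x <- rnorm(200); y <- rnorm(200)
    expect_equal(xapen(x, y), oracle_xapen(x, y), tolerance = 1e-12)
  }
})

test_that("xapen ranks aligned signals as more synchronous than shuffled", {
  set.seed(74)
  t <- (0:499) / 50
  x <- sin(2 * pi * t) + rnorm(500, sd = 0.1)
  y <- sin(2 * pi * t + 0.1) + rnorm(500, sd = 0.1)
  expect_lt(xapen(x, y), xapen(x, sample(y)))
})

test_that("xapen is non-increasing in r once every template matches", {
  set.seed(75)
  x <- rnorm(300); y <- rnorm(300)
  vals <- vapply(c(0.5, 1, 1.5, 2), function(r) xapen(x, y, r = r), 0)
  expect_true(all(diff(vals) <= 1e-12))
})

test_that("drift slope recovers linear trends and annihilates fast sinusoids", {
  t <- (0:999) / 100
  expect_equal(drift_slope(0.01 * t, t), 0.01)
  n <- 1e4
  ts <- 0:(n - 1)
  expect_lt(abs(drift_slope(sin(2 * pi * ts / 50), ts)), 1e-6)
  set.seed(76)
  y <- sin(2 * pi * ts / 50) + 0.02 * ts + rnorm(n, sd = 0.05)
  expect_equal(drift_slope(y, ts), 0.02, tolerance = 0.001)
  expect_error(drift_slope(c(1, 2), c(3, 3)), "degenerate")
})

test_that("drift ratio and turn increment follow the slope arithmetic", {
  t <- (0:999) / 100
  expect_equal(drift_ratio(5 + 3 * t, 5 + 3 * t, t), 1)
  expect_equal(drift_ratio(0.04 * t, 0.01 * t, t), 4)

  y <- c(0.01 * t[1:500], 0.01 * t[500] + 0.02 * (t[501:1000] - t[500]))
  inc <- turn_drift_increment(y, t, 501L)
  expect_equal(inc, 100, tolerance = 1)
  same <- turn_drift_increment(0.01 * t, t, 501L)
  expect_equal(same, 0, tolerance = 1e-6)
})

test_that("Bland-Altman reports mean difference and 1.96-sd limits", {
  r <- bland_altman(1:10, 1:10)
  expect_equal(c(r$mean_diff, r$lo, r$hi), c(0, 0, 0))
  r5 <- bland_altman(1:10 + 5, 1:10)
  expect_equal(c(r5$mean_diff, r5$lo, r5$hi), c(5, 5, 5))

  set.seed(77)
  d <- rnorm(1e4, mean = -4.5, sd = 3)
  rg <- bland_altman(d, rep(0, 1e4))
  expect_equal(rg$mean_diff, -4.5, tolerance = 0.1)
  expect_equal(rg$hi - rg$lo, 2 * 1.96 * 3, tolerance = 0.15)
})

test_that("the one-sample t-test matches the closed form and has power", {
  sym <- c(-2, -1, 0, 1, 2)
  r <- one_sample_ttest(sym)
  expect_equal(r$t, 0)
  expect_equal(r$p, 1)
  expect_false(r$reject)

  set.seed(78)
  shifted <- rnorm(10000, mean = 0.1)
  expect_true(one_sample_ttest(shifted)$reject)
  expect_error(one_sample_ttest(rep(1, 5)), "variance")
})

test_that("SUS scoring spans 0..100 and is monotone in the right direction", {
  top <- matrix(rep(c(5, 1), 5), nrow = 1)
  bottom <- matrix(rep(c(1, 5), 5), nrow = 1)
  mid <- matrix(3, 1, 10)
  expect_equal(sus_score(top)$mean, 100)
  expect_equal(sus_score(bottom)$mean, 0)
  expect_equal(sus_score(mid)$mean, 50)

  set.seed(79)
  for (i in 1:20) {
    resp <- matrix(sample(1:5, 10, replace = TRUE), nrow = 1)
    base <- sus_score(resp)$mean
    item <- sample(1:10, 1)
    up <- resp
    if (item %% 2 == 1) up[item] <- min(5, up[item] + 1) else up[item] <- max(1, up[item] - 1)
    expect_gte(sus_score(up)$mean, base)
  }
  expect_error(sus_score(matrix(6, 1, 10)), "1..5")
  expect_error(sus_score(matrix(3, 1, 9)), "10")
})

test_that("the agreement report bundles the metric suite consistently", {
  set.seed(80)
  t <- (0:999) / 100
  ref <- 10 * sin(2 * pi * t)
  test <- ref + 0.05 * t - 1 + rnorm(1000, sd = 0.1)
  rep <- agreement_report(test, ref, t)
  expect_equal(rep$nrmse, nrmse(test, ref))
  expect_equal(rep$rho, pearson_rho(test, ref))
  expect_equal(rep$ba_mean_diff, bland_altman(test, ref)$mean_diff)
  expect_true(rep$ba_lo <= rep$ba_mean_diff && rep$ba_mean_diff <= rep$ba_hi)
})
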