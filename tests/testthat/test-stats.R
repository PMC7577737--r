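test_that("one-sample t-test matches hand computations", {
  r <- one_sample_t(c(1, 2, 3, 4, 5))
  expect_equal(r$statistic, 3 / (sd(1:5) / sqrt(5)), tolerance = 1e-12)
  expect_equal(r$statistic, 4.2426, tolerance = 1e-4)
  expect_equal(r$p_value, 0.013236, tolerance = 1e-4)
  sym <- one_sample_t(c(-1, 0, 1))
  expect_equal(sym$statistic, 0)
  expect_equal(sym$p_value, 1)
  expect_error(one_sample_t(c(1, 1, 1, 1)), "variance")
  expect_error(one_sample_t(2), "2")
})

test_that("BH-FDR matches the brute-force step-up on random inputs", {
  r <- bh_fdr(c(0.01, 0.02, 0.03, 0.04, 0.05), q = 0.05)
  expect_true(all(r$rejected))
  single <- bh_fdr(0.5, q = 0.05)
  expect_false(single$rejected)
  expect_equal(single$p_adjusted, 0.5)
  set.seed(60)
  for (i in 1:1000) {
    m <- sample(1:50, 1)
    p <- switch(sample(3, 1), runif(m), rbeta(m, 0.3, 3),
                round(runif(m), 2))
    q <- sample(c(0.01, 0.05, 0.1, 0.25), 1)
    r <- bh_fdr(p, q)
    expect_identical(r$rejected, brute_bh_reject(p, q))
    expect_true(all(r$p_adjusted >= p - 1e-12))
  }
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("Pearson correlation matches hand computations and affine invariance", {
  expect_equal(pearson_r(1:10, 2 * (1:10) + 1)$r, 1)
  expect_equal(pearson_r(1:10, -(1:10))$r, -1)
  expect_equal(pearson_r(c(1, 2, 3), c(1, 3, 2))$r, 0.5)
  set.seed(61)
  x <- rnorm(30); y <- rnorm(30)
  base <- pearson_r(x, y)
  shifted <- pearson_r(3 * x - 7, 0.5 * y + 2)
  expect_equal(shifted$r, base$r, tolerance = 1e-12)
  expect_equal(shifted$p_value, base$p_value, tolerance = 1e-12)
  expect_error(pearson_r(c(1, 2), c(3, 4)), "3")
  expect_error(pearson_r(rep(1, 5), 1:5), "variance")
})

test_that("forward-backward coupling picks windows by start time", {
  t_start <- seq(0, 359.5, by = 0.5)
  phase <- sin(2 * pi * t_start / 60)
  est <- data.frame(t_start = t_start, fw_db = 0.3 + 0.2 * phase,
                    bw_db = 0.3 - 0.2 * phase)
  r <- fw_bw_coupling(est, minutes = c(2, 5))
  expect_lt(r$r, -0.99)
  expect_identical(r$n, sum(t_start >= 120 & t_start < 300))
  const <- data.frame(t_start = t_start, fw_db = 1, bw_db = 1)
  expect_error(fw_bw_coupling(const), "variance")
  # independent modulation: mean coupling near zero over seeds
  set.seed(62)
  rs <- replicate(20, {
    e <- data.frame(t_start = t_start, fw_db = rnorm(720), bw_db = rnorm(720))
    fw_bw_coupling(e, c(0, 6))$r
  })
  expect_lt(abs(mean(rs)), 3 * sd(rs) / sqrt(20))
})

test_that("JZS Bayes factor matches reference values and is scale-free", {
  # references computed from an independent implementation of the
  # Cauchy-prior one-sample Bayes factor (scale 0.707)
  ref <- list(list(t = 2, n = 10, bf = 1.2823715),
              list(t = 0, n = 12, bf = 0.2873760),
              list(t = 3, n = 13, bf = 5.3341055),
              list(t = -1.5, n = 13, bf = 0.6887186))
  for (cs in ref) {
    expect_equal(corticalwaves:::jzs_bf10_t(cs$t, cs$n), cs$bf,
                 tolerance = 1e-5)
  }
  set.seed(63)
  x <- rnorm(100, mean = 1, sd = 1)
  expect_gt(jzs_bf10(x), 100)
  expect_equal(jzs_bf10(x), jzs_bf10(2 * x), tolerance = 1e-8)
  expect_lt(jzs_bf10(c(-2, -1, 0, 1, 2)), 1)
  expect_error(jzs_bf10(rep(1, 5)), "variance")
})

test_that("two-sample power follows the noncentral t exactly", {
  expect_equal(two_sample_power(0.3, 0.3, 1, 10), 0.05, tolerance = 1e-12)
  # printed-inputs worked example: means 0.19 vs -0.20, sd 0.29, n 13;
  # power.t.test is the independent cross-check (it drops the far rejection
  # tail, negligible at these effect sizes)
  p_fw <- two_sample_power(0.19, -0.20, 0.29, 13)
  expect_gte(p_fw, 0.90)
  expect_equal(p_fw,
               power.t.test(n = 13, delta = 0.39, sd = 0.29)$power,
               tolerance = 1e-6)
  p_bw <- two_sample_power(0.18, 0.51, 0.25, 13)
  expect_equal(p_bw,
               power.t.test(n = 13, delta = 0.33, sd = 0.25)$power,
               tolerance = 1e-6)
  # monotone in effect and n, decreasing in sd, alpha in the limit
  expect_gt(two_sample_power(0.5, 0, 1, 10), two_sample_power(0.3, 0, 1, 10))
  expect_gt(two_sample_power(0.3, 0, 1, 30), two_sample_power(0.3, 0, 1, 10))
  expect_lt(two_sample_power(0.3, 0, 2, 10), two_sample_power(0.3, 0, 1, 10))
  expect_lt(abs(two_sample_power(0.3, 0, 1e6, 10) - 0.05), 1e-3)
})

test_that("null t-tests keep their nominal type-I rate", {
  set.seed(64)
  reps <- 10000
  p <- replicate(reps, one_sample_t(rnorm(13))$p_value)
  rate <- mean(p < 0.05)
  expect_gt(rate, 0.04)
  expect_lt(rate, 0.06)
})
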