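test_that("near-zero effects are never called", {
  set.seed(3)
  y <- runif(100, -1e-6, 1e-6)
  res <- pa_detect(y)
  expect_false(any(res$called))
  expect_true(all(res$threshold > 0))
})

test_that("a planted outlier among null effects is the only call", {
  set.seed(1)
  y <- c(rnorm(99), 10)
  res <- pa_detect(y)
  expect_equal(which(res$called), 100L)
  oracle <- naive_pa_oracle(y)
  expect_identical(res$called, oracle$called)
  expect_equal(res$threshold, oracle$threshold)
})

test_that("incremental detector is bit-identical to the from-scratch oracle", {
  set.seed(101)
  for (i in 1:25) {
    n <- sample(10:200, 1)
    y <- rnorm(n, sd = runif(1, 0.2, 3)) +
      sample(c(0, 4), n, replace = TRUE, prob = c(0.9, 0.1))
    alpha <- sample(c(0.01, 0.05, 0.1), 1)
    res <- pa_detect(y, alpha = alpha)
    oracle <- naive_pa_oracle(y, alpha = alpha)
    expect_identical(res$called, oracle$called)
    expect_equal(res$threshold, oracle$threshold, tolerance = 1e-12)
  }
})

test_that("sign flip mirrors onto the reversed processing direction", {
  # the criterion is even in y gene-by-gene, but the sequential exclusion is
  # directional: negating y is exactly equivalent to reversing the
  # processing order, not to the original run
  set.seed(13)
  for (i in 1:10) {
    y <- rnorm(80) + sample(c(0, 5), 80, replace = TRUE, prob = c(0.92, 0.08))
    flip <- pa_detect(-y)
    mirror <- pa_detect(y, order = "decreasing")
    expect_identical(flip$called, mirror$called)
    expect_equal(flip$threshold, mirror$threshold, tolerance = 1e-12)
    # the extremity order visits |y| in a sign-free sequence, so there the
    # invariance is exact
    expect_identical(pa_detect(y, order = "extremity")$called,
                     pa_detect(-y, order = "extremity")$called)
  }
})

test_that("calls are invariant to positive rescaling with the default beta", {
  set.seed(17)
  y <- rnorm(120) + sample(c(0, 4), 120, replace = TRUE, prob = c(0.9, 0.1))
  res1 <- pa_detect(y)
  res2 <- pa_detect(2.5 * y)
  expect_identical(res1$called, res2$called)
  expect_equal(res2$threshold, 2.5 * res1$threshold, tolerance = 1e-10)
})

test_that("threshold reflects the sequential exclusion of called effects", {
  # a clump of extreme effects: once the first ones are excluded the
  # reference spread shrinks, so later thresholds are smaller than the
  # threshold a single-pass (non-sequential) interval would use
  set.seed(23)
  y <- c(rnorm(95, sd = 0.5), 8, 8.5, 9, 9.5, 10)
  res <- pa_detect(y)
  expect_true(all(res$called[96:100]))
  ranks <- res$processing_rank[96:100]
  thr <- res$threshold[96:100]
  expect_true(all(diff(thr[order(ranks)]) < 0))
})

test_that("detector validates inputs and degenerate runs", {
  expect_error(pa_detect(c(1, 2)), "at least 3", class = "pade_validation_error")
  expect_error(pa_detect(c(1, NA, 3)), "non-finite", class = "pade_validation_error")
  # tiny n with huge spread: nearly everything gets called until the
  # reference set collapses
  expect_error(pa_detect(c(-1e9, 1, 1.1, 1.2),
                         prior = nig_prior(beta = 1e-6)),
               "reference set", class = "pade_numerical_error")
})

test_that("extremity-first processing order is available and differs in rank", {
  set.seed(31)
  y <- rnorm(50)
  inc <- pa_detect(y, order = "increasing")
  ext <- pa_detect(y, order = "extremity")
  expect_equal(inc$processing_rank[order(y)], 1:50)
  expect_equal(ext$processing_rank[order(-abs(y))], 1:50)
})
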