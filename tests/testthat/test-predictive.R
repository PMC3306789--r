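test_that("default beta follows the (tau - 2) R^2 rule", {
  expect_equal(default_beta(c(0, 1), tau = 3), 1)
  expect_equal(default_beta(c(-2, 0, 2), tau = 3), 16)

  set.seed(5)
  y <- rnorm(1000)
  hi <- -Inf; lo <- Inf
  for (v in y) { if (v > hi) hi <- v; if (v < lo) lo <- v }  # independent scan
  expect_equal(default_beta(y, tau = 3), (hi - lo)^2)
  expect_equal(default_beta(y, tau = 4.5), 2.5 * (hi - lo)^2)

  expect_error(default_beta(rep(2, 5), tau = 3), "range 0",
               class = "pade_numerical_error")
})

test_that("posterior update matches the closed-form conjugate quantities", {
  prior <- nig_prior(mu0 = 0, lambda = 0.01, tau = 3, beta = 1)
  post <- posterior_update(rep(1, 4), prior)
  expect_equal(post$mu_star, 4 / 4.01)
  expect_equal(post$tau_star, 8)
  expect_equal(post$beta_star, 1 + 4 * 0.01 / 4.01)

  # lambda -> 0: posterior location collapses to the sample mean
  set.seed(21)
  y <- rnorm(20, mean = 3)
  p0 <- posterior_update(y, nig_prior(lambda = 1e-12, beta = 2))
  expect_equal(p0$mu_star, mean(y), tolerance = 1e-9)
  expect_equal(p0$beta_star, 2 + 19 * var(y), tolerance = 1e-6)

  # term-by-term oracle on seeded draws
  set.seed(42)
  y <- rnorm(50)
  prior <- nig_prior(mu0 = 0.3, lambda = 0.5, tau = 4, beta = 2)
  post <- posterior_update(y, prior)
  n <- 50; ybar <- loop_mean(y); s2 <- loop_var(y)
  expect_equal(post$mu_star, (n / (n + 0.5)) * ybar + (0.5 / (n + 0.5)) * 0.3)
  expect_equal(post$tau_star, 4 + n + 1)
  expect_equal(post$beta_star, 2 + (n - 1) * s2 + n * 0.5 * (ybar - 0.3)^2 / (n + 0.5))

  # the textbook degrees-of-freedom variant drops the extra unit
  expect_equal(posterior_update(y, prior, df_rule = "conjugate")$tau_star, 4 + n)

  expect_error(posterior_update(1, prior), ">= 2",
               class = "pade_validation_error")
})

test_that("predictive variance follows the scaled-t formula", {
  post <- structure(list(mu_star = 0, tau_star = 4, beta_star = 1,
                         n_ref = 1L, lambda = 1),
                    class = "predictive_params")
  expect_equal(predictive_variance(post), 0.75)
  post2 <- post; post2$beta_star <- 2
  expect_equal(predictive_variance(post2), 1.5)

  set.seed(42)
  y <- rnorm(50)
  p <- posterior_update(y, nig_prior(mu0 = 0.3, lambda = 0.5, tau = 4, beta = 2))
  ts <- p$tau_star
  expect_equal(predictive_variance(p),
               (ts / (ts - 2)) * (p$beta_star * (50 + 0.5 + 1) / (ts * (50 + 0.5))))

  post$tau_star <- 2
  expect_error(predictive_variance(post), "undefined",
               class = "pade_numerical_error")
})

test_that("credibility interval is symmetric with a quadrature-checked quantile", {
  set.seed(9)
  p <- posterior_update(rnorm(8), nig_prior(beta = 1.5))
  ci <- credibility_interval(p, 0.1)
  expect_equal(ci[["upper"]] - p$mu_star, p$mu_star - ci[["lower"]])

  # alpha -> 1: interval collapses onto the location
  ci1 <- credibility_interval(p, 1 - 1e-12)
  expect_lt(ci1[["upper"]] - ci1[["lower"]], 1e-5)

  # tau* = 8 half-width against an integrate-plus-bisection t quantile
  post <- structure(list(mu_star = 0, tau_star = 8, beta_star = 3,
                         n_ref = 5L, lambda = 0.01),
                    class = "predictive_params")
  ci <- credibility_interval(post, 0.05)
  expect_equal(ci[["upper"]],
               t_quantile_oracle(0.975, 8) * sqrt(predictive_variance(post)),
               tolerance = 1e-7)

  expect_error(credibility_interval(p, 1.2), class = "pade_validation_error")
})

test_that("beta* decomposition and location equivariance hold", {
  set.seed(77)
  for (i in 1:20) {
    y <- rnorm(sample(3:40, 1), sd = runif(1, 0.1, 4))
    mu0 <- rnorm(1); lam <- runif(1, 1e-3, 2)
    prior <- nig_prior(mu0 = mu0, lambda = lam, tau = 3, beta = 0.5)
    p <- posterior_update(y, prior)
    n <- length(y)
    add1 <- (n - 1) * var(y)
    add2 <- n * lam * (mean(y) - mu0)^2 / (n + lam)
    expect_equal(p$beta_star - 0.5, add1 + add2)
    expect_gte(add1, 0); expect_gte(add2, 0)

    c0 <- rnorm(1)
    ps <- posterior_update(y + c0, nig_prior(mu0 = mu0 + c0, lambda = lam,
                                             tau = 3, beta = 0.5))
    expect_equal(ps$mu_star, p$mu_star + c0, tolerance = 1e-10)
    expect_equal(ps$beta_star, p$beta_star, tolerance = 1e-8)
    expect_equal(predictive_variance(ps), predictive_variance(p), tolerance = 1e-8)
  }
})
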