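test_that("log densities match known values and an independent implementation", {
  expect_equal(asym_logpdf(lognormal_dist(0, 1), 1), log(1 / sqrt(2 * pi)))
  # gengamma(1, 1, 1) is the unit exponential
  expect_equal(asym_logpdf(gengamma_dist(1, 1, 1), 1), -1)
  # frozen against a 50-digit evaluation of the Stacy density
  expect_equal(asym_logpdf(gengamma_dist(2, 3, 1.5), 2.5),
               -1.5973693093493607, tolerance = 1e-14)
  expect_error(asym_logpdf(lognormal_dist(0, 1), -2), "positive")
  # cross-check against flexsurv's original-parameterization density
  skip_if_not_installed("flexsurv")
  set.seed(3)
  for (i in 1:20) {
    lam <- runif(1, 0.5, 30); psi <- runif(1, 0.2, 50)
    tau <- runif(1, 0.2, 8); A <- runif(1, 0.1, 60)
    expect_equal(asym_logpdf(gengamma_dist(lam, psi, tau), A),
                 flexsurv::dgengamma.orig(A, shape = tau, scale = lam,
                                          k = psi, log = TRUE),
                 tolerance = 1e-10)
  }
})

test_that("densities are normalized and contain gamma and Weibull exactly", {
  set.seed(5)
  for (i in 1:10) {
    d <- gengamma_dist(runif(1, 0.5, 20), runif(1, 0.3, 30),
                       runif(1, 0.3, 6))
    # adaptive quadrature split at the median so narrow densities are
    # not missed on the unbounded interval
    med <- asym_quantile(d, 0.5)
    hi <- 1.5 * asym_quantile(d, 1 - 1e-12)
    total <- integrate(function(a) exp(asym_logpdf(d, a)), 0, med,
                       rel.tol = 1e-9)$value +
      integrate(function(a) exp(asym_logpdf(d, a)), med, hi,
                rel.tol = 1e-9)$value
    expect_equal(total, 1, tolerance = 1e-6)
  }
  A <- seq(0.05, 40, length.out = 200)
  # tau = 1: gamma with shape psi, scale lambda
  expect_equal(asym_logpdf(gengamma_dist(3, 2.5, 1), A),
               dgamma(A, shape = 2.5, scale = 3, log = TRUE),
               tolerance = 1e-12)
  # psi = 1: Weibull with shape tau, scale lambda
  expect_equal(asym_logpdf(gengamma_dist(3, 1, 2.2), A),
               dweibull(A, shape = 2.2, scale = 3, log = TRUE),
               tolerance = 1e-12)
})

test_that("moment-matched gengamma approaches the lognormal as psi grows", {
  # Prentice limit: fix the log-mean and log-sd, push psi up, and the
  # pointwise density discrepancy against the lognormal must shrink
  mu <- 3.06; sig <- 0.194
  kl <- vapply(c(10, 100, 1000), function(psi) {
    tau <- 1 / (sig * sqrt(psi))
    lam <- exp(mu - log(psi) / tau)
    d <- gengamma_dist(lam, psi, tau)
    integrate(function(a) dlnorm(a, mu, sig) *
                (dlnorm(a, mu, sig, log = TRUE) - asym_logpdf(d, a)),
              5, 80, rel.tol = 1e-10)$value
  }, numeric(1))
  expect_true(all(diff(kl) < 0))
  expect_lt(kl[3], 1e-3)
})

test_that("sampling is reproducible and has the right moments", {
  d <- lognormal_dist(3.26, 0.161)
  s1 <- asym_sample(d, 1e5, seed = 42)
  s2 <- asym_sample(d, 1e5, seed = 42)
  expect_identical(s1, s2)
  expect_true(all(s1 > 0))
  expect_equal(mean(log(s1)), 3.26, tolerance = 3 * 0.161 / sqrt(1e5) / 3.26)
  # exponential special case: mean 1
  e <- asym_sample(gengamma_dist(1, 1, 1), 1e5, seed = 7)
  expect_equal(mean(e), 1, tolerance = 0.02)
  # gengamma sampling agrees with the quantile transform distributionally
  g <- asym_sample(gengamma_dist(24.1, 2.03, 5.48), 2e4, seed = 9)
  expect_equal(unname(quantile(g, 0.5)),
               asym_quantile(gengamma_dist(24.1, 2.03, 5.48), 0.5),
               tolerance = 0.02)
})

test_that("quantiles are monotone and match closed forms and Monte Carlo", {
  expect_equal(asym_quantile(lognormal_dist(3.06, 0.194), 0.5), exp(3.06))
  expect_equal(asym_quantile(gengamma_dist(1, 1, 1), 0.5), log(2))
  q <- asym_quantile(gengamma_dist(24.1, 2.03, 5.48), c(0.025, 0.5, 0.975))
  expect_true(all(diff(q) > 0))
  mc <- quantile(asym_sample(gengamma_dist(24.1, 2.03, 5.48), 1e6,
                             seed = 11), 0.975)
  expect_equal(asym_quantile(gengamma_dist(24.1, 2.03, 5.48), 0.975),
               unname(mc), tolerance = 0.005)
  expect_error(asym_quantile(lognormal_dist(0, 1), 1.2), "inside")
})

test_that("lognormal MLE is the closed form and degenerate samples are refused", {
  fit <- asym_fit(c(1, exp(1), exp(2)), "lognormal")
  expect_equal(fit$dist$meanlog, 1)
  expect_equal(fit$dist$sdlog, sqrt(2 / 3))
  expect_error(asym_fit(c(2, 2, 2, 2), "lognormal"),
               class = "nonchron_degenerate_error")
  expect_error(asym_fit(c(2, 2, 2, 2), "gengamma"),
               class = "nonchron_degenerate_error")
})

test_that("gengamma MLE dominates the generating parameters on its own sample", {
  truth <- gengamma_dist(8.70, 30.98, 3.25)
  A <- asym_sample(truth, 5000, seed = 13)
  fit <- asym_fit(A, "gengamma")
  ll_truth <- sum(asym_logpdf(truth, A))
  expect_gte(fit$loglik, ll_truth)
  # and a warm start lands at least as high
  fit2 <- asym_fit(A, "gengamma", start = c(fit$dist$psi, fit$dist$tau))
  expect_gte(fit2$loglik, fit$loglik - 1e-6)
})

test_that("lognormal MLE bias vanishes as the sample grows", {
  truth <- lognormal_dist(3.26, 0.161)
  err <- vapply(c(50, 500, 5000), function(n) {
    est <- vapply(1:30, function(i) {
      f <- asym_fit(asym_sample(truth, n, seed = 1000 + 31 * n + i),
                    "lognormal")
      c(f$dist$meanlog, f$dist$sdlog)
    }, numeric(2))
    abs(mean(est[1, ]) - 3.26) + abs(mean(est[2, ]) - 0.161)
  }, numeric(1))
  expect_lt(err[3], err[1])
  expect_lt(err[3], 0.005)
})
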