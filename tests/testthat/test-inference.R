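test_that("model specs carry the right parameter counts and boxes", {
  expect_identical(model_spec("AL")$k_params, 4L)
  expect_identical(model_spec("AG")$k_params, 5L)
  expect_identical(model_spec("PL")$k_params, 5L)
  expect_identical(model_spec("PG")$k_params, 6L)
  sp <- model_spec("PG")
  expect_equal(sp$bounds$log10_k_prime, c(-12, -1))
  expect_equal(sp$bounds$b, c(0.01, 5))
  expect_equal(sp$bounds$l, c(-10, 10))
  # anamorphic models do not search l
  expect_length(nonchron:::.spec_bounds(model_spec("AG"))$lower, 2L)
  expect_length(nonchron:::.spec_bounds(model_spec("PL"))$lower, 3L)
})

test_that("AIC is the exact bookkeeping identity", {
  expect_equal(aic_from_nll(0, 1), 2)
  fit <- fit_growth_model(simulate_observations(ref$larch$AL, 80, seed = 1),
                          "AL", settings = quick_settings, seed = 1)
  expect_identical(fit$aic, 2 * fit$nll + 2 * fit$k_params)
})

test_that("likelihood ratio tests respect the nesting structure", {
  # equal models: zero statistic, p = 1
  same <- list(model = "AL", nll = 100)
  res <- lr_test(same, list(model = "PG", nll = 100))
  expect_equal(res$chi2, 0)
  expect_equal(res$p, 1)
  expect_identical(res$df, 2L)   # AL within PG adds two parameters
  expect_identical(lr_test(list(model = "AL", nll = 5),
                           list(model = "PL", nll = 4))$df, 1L)
  expect_error(lr_test(list(model = "AG", nll = 5),
                       list(model = "PL", nll = 4)),
               class = "nonchron_nonnested_error")
  expect_error(lr_test(list(model = "PG", nll = 5),
                       list(model = "AL", nll = 4)),
               "nested pair")
})

test_that("refits with the same seed are identical, and fuller models fit at least as well", {
  obs <- simulate_observations(ref$larch$AL, 100, seed = 55)
  f1 <- fit_growth_model(obs, "AL", settings = quick_settings, seed = 9)
  f2 <- fit_growth_model(obs, "AL", settings = quick_settings, seed = 9)
  expect_identical(f1$nll, f2$nll)
  expect_identical(f1$par, f2$par)
  # nesting: PG reaches every AL configuration (l = 0, psi ridge)
  fpg <- fit_growth_model(obs, "PG",
                          settings = pso_settings(n_particles = 16,
                                                  n_iters = 30),
                          seed = 9)
  expect_lte(fpg$nll, f1$nll + 0.05)
})

test_that("bootstrap intervals behave like percentile intervals should", {
  obs <- simulate_observations(ref$larch$AL, 100, seed = 77)
  fit <- fit_growth_model(obs, "AL", settings = quick_settings, seed = 3)
  boot <- bootstrap_ci(obs, "AL", B = 40, seed = 3,
                       settings = quick_settings, fit = fit)
  expect_identical(boot$B, 40L)
  expect_identical(boot$n_failed, 0L)
  ci <- boot$ci
  expect_true(all(ci[, "lower"] <= ci[, "upper"]))
  # point estimates inside their intervals for the distribution moments
  expect_true(ci["mu", "lower"] <= ci["mu", "estimate"] &&
              ci["mu", "estimate"] <= ci["mu", "upper"])
  # reproducible
  boot2 <- bootstrap_ci(obs, "AL", B = 40, seed = 3,
                        settings = quick_settings, fit = fit)
  expect_identical(boot$ci, boot2$ci)
  # degenerate data (identical rows): every replicate fails, structured error
  degen <- observation_set(rep(40, 5), rep(18.2, 5))
  expect_error(bootstrap_ci(degen, "AL", B = 5, seed = 1,
                            settings = quick_settings, fit = fit),
               class = "nonchron_bootstrap_error")
})

test_that("bootstrap intervals narrow as the sample doubles", {
  width <- vapply(c(100, 200), function(n) {
    obs <- simulate_observations(ref$larch$AL, n, seed = 500 + n)
    fit <- fit_growth_model(obs, "AL", settings = quick_settings, seed = 4)
    boot <- bootstrap_ci(obs, "AL", B = 30, seed = 4,
                         settings = quick_settings, fit = fit)
    unname(boot$ci["mu", "upper"] - boot$ci["mu", "lower"])
  }, numeric(1))
  expect_lt(width[2], width[1])
})

test_that("percentile curves are ordered and match their composition", {
  fit_th <- ref$cypress$PG$theta
  d <- ref$cypress$PG$dist
  ages <- seq(11, 110, by = 9)
  pc <- percentile_curves(fit_th, quantiles = c(0.025, 0.5, 0.975),
                          ages = ages, dist = d)
  # independent composition of quantile + curve evaluation
  for (q in c(0.025, 0.5, 0.975)) {
    Aq <- asym_quantile(d, q)
    expect_equal(pc$size[pc$quantile == q], growth_size(fit_th, Aq, ages),
                 tolerance = 1e-12)
  }
  # pointwise ordering in q for l >= 0
  m <- matrix(pc$size, ncol = 3)
  expect_true(all(m[, 1] < m[, 2] & m[, 2] < m[, 3]))
  # anamorphic-lognormal median curve is exp(mu) * f(t)
  thA <- growth_params(k = 0.0463, b = 1.76)
  dA <- lognormal_dist(3.06, 0.194)
  pcA <- percentile_curves(thA, quantiles = 0.5, ages = ages, dist = dA)
  expect_equal(pcA$size, exp(3.06) * growth_size(thA, 1, ages),
               tolerance = 1e-10)
})
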