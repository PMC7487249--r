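test_that("growth_size matches closed forms and limits", {
  th <- growth_params(k = 0.1, b = 1)
  # half-saturation of the b = 1 exponential at t = ln(2)/k
  expect_equal(growth_size(th, A = 25, t = log(2) / 0.1), 12.5)
  # asymptote limit
  th2 <- growth_params(k = 0.0463, b = 1.76)
  expect_equal(growth_size(th2, A = 30, t = 1e6), 30, tolerance = 1e-12)
  # polymorphic evaluation frozen against a 50-digit independent
  # evaluation of A (1 - exp(-k A^l t))^b
  thp <- growth_params(k = 0.0278, b = 1.22, l = 3.85)
  expect_equal(growth_size(thp, A = 20, t = 50), 20)  # fully saturated
  thp2 <- growth_params_kprime(0.0278, b = 1.22, l = 3.85)
  expect_equal(growth_size(thp2, A = 20, t = 50), 7.447097269592976,
               tolerance = 1e-14)
  # domain errors
  expect_error(growth_size(th, A = -1, t = 5), "positive")
  expect_error(growth_size(th, A = 5, t = 0), "positive")
})

test_that("growth_jacobian reduces to the anamorphic closed form at l = 0", {
  th <- growth_params(k = 0.0463, b = 1.76)
  expected <- (1 - exp(-0.0463 * 50))^1.76
  expect_identical(growth_jacobian(th, A = 7, t = 50),
                   growth_jacobian(th, A = 40, t = 50))
  expect_equal(growth_jacobian(th, A = 25, t = 50), expected,
               tolerance = 1e-14)
  # b = 1: derivative is the saturation fraction itself
  th1 <- growth_params(k = 0.08, b = 1)
  expect_equal(growth_jacobian(th1, A = 10, t = 30), 1 - exp(-0.08 * 30),
               tolerance = 1e-14)
  # polymorphic value frozen against the 50-digit evaluation of Eq-form
  # A^l k l b t E (1-E)^(b-1) + (1-E)^b
  thp <- growth_params_kprime(0.0278, b = 1.22, l = 3.85)
  expect_equal(growth_jacobian(thp, A = 20, t = 50), 1.6567069933887785,
               tolerance = 1e-13)
})

test_that("growth_jacobian agrees with central finite differences", {
  set.seed(7)
  for (i in 1:40) {
    l <- sample(c(0, runif(1, -2, 8)), 1)
    th <- growth_params_kprime(10^runif(1, -3, -1), b = runif(1, 0.3, 4),
                               l = l)
    A <- runif(1, 5, 50); t <- runif(1, 5, 140)
    h <- 1e-6 * A
    fd <- (growth_size(th, A + h, t) - growth_size(th, A - h, t)) / (2 * h)
    expect_equal(growth_jacobian(th, A, t), fd, tolerance = 1e-5)
  }
})

test_that("invert_asymptote round-trips and matches its closed form", {
  th <- growth_params(k = 0.1, b = 1)
  expect_equal(invert_asymptote(th, x = 12.5, t = log(2) / 0.1), 25,
               tolerance = 1e-10)
  thp <- growth_params(k = 0.0278, b = 1.22, l = 3.85)
  x <- growth_size(thp, A = 20, t = 50)
  expect_equal(invert_asymptote(thp, x, t = 50), 20, tolerance = 1e-6)
  # random round trips, anamorphic and polymorphic
  set.seed(11)
  for (i in 1:60) {
    th <- growth_params_kprime(10^runif(1, -2.5, -1), b = runif(1, 0.3, 4),
                               l = sample(c(0, runif(1, 0, 9)), 1))
    A <- runif(1, 5, 60); t <- runif(1, 5, 150)
    x <- growth_size(th, A, t)
    expect_equal(invert_asymptote(th, x, t), A, tolerance = 1e-6)
  }
})

test_that("polymorphic inversion agrees with a fine-grid bisection oracle", {
  th <- growth_params_kprime(0.0278, b = 1.22, l = 3.85)
  x <- 15; t <- 40
  # oracle: exhaustive bisection on g(A) = x - A f(t; A) over [x, 1000 x]
  g <- function(A) x - growth_size(th, A, t)
  lo <- x; hi <- 1000 * x
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (g(mid) > 0) lo <- mid else hi <- mid
  }
  expect_equal(invert_asymptote(th, x, t), (lo + hi) / 2, tolerance = 1e-8)
})

test_that("size is monotone in the asymptote for l >= 0, ensuring unique inversion", {
  for (l in c(0, 0.27, 2, 6)) {
    th <- growth_params_kprime(0.03, b = 1.3, l = l)
    for (t in c(15, 60, 110)) {
      x <- growth_size(th, seq(2, 80, length.out = 120), t)
      expect_true(all(diff(x) > 0))
    }
  }
})

test_that("inversion failure carries the offending observation", {
  # a curve set so slow that the asymptote lies beyond the bracket cap
  th <- growth_params_kprime(1e-11, b = 1, l = 1)
  x <- growth_size(th, A = 30, t = 12)
  err <- tryCatch(invert_asymptote(th, x, t = 12), error = identity)
  expect_s3_class(err, "nonchron_inversion_error")
  expect_equal(err$x, x)
  expect_equal(err$t, 12)
})

test_that("reparameterization k = k'/a_ref^l holds exactly", {
  th <- growth_params_kprime(0.0278, b = 1.22, l = 3.85, a_ref = 25)
  expect_identical(th$k, 0.0278 / 25^3.85)
  expect_equal(th$k_prime, 0.0278, tolerance = 1e-15)
  # anamorphic: k' and k coincide
  th0 <- growth_params(k = 0.05, b = 1.3)
  expect_identical(th0$k_prime, 0.05)
})
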