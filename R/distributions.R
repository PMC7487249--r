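#' Asymptote distributions
#'
#' Distributions for the individual asymptotes `A` of a growth curve set.
#' Two families are supported: the lognormal, and the three-parameter
#' generalized gamma in Stacy's form
#' \deqn{p(A) = \frac{\tau}{\Gamma(\psi)\,\lambda}
#'   \left(\frac{A}{\lambda}\right)^{\psi\tau - 1}
#'   \exp\left[-\left(\frac{A}{\lambda}\right)^\tau\right],}
#' which contains the gamma distribution (\eqn{\tau = 1}), the Weibull
#' distribution (\eqn{\psi = 1}) and the lognormal as the \eqn{\psi \to
#' \infty} limit.
#'
#' @param meanlog mean of `log(A)` (log size units).
#' @param sdlog standard deviation of `log(A)`; `> 0`.
#' @return An object of class `"asym_dist"` with elements `family`
#'   (`"lognormal"` or `"gengamma"`) and the named parameters.
#' @examples
#' d <- gengamma_dist(scale = 8.70, psi = 30.98, tau = 3.25)
#' asym_quantile(d, c(0.025, 0.5, 0.975))
#' @export
lognormal_dist <- function(meanlog, sdlog) {
  stopifnot(is.numeric(meanlog), length(meanlog) == 1L, is.finite(meanlog),
            is.numeric(sdlog), length(sdlog) == 1L, is.finite(sdlog),
            sdlog > 0)
  structure(list(family = "lognormal", meanlog = meanlog, sdlog = sdlog),
            class = "asym_dist")
}

#' @rdname lognormal_dist
#' @param scale scale \eqn{\lambda} (size units); `> 0`.
#' @param psi shape \eqn{\psi}; `> 0`.
#' @param tau shape \eqn{\tau} (power); `> 0`.
#' @export
gengamma_dist <- function(scale, psi, tau) {
  stopifnot(is.numeric(scale), length(scale) == 1L, is.finite(scale), scale > 0,
            is.numeric(psi), length(psi) == 1L, is.finite(psi), psi > 0,
            is.numeric(tau), length(tau) == 1L, is.finite(tau), tau > 0)
  structure(list(family = "gengamma", scale = scale, psi = psi, tau = tau),
            class = "asym_dist")
}

#' @export
print.asym_dist <- function(x, ...) {
  if (x$family == "lognormal")
    cat(sprintf("Lognormal asymptote distribution: meanlog = %.4g, sdlog = %.4g\n",
                x$meanlog, x$sdlog))
  else
    cat(sprintf("Generalized gamma asymptote distribution: scale = %.4g, psi = %.4g, tau = %.4g\n",
                x$scale, x$psi, x$tau))
  invisible(x)
}

#' Log density of an asymptote distribution
#'
#' Computed through `lgamma()`; no raw gamma-function evaluation, so the
#' density stays finite for very large shape \eqn{\psi} (the lognormal
#' limit).
#'
#' @param dist an `"asym_dist"` object.
#' @param A asymptote value(s), `> 0`.
#' @return Log density at `A` (vectorized).
#' @export
asym_logpdf <- function(dist, A) {
  stopifnot(inherits(dist, "asym_dist"))
  .check_pos(A, "A")
  if (dist$family == "lognormal")
    return(stats::dlnorm(A, dist$meanlog, dist$sdlog, log = TRUE))
  z <- A / dist$scale
  log(dist$tau) - lgamma(dist$psi) - log(dist$scale) +
    (dist$psi * dist$tau - 1) * log(z) - z^dist$tau
}

#' Sample asymptotes
#'
#' Generalized gamma variates are generated as
#' \eqn{A = \lambda G^{1/\tau}} with \eqn{G \sim \mathrm{Gamma}(\psi, 1)}.
#'
#' @inheritParams asym_logpdf
#' @param n number of draws.
#' @param seed optional integer; when given, draws are reproducible and
#'   the caller's RNG state is left untouched.
#' @return Numeric vector of `n` positive draws.
#' @export
asym_sample <- function(dist, n, seed = NULL) {
  stopifnot(inherits(dist, "asym_dist"), n >= 1)
  draw <- function() {
    if (dist$family == "lognormal")
      stats::rlnorm(n, dist$meanlog, dist$sdlog)
    else
      dist$scale * stats::rgamma(n, shape = dist$psi)^(1 / dist$tau)
  }
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

#' Quantiles of an asymptote distribution
#'
#' @inheritParams asym_logpdf
#' @param q probability(ies) in `(0, 1)`.
#' @return Quantile(s); monotone in `q`. For the generalized gamma the
#'   quantile is the same monotone transform of the gamma quantile used
#'   for sampling, \eqn{\lambda\, Q_{\Gamma(\psi)}(q)^{1/\tau}}.
#' @export
asym_quantile <- function(dist, q) {
  stopifnot(inherits(dist, "asym_dist"))
  if (!is.numeric(q) || anyNA(q) || any(q <= 0) || any(q >= 1))
    stop("'q' must lie strictly inside (0, 1)", call. = FALSE)
  if (dist$family == "lognormal")
    stats::qlnorm(q, dist$meanlog, dist$sdlog)
  else
    dist$scale * stats::qgamma(q, shape = dist$psi)^(1 / dist$tau)
}

# Negative log-likelihood of gengamma shapes (lpsi, ltau) with the scale
# profiled out in closed form: d ll / d lambda = 0 gives
# lambda^tau = sum(A^tau) / (n psi).
.gengamma_profile_nll <- function(par, logA, bounds) {
  psi <- exp(par[1]); tau <- exp(par[2])
  if (psi < bounds$psi[1] || psi > bounds$psi[2] ||
      tau < bounds$tau[1] || tau > bounds$tau[2])
    return(1e10 + sum(par^2))
  n <- length(logA)
  s <- .logsumexp(tau * logA)            # log sum A^tau
  loglam <- (s - log(n * psi)) / tau
  loglam <- min(max(loglam, log(bounds$scale[1])), log(bounds$scale[2]))
  z <- exp(tau * (logA - loglam))
  ll <- n * log(tau) - n * lgamma(psi) - n * loglam +
    (psi * tau - 1) * sum(logA - loglam) - sum(z)
  if (!is.finite(ll)) return(1e10)
  -ll
}

.logsumexp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}

.gengamma_bounds <- list(scale = c(1e-6, 1e3), psi = c(1e-3, 1e6),
                         tau = c(0.1, 10))

#' Maximum-likelihood fit of an asymptote distribution
#'
#' Lognormal fits are closed form (`meanlog` = mean of `log(A)`,
#' `sdlog^2` = the MLE variance of `log(A)`, divisor `n`). Generalized
#' gamma fits profile the scale \eqn{\lambda} out analytically and run a
#' Nelder-Mead search over \eqn{(\log\psi, \log\tau)} from several
#' deterministic starts (moment-matched gamma, Weibull, the lognormal
#' \eqn{\psi \to \infty} ridge, and a generic interior point), within the
#' box \eqn{\lambda \in [10^{-6}, 10^3]}, \eqn{\psi \in [10^{-3}, 10^6]},
#' \eqn{\tau \in [0.1, 10]}. The \eqn{\psi} cap keeps the lognormal-limit
#' ridge finite.
#'
#' @param A positive asymptote values, `length >= 2` (>= 3 recommended for
#'   the generalized gamma).
#' @param family `"lognormal"` or `"gengamma"`.
#' @param start optional `c(psi, tau)` warm start for the generalized
#'   gamma search (e.g. the previous fit during nested optimization).
#' @return List with elements `dist` (the fitted `"asym_dist"`) and
#'   `loglik` (the maximized log-likelihood \eqn{\sum_i \log p(A_i)}).
#' @export
asym_fit <- function(A, family = c("lognormal", "gengamma"), start = NULL) {
  family <- match.arg(family)
  .check_pos(A, "A")
  if (length(A) < 2L) stop("need at least 2 asymptote values", call. = FALSE)
  logA <- log(A)
  if (stats::var(logA) < 1e-16)
    stop(errorCondition(
      "degenerate asymptote sample: zero variance on the log scale (unbounded likelihood)",
      class = c("nonchron_degenerate_error", "nonchron_error")))
  if (family == "lognormal") {
    mu <- mean(logA)
    sig <- sqrt(mean((logA - mu)^2))
    dist <- lognormal_dist(mu, sig)
    return(list(dist = dist, loglik = sum(asym_logpdf(dist, A))))
  }
  .gengamma_fit(A, logA, start)
}

.gengamma_fit <- function(A, logA, start = NULL) {
  bounds <- .gengamma_bounds
  n <- length(A)
  m <- mean(A); v <- stats::var(A)
  mu_l <- mean(logA); sd_l <- stats::sd(logA)
  starts <- list(
    c(max(m^2 / v, 1e-2), 1),                      # moment-matched gamma
    c(1, min(max(1.2825 / sd_l, 0.15), 9)),        # Weibull (log-sd match)
    local({                                        # lognormal-limit ridge
      psi0 <- min(1e4, 1 / (0.04 * sd_l^2))
      tau0 <- min(max(1 / (sd_l * sqrt(psi0)), 0.10001), 10)
      c(psi0, tau0)
    }),
    c(2, 2))
  maxit <- 400L
  if (!is.null(start)) {        # warm start plus one safeguard start
    starts <- c(list(start), starts[1])
    maxit <- 150L               # warm starts sit near the optimum already
  }
  best <- NULL
  for (s in starts) {
    par0 <- log(pmin(pmax(s, c(bounds$psi[1], bounds$tau[1]) * 1.0001),
                     c(bounds$psi[2], bounds$tau[2]) * 0.9999))
    opt <- stats::optim(par0, .gengamma_profile_nll, logA = logA,
                        bounds = bounds, method = "Nelder-Mead",
                        control = list(maxit = maxit, reltol = 1e-10))
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  psi <- exp(best$par[1]); tau <- exp(best$par[2])
  loglam <- (.logsumexp(tau * logA) - log(n * psi)) / tau
  lam <- min(max(exp(loglam), bounds$scale[1]), bounds$scale[2])
  dist <- gengamma_dist(lam, psi, tau)
  list(dist = dist, loglik = sum(asym_logpdf(dist, A)))
}
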