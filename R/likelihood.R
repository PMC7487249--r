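#' Profile negative log-likelihood of a growth curve set
#'
#' The core of the estimation method. For nonchronological data the
#' log-likelihood factorizes as
#' \deqn{LL = \sum_i \ln p(t_i) + \sum_i \ln p(A_i)
#'   - \sum_i \ln \left.\frac{dx}{dA}\right|_{t_i, A_i},}
#' where \eqn{A_i} is the asymptote of the curve passing through
#' observation \eqn{(t_i, x_i)} and \eqn{dx/dA} is the change-of-variables
#' Jacobian that maps the asymptote density onto the size density at age
#' \eqn{t_i}. The age term \eqn{\sum_i \ln p(t_i)} does not depend on the
#' model and is excluded throughout (reported NLLs follow that
#' convention).
#'
#' For fixed curve parameters the asymptote-distribution parameters enter
#' only through \eqn{\sum_i \ln p(A_i)}, so they are profiled out: the
#' distribution is fitted to \eqn{\{A_i\}} by maximum likelihood
#' ([asym_fit()]) and its maximized log-likelihood used as that
#' summation.
#'
#' Inside an outer optimization a candidate `theta` whose inversion fails
#' or whose asymptotes are degenerate must not abort the search; with
#' `penalty = TRUE` (the default) such candidates return `nll = Inf` (a
#' sentinel the optimizer skips) instead of raising.
#'
#' @param theta a [growth_params()] object.
#' @param data an [observation_set()].
#' @param dist_family `"lognormal"` or `"gengamma"`.
#' @param start optional warm start for the generalized gamma inner fit.
#' @param penalty return an `Inf` sentinel instead of raising on
#'   inversion failure or degenerate asymptotes.
#' @return List of class `"likelihood_value"`: `nll` (negative
#'   log-likelihood in nats, age term excluded), `dist` (fitted
#'   asymptote distribution), `asymptotes` (per-observation \eqn{A_i}),
#'   `jacobians` (per-observation \eqn{dx/dA}), and `reason` (`NULL`, or
#'   why the sentinel was returned).
#' @export
profile_negloglik <- function(theta, data, dist_family = c("lognormal", "gengamma"),
                              start = NULL, penalty = TRUE) {
  stopifnot(inherits(theta, "growth_params"), inherits(data, "observation_set"))
  dist_family <- match.arg(dist_family)
  fail <- function(reason, cond) {
    if (!penalty) stop(cond)
    structure(list(nll = Inf, dist = NULL, asymptotes = NULL,
                   jacobians = NULL, reason = reason),
              class = "likelihood_value")
  }
  A <- tryCatch(invert_asymptote(theta, data$size, data$age),
                nonchron_error = function(e) e)
  if (inherits(A, "condition")) return(fail(conditionMessage(A), A))
  J <- growth_jacobian(theta, A, data$age)
  if (any(!is.finite(J)) || any(J <= 0))
    return(fail("non-positive or non-finite Jacobian",
                simpleError("non-positive Jacobian")))
  fit <- tryCatch(asym_fit(A, dist_family, start = start),
                  nonchron_error = function(e) e)
  if (inherits(fit, "condition")) return(fail(conditionMessage(fit), fit))
  nll <- -(fit$loglik - sum(log(J)))
  if (!is.finite(nll))
    return(fail("non-finite likelihood", simpleError("non-finite likelihood")))
  structure(list(nll = nll, dist = fit$dist, asymptotes = A, jacobians = J,
                 reason = NULL),
            class = "likelihood_value")
}

#' Conditional size density at a given age
#'
#' The density of observed size `x` at fixed age `t` implied by the
#' growth curve set and the asymptote distribution:
#' \eqn{p(x \mid t) = p(A(x, t)) \cdot (dx/dA)^{-1}}. Mass is conserved
#' under the change of variables, so for each `t` the density integrates
#' to one over `x` and quantiles of the asymptote distribution map onto
#' quantiles of the size distribution.
#'
#' @inheritParams profile_negloglik
#' @param dist an `"asym_dist"` object.
#' @param t age (scalar), years.
#' @param x size value(s) at which to evaluate the density.
#' @return Density values (zero where no curve passes through `(t, x)`).
#' @export
conditional_size_density <- function(theta, dist, t, x) {
  stopifnot(inherits(theta, "growth_params"), inherits(dist, "asym_dist"),
            length(t) == 1L)
  .check_pos(t, "t")
  vapply(x, function(xi) {
    if (!is.finite(xi) || xi <= 0) return(0)
    A <- tryCatch(invert_asymptote(theta, xi, t),
                  nonchron_error = function(e) NA_real_)
    if (is.na(A)) return(0)
    J <- growth_jacobian(theta, A, t)
    if (!is.finite(J) || J <= 0) return(0)
    exp(asym_logpdf(dist, A)) / J
  }, numeric(1))
}
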