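#' Growth curve set parameters
#'
#' Parameters of a Richards-type growth curve set
#' \deqn{x = A \left[1 - \exp(-k A^l t)\right]^b}
#' where \eqn{A} is the individual asymptote, \eqn{t} age and \eqn{x} size.
#' With \eqn{l = 0} the set is *anamorphic*: every curve is the same
#' standard curve scaled by its asymptote. With \eqn{l \neq 0} the rate
#' \eqn{k A^l} covaries with the asymptote and the set is *polymorphic*.
#'
#' During optimization the rate is searched as the reparameterized
#' \eqn{k' = k \cdot a_{ref}^l}, i.e. the effective rate of an individual
#' whose asymptote equals the reference asymptote `a_ref` (default 25 size
#' units, a rough average asymptote). This keeps the search box for the
#' rate comparable across values of `l`; [growth_params_kprime()] builds
#' parameters from that scale.
#'
#' @param k growth rate (per year) multiplying \eqn{A^l}; `> 0`.
#' @param b shape exponent, dimensionless; `> 0`.
#' @param l asymptote exponent, dimensionless; `0` gives the anamorphic set.
#' @param a_ref reference asymptote (size units) used by the \eqn{k'}
#'   reparameterization; `> 0`.
#' @return An object of class `"growth_params"`.
#' @seealso [growth_size()], [growth_jacobian()], [invert_asymptote()]
#' @examples
#' th <- growth_params(k = 0.0463, b = 1.76)        # anamorphic
#' growth_size(th, A = 25, t = 50)
#' @export
growth_params <- function(k, b, l = 0, a_ref = 25) {
  stopifnot(is.numeric(k), length(k) == 1L, is.finite(k), k > 0,
            is.numeric(b), length(b) == 1L, is.finite(b), b > 0,
            is.numeric(l), length(l) == 1L, is.finite(l),
            is.numeric(a_ref), length(a_ref) == 1L, is.finite(a_ref),
            a_ref > 0)
  structure(list(k = k, b = b, l = l, a_ref = a_ref,
                 k_prime = k * a_ref^l),
            class = "growth_params")
}

#' @rdname growth_params
#' @param k_prime reparameterized rate \eqn{k' = k \cdot a_{ref}^l}; `> 0`.
#' @export
growth_params_kprime <- function(k_prime, b, l = 0, a_ref = 25) {
  stopifnot(is.numeric(k_prime), length(k_prime) == 1L,
            is.finite(k_prime), k_prime > 0)
  growth_params(k = k_prime / a_ref^l, b = b, l = l, a_ref = a_ref)
}

#' @export
print.growth_params <- function(x, ...) {
  fam <- if (x$l == 0) "anamorphic" else "polymorphic"
  cat(sprintf("Growth curve set (%s): k = %.6g, b = %.4g, l = %.4g (a_ref = %g, k' = %.6g)\n",
              fam, x$k, x$b, x$l, x$a_ref, x$k_prime))
  invisible(x)
}

# saturation fraction f(t; A) = (1 - exp(-k A^l t))^b, computed through
# expm1/log1p so that both u -> 0 and u -> Inf stay accurate
.saturation <- function(params, A, t) {
  u <- params$k * A^params$l * t
  (-expm1(-u))^params$b
}

.check_pos <- function(x, what) {
  if (!is.numeric(x) || length(x) == 0L || anyNA(x) || any(x <= 0) ||
      any(!is.finite(x)))
    stop(sprintf("'%s' must be strictly positive and finite", what),
         call. = FALSE)
  invisible(x)
}

#' Evaluate a growth curve set
#'
#' Size of an individual with asymptote `A` at age `t`:
#' \eqn{x = A (1 - e^{-k A^l t})^b}. Vectorized over `A` and `t`
#' (recycled).
#'
#' @param params a [growth_params()] object.
#' @param A asymptote(s), `> 0`.
#' @param t age(s) in years, `> 0`.
#' @return Numeric vector of sizes, `0 < x < A`, approaching `A` as
#'   `t` grows.
#' @export
growth_size <- function(params, A, t) {
  stopifnot(inherits(params, "growth_params"))
  .check_pos(A, "A"); .check_pos(t, "t")
  A * .saturation(params, A, t)
}

#' Derivative of size with respect to the asymptote
#'
#' The Jacobian \eqn{dx/dA} of the growth curve set at fixed age,
#' \deqn{dx/dA = A^l k l b t E (1-E)^{b-1} + (1-E)^b, \quad E = e^{-k A^l t},}
#' which reduces to \eqn{(1 - e^{-kt})^b} (independent of `A`) for the
#' anamorphic case \eqn{l = 0}. This is the change-of-variables factor that
#' converts the asymptote density into the size density at age `t`.
#'
#' @inheritParams growth_size
#' @return Numeric vector of derivatives (dimensionless); strictly
#'   positive for `l >= 0`.
#' @export
growth_jacobian <- function(params, A, t) {
  stopifnot(inherits(params, "growth_params"))
  .check_pos(A, "A"); .check_pos(t, "t")
  u <- params$k * A^params$l * t
  E <- exp(-u)
  one <- -expm1(-u)                    # 1 - E
  b <- params$b
  u * params$l * b * E * one^(b - 1) + one^b
}

#' Invert a growth curve set: asymptote from (size, age)
#'
#' Recovers the asymptote `A` of the curve passing through the observed
#' point `(t, x)`. Anamorphic sets (`l = 0`) invert in closed form,
#' `A = x / (1 - exp(-k t))^b`; otherwise the root of
#' `x - A f(t; A) = 0` is found by bracketed (Brent) root finding followed
#' by Newton polishing, to a relative tolerance of about `1e-10`.
#'
#' The initial bracket is `[x, max(2x, a_ref)]` (the asymptote can never
#' be below the observed size) and the upper end is doubled until the
#' objective changes sign, up to `1e6 * x`. For `l < 0` the size need not
#' be monotone in `A`; a coarse scan of the bracket detects multiple sign
#' changes and raises an ambiguity error rather than silently returning
#' one root.
#'
#' @inheritParams growth_size
#' @param x observed size(s), `> 0`.
#' @return Numeric vector of asymptotes with
#'   `growth_size(params, A, t) == x` to within relative `1e-8`.
#' @export
invert_asymptote <- function(params, x, t) {
  stopifnot(inherits(params, "growth_params"))
  .check_pos(x, "x"); .check_pos(t, "t")
  n <- max(length(x), length(t))
  x <- rep_len(x, n); t <- rep_len(t, n)
  if (params$l == 0) {
    f <- .saturation(params, 1, t)     # A-independent saturation fraction
    return(x / f)
  }
  if (params$l > 0) {
    # size is monotone in A: vectorized Newton from an anamorphic-style
    # guess, with the bracketed Brent solver as per-element fallback
    A <- .invert_newton(params, x, t)
    bad <- which(is.na(A))
    for (i in bad) A[i] <- .invert_one(params, x[i], t[i])
    return(A)
  }
  vapply(seq_len(n), function(i) .invert_one(params, x[i], t[i]), numeric(1))
}

.invert_newton <- function(params, x, t) {
  A <- pmax(x / .saturation(params, pmax(x, params$a_ref), t), x * (1 + 1e-12))
  hi <- 1e6 * x
  ok <- rep(TRUE, length(x))
  for (iter in 1:40) {
    fx <- A * .saturation(params, A, t)
    J <- growth_jacobian(params, A, t)
    step <- (x - fx) / J
    bad <- !is.finite(step) | J <= 0
    step[bad] <- 0
    A2 <- pmin(pmax(A + step, x), hi)
    ok <- ok & !bad
    conv <- abs(step) <= 1e-13 * A2
    A <- A2
    if (all(conv | !ok)) break
  }
  # verify the round trip; reject elements Newton did not solve
  resid <- abs(A * .saturation(params, A, t) - x)
  A[!ok | resid > 1e-8 * x] <- NA_real_
  A
}

.invert_one <- function(params, x, t) {
  g <- function(A) x - growth_size(params, A, t)
  lo <- x
  glo <- g(lo)
  if (glo == 0) return(lo)
  if (glo < 0)                          # cannot happen for a curve below
    stop(.inversion_cond(x, t, "size above every curve at this age"))
  hi <- max(2 * x, params$a_ref)
  while (g(hi) > 0 && hi < 1e6 * x) hi <- 2 * hi
  if (g(hi) > 0)
    stop(.inversion_cond(x, t, "no sign change within expanded bracket"))
  if (params$l < 0) {
    grid <- exp(seq(log(lo), log(hi), length.out = 64L))
    sg <- sign(g(grid))
    flips <- sum(diff(sg[sg != 0]) != 0)
    if (flips > 1L)
      stop(errorCondition(
        sprintf("ambiguous inversion at (x = %g, t = %g): multiple roots in bracket (l = %g < 0)",
                x, t, params$l),
        x = x, t = t,
        class = c("nonchron_ambiguity_error", "nonchron_error")))
  }
  A <- stats::uniroot(g, lower = lo, upper = hi,
                      tol = 1e-10 * max(1, x))$root
  for (i in 1:3) {                      # Newton polish to machine precision
    d <- growth_jacobian(params, A, t)
    if (!is.finite(d) || d <= 0) break
    step <- g(A) / d
    A2 <- A + step
    if (!is.finite(A2) || A2 <= 0) break
    A <- A2
    if (abs(step) < 1e-14 * A) break
  }
  A
}

.inversion_cond <- function(x, t, why) {
  errorCondition(
    sprintf("inversion failure at (x = %g, t = %g): %s", x, t, why),
    x = x, t = t,
    class = c("nonchron_inversion_error", "nonchron_error"))
}
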