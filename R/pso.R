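#' Particle swarm optimization settings
#'
#' Defaults follow the well-studied constriction parameterization
#' (inertia 0.729, cognitive = social = 1.49445) with 40 particles, 300
#' iterations, velocities clamped to half the box width per dimension,
#' and reflection at the bounds. A Nelder-Mead polish from the swarm
#' incumbent is applied at the end (particle swarms terminate near, not
#' at, optima).
#'
#' @param n_particles swarm size.
#' @param n_iters maximum iterations.
#' @param inertia inertia weight `w`, in `(0, 1)`.
#' @param c_cog,c_soc cognitive and social acceleration coefficients.
#' @param v_max_frac velocity clamp as a fraction of the box width.
#' @param tol stagnation tolerance on the incumbent objective.
#' @param patience iterations without `tol` improvement before stopping.
#' @param polish apply the final Nelder-Mead refinement.
#' @return A list of class `"pso_settings"`.
#' @export
pso_settings <- function(n_particles = 40L, n_iters = 300L, inertia = 0.729,
                         c_cog = 1.49445, c_soc = 1.49445, v_max_frac = 0.5,
                         tol = 1e-10, patience = 50L, polish = TRUE) {
  stopifnot(n_particles >= 1, n_iters >= 1, inertia > 0, inertia < 1,
            c_cog > 0, c_soc > 0, v_max_frac > 0, patience >= 1)
  structure(list(n_particles = as.integer(n_particles),
                 n_iters = as.integer(n_iters), inertia = inertia,
                 c_cog = c_cog, c_soc = c_soc, v_max_frac = v_max_frac,
                 tol = tol, patience = as.integer(patience),
                 polish = isTRUE(polish)),
            class = "pso_settings")
}

# reflect positions at the box boundary, flipping the velocity component
.reflect <- function(x, v, lower, upper) {
  for (rep in 1:3) {
    below <- x < lower
    x[below] <- (2 * lower - x)[below]; v[below] <- -v[below]
    above <- x > upper
    x[above] <- (2 * upper - x)[above]; v[above] <- -v[above]
    if (!any(x < lower | x > upper)) break
  }
  x <- pmin(pmax(x, lower), upper)
  list(x = x, v = v)
}

#' Minimize a bounded objective by particle swarm optimization
#'
#' Global search over a box. The objective may return `Inf` as an
#' infeasibility sentinel; if every evaluation is infeasible a
#' "no feasible point" error is raised. Deterministic for a fixed
#' `seed`.
#'
#' @param fn objective, a function of a numeric vector returning a
#'   finite value or `Inf`.
#' @param lower,upper finite bound vectors of equal length.
#' @param settings a [pso_settings()] object.
#' @param seed integer seed (required for reproducibility).
#' @param init optional matrix (rows = points) of initial positions to
#'   seed into the swarm, e.g. a previous fit's optimum.
#' @return List with `par` (best position), `value` (best objective),
#'   `trace` (incumbent value per iteration), and `evals`.
#' @examples
#' pso_minimize(function(z) sum(z^2), rep(-5, 3), rep(5, 3),
#'              settings = pso_settings(n_particles = 20, n_iters = 50),
#'              seed = 1)$value
#' @export
pso_minimize <- function(fn, lower, upper, settings = pso_settings(),
                         seed = 1L, init = NULL) {
  stopifnot(is.function(fn), length(lower) == length(upper),
            all(is.finite(lower)), all(is.finite(upper)),
            all(lower < upper), inherits(settings, "pso_settings"))
  d <- length(lower)
  with_seed(seed, {
    np <- settings$n_particles
    width <- upper - lower
    vmax <- settings$v_max_frac * width
    X <- matrix(stats::runif(d * np, lower, upper), nrow = d)
    if (!is.null(init)) {
      init <- matrix(init, ncol = d)
      take <- min(nrow(init), np)
      for (j in seq_len(take))
        X[, j] <- pmin(pmax(init[j, ], lower), upper)
    }
    V <- matrix(stats::runif(d * np, -vmax, vmax), nrow = d)
    fvals <- apply(X, 2, fn)
    evals <- np
    if (all(!is.finite(fvals)))
      feasible_seen <- FALSE
    else feasible_seen <- TRUE
    Pbest <- X; pbest_f <- fvals
    gi <- which.min(pbest_f)
    gbest <- X[, gi]; gbest_f <- pbest_f[gi]
    trace <- numeric(settings$n_iters)
    stall <- 0L
    for (it in seq_len(settings$n_iters)) {
      r1 <- matrix(stats::runif(d * np), nrow = d)
      r2 <- matrix(stats::runif(d * np), nrow = d)
      V <- settings$inertia * V +
        settings$c_cog * r1 * (Pbest - X) +
        settings$c_soc * r2 * (gbest - X)
      V <- pmin(pmax(V, -vmax), vmax)
      X <- X + V
      for (j in seq_len(np)) {
        rj <- .reflect(X[, j], V[, j], lower, upper)
        X[, j] <- rj$x; V[, j] <- rj$v
      }
      fvals <- apply(X, 2, fn)
      evals <- evals + np
      if (any(is.finite(fvals))) feasible_seen <- TRUE
      improved <- fvals < pbest_f
      Pbest[, improved] <- X[, improved]
      pbest_f[improved] <- fvals[improved]
      gi <- which.min(pbest_f)
      if (pbest_f[gi] < gbest_f - settings$tol) stall <- 0L
      else stall <- stall + 1L
      if (pbest_f[gi] < gbest_f) {
        gbest_f <- pbest_f[gi]; gbest <- Pbest[, gi]
      }
      trace[it] <- gbest_f
      if (stall >= settings$patience) {
        trace <- trace[seq_len(it)]
        break
      }
    }
    if (!feasible_seen || !is.finite(gbest_f))
      stop(errorCondition("no feasible point found: objective was infinite everywhere",
                          class = c("nonchron_infeasible_error", "nonchron_error")))
    if (settings$polish) {
      pen <- function(p) {
        if (any(p < lower) || any(p > upper)) return(1e12)
        v <- fn(p)
        if (!is.finite(v)) 1e12 else v
      }
      pol <- stats::optim(gbest, pen, method = "Nelder-Mead",
                          control = list(maxit = 500, reltol = 1e-12))
      evals <- evals + pol$counts[1]
      if (is.finite(pol$value) && pol$value < gbest_f &&
          all(pol$par >= lower) && all(pol$par <= upper)) {
        gbest <- pol$par; gbest_f <- pol$value
      }
    }
    list(par = as.numeric(gbest), value = gbest_f, trace = trace,
         evals = as.numeric(evals))
  })
}
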