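# Shared fixtures: published point estimates used as generating truths,
# and small swarm budgets suited to the smooth 2-3 parameter profile
# surfaces exercised in the tests.

ref <- reference_true_models()

quick_settings <- pso_settings(n_particles = 16L, n_iters = 40L,
                               patience = 20L)

# independent log-least-squares estimator of the anamorphic-lognormal
# model: minimize sum (log x - c - log f(t; k, b))^2 jointly over
# (c, log10 k, b) by multi-start Nelder-Mead
log_lse_fit <- function(obs) {
  sse <- function(p) {
    k <- 10^p[2]; b <- p[3]
    if (k <= 0 || b <= 0 || b > 10) return(1e10)
    lf <- b * log(-expm1(-k * obs$age))
    sum((log(obs$size) - p[1] - lf)^2)
  }
  best <- NULL
  for (s in list(c(3, -1.3, 1.5), c(3, -2, 1), c(2.5, -1, 3))) {
    o <- stats::optim(s, sse, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-12))
    o <- stats::optim(o$par, sse, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-12))
    if (is.null(best) || o$value < best$value) best <- o
  }
  list(c = best$par[1], k = 10^best$par[2], b = best$par[3],
       sse = best$value)
}
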